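#' Simulate, estimate and score a scenario's design grid
#'
#' For every non-excluded design row, simulates `n_sim` independent trials,
#' reduces each to its estimates ([summarize_trial()] statistics), and scores
#' every replicate with all four benefit-assessment rules
#' ([assess_benefit()]).  Randomness uses one L'Ecuyer-CMRG stream per
#' subscenario, indexed by the subscenario's position in its scenario grid
#' and derived deterministically from the master seed; replicate-level
#' results therefore do not depend on row order, on subsetting the grid, or
#' on how subscenarios would be distributed over workers.
#'
#' @param designs Design grid from [build_design_grid()] (or a
#'   [scenario_spec()], which is expanded first).
#' @param n_sim Number of simulated trials per subscenario.
#' @param seed Master seed (integer).
#' @param table ESMO threshold table.
#' @param tail_at,tail_rule Passed to [assess_benefit()].
#' @param directional Require `hr_pe < 1` in addition to log-rank
#'   significance (default); `FALSE` gates on the p-value alone.
#' @param level Wald confidence level.
#' @return Tibble with one row per replicate: design identifiers, replicate
#'   index, `status` (significant / non_significant / degenerate), the trial
#'   estimates, and the four method scores.
#' @examples
#' \donttest{
#' spec <- scenario_spec("standard", design_hr = 0.6, med_c = 12, power = 0.9)
#' reps <- run_scenario(build_design_grid(spec), n_sim = 20, seed = 1)
#' }
#' @export
run_scenario <- function(designs, n_sim, seed, table = esmo_thresholds(),
                         tail_at = c("estimated", "design"),
                         tail_rule = c("absolute", "relative"),
                         directional = TRUE, level = 0.95) {
  if (inherits(designs, "scenario_spec")) designs <- build_design_grid(designs)
  stopifnot(is.data.frame(designs), n_sim >= 1, is.numeric(seed))
  tail_at <- match.arg(tail_at)

  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())

  # stream k belongs to grid index k (parsed from the subscenario id), so a
  # subset or reordering of the grid reproduces the full run's replicates
  idx <- as.integer(sub(".*_", "", designs$subscenario))
  if (anyNA(idx)) idx <- seq_len(nrow(designs))
  streams <- vector("list", max(idx))
  for (k in seq_len(max(idx))) {
    stream <- parallel::nextRNGStream(stream)
    streams[[k]] <- stream
  }

  active <- which(!designs$excluded)
  chunks <- vector("list", length(active))
  for (ci in seq_along(active)) {
    i <- active[ci]
    design <- as.list(designs[i, ])
    assign(".Random.seed", streams[[idx[i]]], globalenv())
    est <- matrix(NA_real_, n_sim, length(est_names),
                  dimnames = list(NULL, est_names))
    for (r in seq_len(n_sim)) {
      raw <- sim_trial_raw(design)
      est[r, ] <- reduce_trial(raw$time, raw$event, raw$arm, design,
                               level = level)
    }
    chunk <- tibble::as_tibble(est)
    chunk$scenario <- design$scenario
    chunk$subscenario <- design$subscenario
    chunk$replicate <- seq_len(n_sim)
    chunks[[ci]] <- chunk
  }
  out <- purrr::list_rbind(chunks)
  if (nrow(out) == 0) stop("all designs are excluded.", call. = FALSE)
  alpha <- designs$alpha[1]
  out <- out |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$degenerate == 1 ~ "degenerate",
        .data$logrank_p < alpha &
          (.data$hr_pe < 1 | !directional) ~ "significant",
        TRUE ~ "non_significant"),
      med_fallback_C = .data$med_fallback_C == 1,
      med_fallback_T = .data$med_fallback_T == 1) |>
    dplyr::select(-"degenerate") |>
    dplyr::relocate("scenario", "subscenario", "replicate", "status") |>
    assess_benefit(table = table, tail_at = tail_at, tail_rule = tail_rule)
  # designs the replicates came from, for joins downstream
  attr(out, "designs") <- designs
  out
}

#' Read a run configuration file
#'
#' YAML key-value config with fields `scenarios` (character vector),
#' `n_sim`, `seed`, `out_dir`, and the optional toggles `tail_at`
#' (`estimated`/`design`), `tail_rule` (`absolute`/`relative`),
#' `directional` and `conditional`.
#'
#' @param path Path to the YAML file, or a named list already in memory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(scenarios = "standard", n_sim = 100L, seed = 1L,
                   out_dir = "benefitsim-results", tail_at = "estimated",
                   tail_rule = "absolute", directional = TRUE,
                   conditional = TRUE,
                   # optional grid restrictions, mainly for desk-scale runs
                   design_hr = NULL, med_c = NULL, power = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$n_sim >= 1, is.numeric(cfg$seed),
            all(cfg$scenarios %in% c("standard", "mispowered", "weibull",
                                     "gompertz", "delayed")),
            cfg$tail_at %in% c("estimated", "design"),
            cfg$tail_rule %in% c("absolute", "relative"))
  structure(cfg, class = "run_config")
}

#' Run the full study described by a configuration
#'
#' Expands, simulates, scores and summarizes every scenario in the config,
#' writing per-scenario design grids, replicate-level results, summary
#' tables, cutoff tables and a run manifest as plain CSV/YAML under the
#' config's output directory.
#'
#' @param config A [read_run_config()] list, a path to a YAML config, or a
#'   plain named list.
#' @return Invisibly, the output directory.
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec_args <- list()
  for (f in c("design_hr", "med_c", "power")) {
    if (!is.null(cfg[[f]])) spec_args[[f]] <- cfg[[f]]
  }
  for (sc in cfg$scenarios) {
    designs <- build_design_grid(
      do.call(scenario_spec, c(list(scenario = sc), spec_args)))
    reps <- run_scenario(designs, n_sim = cfg$n_sim, seed = cfg$seed,
                         tail_at = cfg$tail_at, tail_rule = cfg$tail_rule,
                         directional = cfg$directional)
    write.csv(designs, file.path(cfg$out_dir,
                                 paste0("designs_", sc, ".csv")),
              row.names = FALSE)
    write.csv(reps, file.path(cfg$out_dir,
                              paste0("replicates_", sc, ".csv")),
              row.names = FALSE)
  }
  manifest <- c(unclass(cfg),
                list(package_version = as.character(
                  utils::packageVersion("benefitsim")),
                  r_version = as.character(getRversion())))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  summarize_outputs(cfg$out_dir)
  invisible(cfg$out_dir)
}

#' Aggregate stored replicate-level results into scenario reports
#'
#' Re-reads the replicate CSVs written by [run_study()] and (re)writes the
#' scenario-level summary tables — category proportions, ASCO medians,
#' correlations — and the cutoff tables.  Idempotent: re-running without
#' re-simulating reproduces identical tables.
#'
#' @param out_dir Directory written by [run_study()].
#' @return Invisibly, the list of scenario summaries.
#' @export
summarize_outputs <- function(out_dir) {
  files <- list.files(out_dir, pattern = "^replicates_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no replicate files found in ", out_dir, call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(file.path(out_dir, "manifest.yaml")),
                  error = function(e) list(conditional = TRUE))
  conditional <- !isFALSE(cfg$conditional)
  summaries <- list()
  for (f in files) {
    sc <- sub("^replicates_(.*)\\.csv$", "\\1", basename(f))
    reps <- tibble::as_tibble(read.csv(f)) |>
      dplyr::mutate(
        iqwig_rr = factor(.data$iqwig_rr, levels = iqwig_levels,
                          ordered = TRUE),
        mod_iqwig = factor(.data$mod_iqwig, levels = iqwig_levels,
                           ordered = TRUE))
    smry <- summarize_scenario(reps, conditional = conditional)
    summaries[[sc]] <- smry
    write.csv(smry$proportions,
              file.path(out_dir, paste0("proportions_", sc, ".csv")),
              row.names = FALSE)
    write.csv(smry$asco,
              file.path(out_dir, paste0("asco_", sc, ".csv")),
              row.names = FALSE)
    write.csv(smry$correlations,
              file.path(out_dir, paste0("correlations_", sc, ".csv")),
              row.names = FALSE)
    write.csv(cutoff_table(reps),
              file.path(out_dir, paste0("cutoffs_", sc, ".csv")),
              row.names = FALSE)
  }
  invisible(summaries)
}
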
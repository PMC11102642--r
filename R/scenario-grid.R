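#' Scenario specification for a simulated benefit-assessment study
#'
#' A scenario bundles the factor grids from which the full factorial set of
#' trial designs ("subscenarios") is expanded.  The five built-in scenarios
#' share a design hazard-ratio grid of 0.30 to 0.90 in steps of 0.02 (31
#' values), control medians of 6/12/18/24/30 months, powers of 80% and 90%, a
#' two-sided 5% significance level, 24 months of uniform accrual, follow-up of
#' twice the control median, and an overall target censoring rate of 60%.
#' They differ in the failure-time family, its shape grid, and the deviation
#' factor between the design and true hazard ratio:
#'
#' * `standard`: exponential failure times, true effect equals design effect
#'   (310 subscenarios).
#' * `mispowered`: exponential, true hazard ratio is 0.8/0.9/1.1/1.2 times the
#'   design value, giving over- and underpowered trials (1,240 subscenarios).
#' * `weibull`: Weibull with shape 0.5 and 1.5 (620 subscenarios).
#' * `gompertz`: Gompertz with shape -0.2 and 0.2 (620 subscenarios; designs
#'   whose administrative censoring alone exceeds the 60% target are flagged
#'   excluded by [build_design_grid()]).
#' * `delayed`: piecewise-exponential delayed treatment effect with onset at
#'   one third of the control median (310 subscenarios).
#'
#' @param scenario One of `"standard"`, `"mispowered"`, `"weibull"`,
#'   `"gompertz"`, `"delayed"`.
#' @param design_hr Grid of design hazard ratios in (0, 1).
#' @param med_c Grid of control median survival times, months.
#' @param power Grid of target powers, fractions.
#' @param hr_var Grid of deviation factors (trueHR = designHR * hr_var).
#' @param shape Grid of family shape parameters (ignored for exponential and
#'   piecewise-delayed families).
#' @param alpha Two-sided significance level.
#' @param accrual Accrual period, months.
#' @param target_censoring Overall censoring rate the design aims for.
#' @return A list of class `scenario_spec`.
#' @examples
#' scenario_spec("standard")
#' @export
scenario_spec <- function(scenario = c("standard", "mispowered", "weibull",
                                       "gompertz", "delayed"),
                          design_hr = seq(0.30, 0.90, by = 0.02),
                          med_c = c(6, 12, 18, 24, 30),
                          power = c(0.80, 0.90),
                          hr_var = NULL,
                          shape = NULL,
                          alpha = 0.05,
                          accrual = 24,
                          target_censoring = 0.60) {
  scenario <- match.arg(scenario)
  family <- switch(scenario,
    standard = "exponential", mispowered = "exponential",
    weibull = "weibull", gompertz = "gompertz", delayed = "piecewise_delayed")
  if (is.null(hr_var)) {
    hr_var <- if (scenario == "mispowered") c(0.8, 0.9, 1.1, 1.2) else 1.0
  }
  if (is.null(shape)) {
    shape <- switch(family,
      weibull = c(0.5, 1.5), gompertz = c(-0.2, 0.2), NA_real_)
  }
  stopifnot(
    length(design_hr) >= 1, all(design_hr > 0 & design_hr < 1),
    !is.unsorted(design_hr, strictly = TRUE),
    all(med_c > 0), all(power > 0 & power < 1), all(hr_var > 0),
    alpha > 0 && alpha < 1, accrual > 0,
    target_censoring >= 0 && target_censoring < 1
  )
  structure(
    list(scenario = scenario, family = family, design_hr = design_hr,
         med_c = med_c, power = power, hr_var = hr_var, shape = shape,
         alpha = alpha, accrual = accrual,
         target_censoring = target_censoring),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$scenario, " (", x$family, ")\n", sep = "")
  cat("  designHR: ", length(x$design_hr), " values in [",
      min(x$design_hr), ", ", max(x$design_hr), "]\n", sep = "")
  cat("  med_C:", paste(x$med_c, collapse = "/"),
      " power:", paste(x$power, collapse = "/"),
      " HR_var:", paste(x$hr_var, collapse = "/"),
      " shape:", paste(x$shape, collapse = "/"), "\n")
  invisible(x)
}

#' Required number of events by Schoenfeld's formula
#'
#' Number of events needed for a two-sided log-rank test with 1:1 allocation:
#' `ceiling(4 * (z[1 - alpha/2] + z[power])^2 / log(design_hr)^2)`.
#'
#' @param design_hr Hazard ratio assumed for sizing, in (0, 1).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer number of events.
#' @examples
#' schoenfeld_events(0.7, 0.05, 0.90) # 331
#' @export
schoenfeld_events <- function(design_hr, alpha = 0.05, power = 0.90) {
  if (any(design_hr <= 0) || any(design_hr >= 1)) {
    stop("`design_hr` must lie strictly inside (0, 1); the event formula ",
         "diverges at a null effect.", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  as.integer(ceiling(4 * (qnorm(1 - alpha / 2) + qnorm(power))^2 /
                       log(design_hr)^2))
}

#' Total sample size from required events under a target censoring rate
#'
#' Inflates the event count to patients, `ceiling(events / (1 - target))`,
#' rounded up to the next even integer so that 1:1 allocation is exact.
#'
#' @param required_events Positive integer event count.
#' @param target_censoring Overall censoring fraction in `[0, 1)`.
#' @return Even integer total sample size.
#' @examples
#' sample_size_from_events(331, 0.6) # 828
#' @export
sample_size_from_events <- function(required_events, target_censoring = 0.60) {
  if (any(target_censoring >= 1) || any(target_censoring < 0)) {
    stop("`target_censoring` must lie in [0, 1).", call. = FALSE)
  }
  stopifnot(all(required_events >= 1))
  n <- ceiling(required_events / (1 - target_censoring))
  as.integer(n + n %% 2)
}

# Gauss-Legendre nodes, cached
gl_nodes <- function(n, a, b) {
  key <- paste0("gl", n)
  if (is.null(the[[key]])) the[[key]] <- pracma::gaussLegendre(n, 0, 1)
  g <- the[[key]]
  list(x = a + (b - a) * g$x, w = (b - a) * g$w)
}

# Survival function of one arm under the design assumptions (vectorised in x).
# hr = 1 gives the control arm; the treatment arm uses the design effect.
arm_survival <- function(x, family, shape, rate_c, hr, start_t = NA) {
  r <- rate_c * hr
  switch(family,
    exponential = exp(-r * x),
    weibull = exp(-r * x^shape),
    gompertz = exp(-(r / shape) * (exp(shape * x) - 1)),
    piecewise_delayed = {
      if (hr == 1) exp(-rate_c * x)
      else exp(-rate_c * pmin(x, start_t) - rate_c * hr * pmax(x - start_t, 0))
    },
    stop("unknown family: ", family, call. = FALSE))
}

# 1:1 mixture survival over both arms under the design effect
mixture_survival <- function(x, design) {
  rate_c <- rate_from_median(design$family, design$shape, design$medC)
  0.5 * arm_survival(x, design$family, design$shape, rate_c, 1,
                     design$startT) +
    0.5 * arm_survival(x, design$family, design$shape, rate_c,
                       design$designHR, design$startT)
}

#' Overall censoring probability of a design
#'
#' Probability that a patient is censored, i.e. that the failure time exceeds
#' the minimum of an independent exponential censoring time with the given
#' rate and the administrative censoring time `accrual + followup - entry`,
#' entry uniform on `[0, accrual]`.  Failure times follow the 1:1 arm mixture
#' under the design effect.  Evaluated by Gauss-Legendre quadrature over
#' entry and censoring time (split at the effect onset for the delayed
#' family, where the hazard has a kink).
#'
#' @param design A one-row design (from [build_design_grid()]) or an
#'   equivalent named list.
#' @param censor_rate Exponential censoring rate per month (>= 0).
#' @return Censoring probability in `[0, 1]`.
#' @export
censoring_probability <- function(design, censor_rate) {
  design <- as.list(design)
  stopifnot(censor_rate >= 0)
  fu <- design$followup
  outer <- gl_nodes(32, fu, fu + design$accrual) # administrative horizon tau
  p_tau <- vapply(outer$x, function(tau) {
    admin <- exp(-censor_rate * tau) * mixture_survival(tau, design)
    if (censor_rate == 0) return(admin)
    brk <- if (identical(design$family, "piecewise_delayed") &&
               is.finite(design$startT) && design$startT < tau) {
      c(0, design$startT, tau)
    } else c(0, tau)
    inner <- 0
    for (i in seq_len(length(brk) - 1)) {
      g <- gl_nodes(64, brk[i], brk[i + 1])
      inner <- inner + sum(g$w * censor_rate * exp(-censor_rate * g$x) *
                             mixture_survival(g$x, design))
    }
    admin + inner
  }, numeric(1))
  sum(outer$w * p_tau) / design$accrual
}

#' Calibrate the exponential censoring rate to the target censoring rate
#'
#' Finds the exponential censoring rate such that the design's overall
#' censoring probability ([censoring_probability()]) equals the target.  If
#' administrative censoring alone already exceeds the target, the design
#' cannot be calibrated and is marked excluded; in practice this occurs for
#' decreasing-hazard Gompertz designs with strong effects, where a fraction
#' of patients never fails during follow-up.
#'
#' @inheritParams censoring_probability
#' @return A list with `censor_rate` (0 when the administrative scheme alone
#'   attains the target; `NA` when excluded), `admin_cens` (administrative-only
#'   censoring probability), `excluded` and `exclude_reason`.
#' @export
calibrate_censor_rate <- function(design) {
  design <- as.list(design)
  target <- design$target_censoring
  admin <- censoring_probability(design, 0)
  if (admin > target + 1e-10) {
    return(list(censor_rate = NA_real_, admin_cens = admin, excluded = TRUE,
                exclude_reason = sprintf(
                  "administrative censoring alone (%.3f) exceeds target %.2f",
                  admin, target)))
  }
  if (abs(admin - target) <= 1e-10) {
    return(list(censor_rate = 0, admin_cens = admin, excluded = FALSE,
                exclude_reason = NA_character_))
  }
  f <- function(r) censoring_probability(design, r) - target
  hi <- 0.05
  for (i in 1:60) {
    if (f(hi) > 0) break
    hi <- hi * 2
  }
  if (f(hi) <= 0) {
    stop("censoring calibration failed to bracket a root (family ",
         design$family, ", medC ", design$medC, ", designHR ",
         design$designHR, ")", call. = FALSE)
  }
  root <- uniroot(f, c(0, hi), tol = 1e-12)
  list(censor_rate = root$root, admin_cens = admin, excluded = FALSE,
       exclude_reason = NA_character_)
}

#' Expand a scenario into its full factorial design grid
#'
#' Builds one row per subscenario: the factorial combination of design hazard
#' ratio, control median, power, deviation factor and shape, with Schoenfeld
#' event counts, total sample sizes inflated for 60% censoring, follow-up of
#' twice the control median, the calibrated exponential censoring rate, and
#' the exclusion flag for designs whose administrative censoring alone
#' exceeds the target.  Excluded designs are retained in the grid but
#' flagged; [run_scenario()] skips them.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with one row per subscenario, ordered by shape, control
#'   median, power, deviation factor and design hazard ratio.
#' @examples
#' grid <- build_design_grid(scenario_spec("standard"))
#' nrow(grid) # 310
#' @export
build_design_grid <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- tidyr::expand_grid(
    shape = spec$shape, medC = spec$med_c, power = spec$power,
    HR_var = spec$hr_var, designHR = spec$design_hr)
  if (nrow(grid) == 0) stop("empty design grid", call. = FALSE)
  grid <- grid |>
    dplyr::mutate(
      scenario = spec$scenario,
      family = spec$family,
      trueHR = .data$designHR * .data$HR_var,
      alpha = spec$alpha,
      accrual = spec$accrual,
      followup = 2 * .data$medC,
      startT = if (spec$family == "piecewise_delayed") .data$medC / 3 else
        NA_real_,
      target_censoring = spec$target_censoring,
      required_events = schoenfeld_events(.data$designHR, spec$alpha,
                                          .data$power),
      n_total = sample_size_from_events(.data$required_events,
                                        spec$target_censoring))

  # censoring calibration depends only on (family, shape, medC, designHR)
  cal_keys <- dplyr::distinct(grid, .data$family, .data$shape, .data$medC,
                              .data$designHR, .data$accrual, .data$followup,
                              .data$startT, .data$target_censoring)
  cal <- purrr::pmap(cal_keys, function(...) calibrate_censor_rate(list(...)))
  cal_keys$censor_rate <- purrr::map_dbl(cal, "censor_rate")
  cal_keys$admin_cens <- purrr::map_dbl(cal, "admin_cens")
  cal_keys$excluded <- purrr::map_lgl(cal, "excluded")
  cal_keys$exclude_reason <- purrr::map_chr(cal, "exclude_reason")

  grid |>
    dplyr::left_join(cal_keys,
                     by = c("family", "shape", "medC", "designHR", "accrual",
                            "followup", "startT", "target_censoring")) |>
    dplyr::mutate(subscenario = sprintf("%s_%04d", .data$scenario,
                                        dplyr::row_number())) |>
    dplyr::select("scenario", "subscenario", "family", "shape", "designHR",
                  "HR_var", "trueHR", "medC", "power", "alpha", "accrual",
                  "followup", "startT", "target_censoring", "required_events",
                  "n_total", "censor_rate", "admin_cens", "excluded",
                  "exclude_reason")
}
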
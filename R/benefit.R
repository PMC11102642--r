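#' Convert a relative-risk threshold to the hazard-ratio scale
#'
#' Numerically inverts VanderWeele's approximate conversion
#' `RR(HR) = (1 - 0.5^sqrt(HR)) / (1 - 0.5^(1/sqrt(HR)))` by root search, so
#' that IQWiG's relative-risk-scaled category thresholds (0.85, 0.95) can be
#' restated on the hazard-ratio scale (0.79, 0.93) for the modified IQWiG
#' rule.
#'
#' @param rr Relative-risk threshold in (0, 1].
#' @param digits Decimals to round the root to (2 matches the published
#'   thresholds); `NA` for the unrounded root.
#' @return Hazard-ratio threshold.
#' @examples
#' vanderweele_rr_to_hr(0.85) # 0.79
#' vanderweele_rr_to_hr(0.95) # 0.93
#' @export
vanderweele_rr_to_hr <- function(rr, digits = 2) {
  stopifnot(all(rr > 0), all(rr <= 1))
  hr <- vapply(rr, function(r) {
    if (r == 1) return(1)
    f <- function(h) vanderweele_hr_to_rr(h) - r
    if (f(1e-12) > 0) stop("no root in (0, 1] for rr = ", r, call. = FALSE)
    uniroot(f, c(1e-12, 1), tol = 1e-10)$root
  }, numeric(1))
  if (is.na(digits)) hr else round(hr, digits)
}

#' @rdname vanderweele_rr_to_hr
#' @param hr Hazard ratio in (0, 1].
#' @export
vanderweele_hr_to_rr <- function(hr) {
  stopifnot(all(hr > 0), all(hr <= 1))
  ifelse(hr == 1, 1, (1 - 0.5^sqrt(hr)) / (1 - 0.5^(1 / sqrt(hr))))
}

# Mod-IQWiG thresholds on the HR scale, fixed at the two-decimal published
# values (equal to vanderweele_rr_to_hr(c(0.85, 0.95)))
mod_iqwig_thresholds <- function() c(0.79, 0.93)

asco_vec <- function(hr_pe, s2med_c, s2med_t,
                     tail_rule = c("absolute", "relative")) {
  tail_rule <- match.arg(tail_rule)
  improved <- if (tail_rule == "absolute") {
    s2med_t - s2med_c >= 0.50
  } else {
    s2med_t >= 1.5 * s2med_c
  }
  tail <- !is.na(s2med_c) & !is.na(s2med_t) & s2med_c > 0.20 & improved
  list(score = 100 * (1 - hr_pe) + 20 * tail, tail = tail)
}

#' ASCO net-health-benefit score (clinical benefit plus tail-of-curve bonus)
#'
#' The clinical-benefit part is `100 * (1 - hr_pe)`.  The 20-point
#' tail-of-curve bonus is granted when, at twice the estimated control
#' median ("tail of the curve"), more than 20% of the control arm survives
#' and the proportion alive under treatment has improved by 50% or more.
#' The improvement criterion is ambiguous in the published wording and both
#' readings are implemented: `"absolute"` (the default) requires an
#' improvement of 50 percentage points, under which the bonus is rare in
#' proportional-hazards scenarios and the pooled score medians match the
#' published ones; `"relative"` requires treatment-arm survival of at least
#' 1.5 times the control-arm survival, under which the bonus fires for
#' roughly every hazard ratio below 0.71 with exponential failure times.
#'
#' @param est One-row trial estimates from [summarize_trial()] (needs
#'   `hr_pe`, `s2med_C`, `s2med_T`).
#' @param tail_rule `"absolute"` (>= 50 percentage points) or `"relative"`
#'   (>= 1.5-fold).
#' @return One-row tibble with `asco` (score) and `asco_tail` (logical).
#' @examples
#' asco_nhb_score(tibble::tibble(hr_pe = 0.59, s2med_C = 0.1, s2med_T = 0.1))
#' @export
asco_nhb_score <- function(est, tail_rule = c("absolute", "relative")) {
  a <- asco_vec(est$hr_pe, est$s2med_C, est$s2med_T, tail_rule)
  tibble::tibble(asco = a$score, asco_tail = a$tail)
}

iqwig_levels <- c("minor", "considerable", "major")

iqwig_vec <- function(hr_hi, thresholds) {
  factor(ifelse(hr_hi < thresholds[1], "major",
                ifelse(hr_hi < thresholds[2], "considerable", "minor")),
         levels = iqwig_levels, ordered = TRUE)
}

#' IQWiG added-benefit category from the upper confidence limit
#'
#' `major` when the upper 95% confidence limit of the hazard ratio is below
#' the first threshold, `considerable` when below the second, `minor`
#' otherwise.  The original rule compares against the relative-risk-scaled
#' thresholds (0.85, 0.95); the modified rule uses the hazard-ratio-scaled
#' thresholds (0.79, 0.93) from [vanderweele_rr_to_hr()].
#'
#' @param hr_hi Upper 95% confidence limit(s) of the hazard ratio.
#' @param thresholds Increasing pair of category thresholds.
#' @return Ordered factor `minor < considerable < major`.
#' @examples
#' iqwig_category(c(0.84, 0.85, 0.96))
#' @export
iqwig_category <- function(hr_hi, thresholds = c(0.85, 0.95)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2],
            all(hr_hi > 0))
  iqwig_vec(hr_hi, thresholds)
}

#' ESMO grading thresholds for overall survival in advanced disease
#'
#' The dual-rule threshold table: per control-median band, the lower
#' confidence limit ceiling and minimum gain in median survival required for
#' each grade, plus the milestone (2-year survival for a control median of
#' up to 12 months, 3-year survival beyond) at which an absolute survival
#' increase of at least 10 percentage points grants the maximal grade on
#' its own.  Shipped as a plain-text config file
#' (`inst/extdata/esmo-thresholds-os-advanced.csv`) so the transcription is
#' explicit and swappable via the `file` argument.
#'
#' @param file Path to an alternative threshold table.
#' @return Tibble with columns `band`, `medc_min`, `medc_max`, `grade`,
#'   `hr_lo_max`, `gain_min`, `milestone_months`, `milestone_increase_min`.
#' @export
esmo_thresholds <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(the$esmo)) return(the$esmo)
    file <- system.file("extdata", "esmo-thresholds-os-advanced.csv",
                        package = "benefitsim", mustWork = TRUE)
    the$esmo <- tibble::as_tibble(read.csv(file))
    return(the$esmo)
  }
  tibble::as_tibble(read.csv(file))
}

esmo_vec <- function(hr_lo, gain, med_c, s24_c, s24_t, s36_c, s36_t,
                     table = esmo_thresholds()) {
  grade <- rep(1L, length(hr_lo))
  for (r in seq_len(nrow(table))) {
    row <- table[r, ]
    in_band <- med_c > row$medc_min & med_c <= row$medc_max
    ok <- in_band & hr_lo <= row$hr_lo_max & gain >= row$gain_min
    if (!is.na(row$milestone_months)) {
      inc <- if (row$milestone_months <= 24) s24_t - s24_c else s36_t - s36_c
      ok <- ok | (in_band & !is.na(inc) & inc >= row$milestone_increase_min)
    }
    ok[is.na(ok)] <- FALSE
    grade[ok] <- pmax(grade[ok], row$grade)
  }
  grade[is.na(hr_lo)] <- NA_integer_
  as.integer(grade)
}

#' ESMO magnitude-of-clinical-benefit grade (overall survival, grades 1-4)
#'
#' Dual rule on the lower 95% confidence limit of the hazard ratio and the
#' absolute gain in median survival, with thresholds depending on the
#' control-median band; an absolute increase of at least 10 percentage
#' points in the band's milestone survival rate grants grade 4 regardless of
#' the other criteria.  The grade is the maximum implied by any satisfied
#' rule.
#'
#' @param est One-row trial estimates from [summarize_trial()] (needs
#'   `hr_lo`, `gain`, `med_hat_C` and the milestone survival columns).
#' @param table Threshold table, see [esmo_thresholds()].
#' @return Integer grade in 1-4.
#' @export
esmo_grade <- function(est, table = esmo_thresholds()) {
  esmo_vec(est$hr_lo, est$gain, est$med_hat_C, est$s24_C, est$s24_T,
           est$s36_C, est$s36_T, table)
}

#' Score trial estimates with all four benefit-assessment rules
#'
#' Adds the ASCO net-health-benefit score (with tail-of-curve flag), the
#' IQWiG and modified-IQWiG categories, and the ESMO grade to a tibble of
#' per-trial estimates.
#'
#' @param estimates Tibble of trial estimates, one row per trial
#'   (from [summarize_trial()] or [run_scenario()]).
#' @param table ESMO threshold table, see [esmo_thresholds()].
#' @param tail_at Evaluate the ASCO tail-of-curve bonus at twice the
#'   `"estimated"` (default) or twice the `"design"` control median.
#' @param tail_rule Tail-of-curve improvement reading, see
#'   [asco_nhb_score()].
#' @return `estimates` with columns `asco`, `asco_tail`, `iqwig_rr`,
#'   `mod_iqwig`, `esmo` appended.
#' @export
assess_benefit <- function(estimates, table = esmo_thresholds(),
                           tail_at = c("estimated", "design"),
                           tail_rule = c("absolute", "relative")) {
  tail_at <- match.arg(tail_at)
  s_c <- if (tail_at == "estimated") estimates$s2med_C else
    estimates$s2med_design_C
  s_t <- if (tail_at == "estimated") estimates$s2med_T else
    estimates$s2med_design_T
  a <- asco_vec(estimates$hr_pe, s_c, s_t, tail_rule)
  estimates |>
    dplyr::mutate(
      asco = a$score,
      asco_tail = a$tail,
      iqwig_rr = iqwig_vec(.data$hr_hi, c(0.85, 0.95)),
      mod_iqwig = iqwig_vec(.data$hr_hi, mod_iqwig_thresholds()),
      esmo = esmo_vec(.data$hr_lo, .data$gain, .data$med_hat_C, .data$s24_C,
                      .data$s24_T, .data$s36_C, .data$s36_T, table))
}
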
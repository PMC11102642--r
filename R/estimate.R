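# Lean Kaplan-Meier and log-rank internals.  These are the textbook
# estimators computed with cumsum/cumprod so that a six-figure number of
# simulated trials reduces in minutes; the test suite asserts exact agreement
# with survival::survfit / survival::survdiff on tied and untied data.

# Kaplan-Meier curve of one arm: distinct observed times, survival, last time
km_fit <- function(time, event) {
  ord <- order(time)
  t <- time[ord]
  e <- event[ord]
  n <- length(t)
  if (anyDuplicated(t) == 0L) {
    ut <- t
    nrisk <- n:1
    d <- e
  } else {
    first <- !duplicated(t)
    ut <- t[first]
    nrisk <- n - which(first) + 1L
    d <- as.vector(rowsum(e, cumsum(first)))
  }
  list(time = ut, surv = cumprod(1 - d / nrisk), last = t[n])
}

# step-function evaluation (right-continuous), carrying the last value
km_eval <- function(fit, t0) {
  idx <- findInterval(t0, fit$time)
  ifelse(idx == 0L, 1, fit$surv[pmax(idx, 1L)])
}

# first time the curve drops to <= 0.5; last observed time as fallback
km_median <- function(fit) {
  i <- which(fit$surv <= 0.5 + 1e-9)
  if (length(i) == 0L) {
    c(median = fit$last, fallback = 1)
  } else {
    c(median = fit$time[i[1L]], fallback = 0)
  }
}

# two-sample log-rank statistic; returns c(chisq, p); p is NA when the
# variance is zero (degenerate trial)
logrank_stat <- function(time, event, arm) {
  ord <- order(time)
  t <- time[ord]
  e <- event[ord]
  a <- arm[ord]
  n <- length(t)
  n1 <- sum(a)
  cum1 <- cumsum(a)
  if (anyDuplicated(t) == 0L) {
    nrisk <- n:1
    n1risk <- n1 - c(0, cum1[-n])
    d <- e
    d1 <- e * a
  } else {
    first <- !duplicated(t)
    idx <- which(first)
    nrisk <- n - idx + 1L
    n1risk <- n1 - c(0, cum1)[idx]
    gid <- cumsum(first)
    d <- as.vector(rowsum(e, gid))
    d1 <- as.vector(rowsum(e * a, gid))
  }
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]
  nrisk <- nrisk[keep]; n1risk <- n1risk[keep]
  p1 <- n1risk / nrisk
  o_minus_e <- sum(d1) - sum(d * p1)
  v <- sum(ifelse(nrisk > 1,
                  d * p1 * (1 - p1) * (nrisk - d) / (nrisk - 1), 0))
  if (v <= 0) return(c(chisq = NA_real_, p = NA_real_))
  chisq <- o_minus_e^2 / v
  c(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Cox fit with a single arm indicator via survival's fitting engine
# (Efron ties).  Returns c(beta, se) or NULL when degenerate.
cox_fit_arm <- function(time, event, arm) {
  # monotone-likelihood warnings (tiny event counts, huge effects) are
  # expected in bulk simulation; the finite-estimate check below governs
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(matrix(as.double(arm), ncol = 1),
                          survival::Surv(time, event),
                          strata = NULL, offset = NULL, init = 0,
                          control = survival::coxph.control(),
                          weights = NULL, method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  beta <- as.double(fit$coefficients[1])
  se <- sqrt(as.double(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se <= 0) return(NULL)
  c(beta = beta, se = se)
}

est_names <- c(
  "hr_pe", "hr_lo", "hr_hi", "logrank_p", "med_hat_C", "med_hat_T",
  "med_fallback_C", "med_fallback_T", "gain",
  "s24_C", "s24_T", "s36_C", "s36_T", "s60_C", "s60_T",
  "s2med_C", "s2med_T", "s2med_design_C", "s2med_design_T", "cens_frac",
  "degenerate")

# one simulated trial -> named numeric vector of summary statistics
reduce_trial <- function(time, event, arm, design, level = 0.95) {
  out <- setNames(rep(NA_real_, length(est_names)), est_names)
  out["cens_frac"] <- 1 - mean(event)
  ctrl <- arm == 0L
  if (sum(event[ctrl]) == 0L || sum(event[!ctrl]) == 0L) {
    out["degenerate"] <- 1
    return(out)
  }
  cx <- cox_fit_arm(time, event, arm)
  lr <- logrank_stat(time, event, arm)
  if (is.null(cx) || !is.finite(lr["p"])) {
    out["degenerate"] <- 1
    return(out)
  }
  z <- qnorm(1 - (1 - level) / 2)
  out["hr_pe"] <- exp(cx["beta"])
  out["hr_lo"] <- exp(cx["beta"] - z * cx["se"])
  out["hr_hi"] <- exp(cx["beta"] + z * cx["se"])
  out["logrank_p"] <- lr["p"]

  km_c <- km_fit(time[ctrl], event[ctrl])
  km_t <- km_fit(time[!ctrl], event[!ctrl])
  mc <- km_median(km_c)
  mt <- km_median(km_t)
  out["med_hat_C"] <- mc["median"]
  out["med_hat_T"] <- mt["median"]
  out["med_fallback_C"] <- mc["fallback"]
  out["med_fallback_T"] <- mt["fallback"]
  out["gain"] <- mt["median"] - mc["median"]

  ms <- c(24, 36, 60)
  out[c("s24_C", "s36_C", "s60_C")] <- km_eval(km_c, ms)
  out[c("s24_T", "s36_T", "s60_T")] <- km_eval(km_t, ms)
  out["s2med_C"] <- km_eval(km_c, 2 * mc["median"])
  out["s2med_T"] <- km_eval(km_t, 2 * mc["median"])
  out["s2med_design_C"] <- km_eval(km_c, 2 * design$medC)
  out["s2med_design_T"] <- km_eval(km_t, 2 * design$medC)
  out["degenerate"] <- 0
  out
}

trial_arm01 <- function(trial) {
  as.integer(trial$arm == "treatment" | trial$arm == 1 | trial$arm == TRUE)
}

#' Two-sided log-rank p-value of a simulated trial
#'
#' @param trial Patient-level data with columns `arm`, `time`, `event`
#'   (as returned by [simulate_trial()]).
#' @return Two-sided p-value.
#' @export
logrank_p <- function(trial) {
  arm <- trial_arm01(trial)
  if (sum(trial$event[arm == 0L]) == 0L || sum(trial$event[arm == 1L]) == 0L) {
    stop("degenerate trial: an arm has no events.", call. = FALSE)
  }
  p <- logrank_stat(trial$time, as.integer(trial$event), arm)[["p"]]
  if (!is.finite(p)) stop("degenerate trial: zero log-rank variance.",
                          call. = FALSE)
  p
}

#' Hazard-ratio point estimate and Wald confidence interval
#'
#' Fits a proportional-hazards regression with the single treatment
#' indicator (Efron tie handling) and returns the exponentiated coefficient
#' with its Wald interval.
#'
#' @inheritParams logrank_p
#' @param level Confidence level.
#' @return One-row tibble with `hr_pe`, `hr_lo`, `hr_hi`.
#' @export
cox_hr_ci <- function(trial, level = 0.95) {
  stopifnot(level > 0, level < 1)
  arm <- trial_arm01(trial)
  if (sum(trial$event[arm == 0L]) == 0L || sum(trial$event[arm == 1L]) == 0L) {
    stop("degenerate trial: an arm has no events.", call. = FALSE)
  }
  cx <- cox_fit_arm(trial$time, as.integer(trial$event), arm)
  if (is.null(cx)) stop("proportional-hazards fit did not converge.",
                        call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(hr_pe = exp(cx[["beta"]]),
                 hr_lo = exp(cx[["beta"]] - z * cx[["se"]]),
                 hr_hi = exp(cx[["beta"]] + z * cx[["se"]]))
}

#' Kaplan-Meier median with conservative fallback
#'
#' The median is the first time the Kaplan-Meier curve drops to 0.5 or
#' below.  When the curve never reaches 0.5 (large effects, heavy
#' censoring), the last observed event or censoring time of the arm is
#' returned instead and flagged.
#'
#' @inheritParams logrank_p
#' @param arm `"control"` or `"treatment"`.
#' @return One-row tibble with `median` (months) and `fallback` (logical).
#' @export
km_median_fallback <- function(trial, arm = c("control", "treatment")) {
  arm <- match.arg(arm)
  sel <- trial_arm01(trial) == (arm == "treatment")
  if (!any(sel)) stop("empty arm.", call. = FALSE)
  m <- km_median(km_fit(trial$time[sel], as.integer(trial$event[sel])))
  tibble::tibble(median = unname(m["median"]), fallback = m["fallback"] == 1)
}

#' Kaplan-Meier survival fraction at given times
#'
#' Evaluates the arm's Kaplan-Meier step function; beyond the arm's last
#' observed time the last value is carried forward and flagged as
#' extrapolated.
#'
#' @inheritParams km_median_fallback
#' @param t Times in months (> 0), vectorised.
#' @return Tibble with one row per time: `time`, `surv`, `extrapolated`.
#' @export
km_survival_at <- function(trial, arm = c("control", "treatment"), t) {
  arm <- match.arg(arm)
  stopifnot(all(t > 0))
  sel <- trial_arm01(trial) == (arm == "treatment")
  if (!any(sel)) stop("empty arm.", call. = FALSE)
  fit <- km_fit(trial$time[sel], as.integer(trial$event[sel]))
  tibble::tibble(time = t, surv = km_eval(fit, t), extrapolated = t > fit$last)
}

#' Reduce a simulated trial to the statistics the scoring rules need
#'
#' Bundles the log-rank p-value, the hazard-ratio point and Wald interval
#' estimates, arm medians with the conservative fallback, the gain in median
#' survival, and Kaplan-Meier survival at the 2-, 3- and 5-year milestones
#' and at twice the (estimated and design) control median.  A trial counts
#' as significant when the log-rank p-value is below `alpha` and the hazard
#' ratio points in the favorable direction (`hr_pe < 1`).
#'
#' @inheritParams logrank_p
#' @param design The design row the trial was simulated under.
#' @param alpha Two-sided significance level for the log-rank gate.
#' @param level Confidence level of the Wald interval.
#' @return One-row tibble of estimates; degenerate trials (an arm without
#'   events, or a failed fit) carry `status = "degenerate"` and `NA`
#'   estimates.
#' @export
summarize_trial <- function(trial, design, alpha = 0.05, level = 0.95) {
  design <- as.list(design)
  est <- reduce_trial(trial$time, as.integer(trial$event), trial_arm01(trial),
                      design, level = level)
  out <- tibble::as_tibble(as.list(est))
  out$med_fallback_C <- out$med_fallback_C == 1
  out$med_fallback_T <- out$med_fallback_T == 1
  out$status <- dplyr::case_when(
    est["degenerate"] == 1 ~ "degenerate",
    est["logrank_p"] < alpha & est["hr_pe"] < 1 ~ "significant",
    TRUE ~ "non_significant")
  out$significant <- out$status == "significant"
  dplyr::select(out, -"degenerate")
}
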
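#' Rate parameter fixing the median of a failure-time distribution
#'
#' Returns the control-arm rate such that survival equals 0.5 at the given
#' median: exponential `log(2)/m`; Weibull (hazard `rate * k * t^(k-1)`)
#' `log(2)/m^k`; Gompertz (hazard `rate * exp(shape * t)`)
#' `shape * log(2) / (exp(shape * m) - 1)`.  The piecewise-delayed family
#' uses the exponential control rate.  Under proportional hazards the
#' treatment-arm rate is the true hazard ratio times the control rate.
#'
#' @param family `"exponential"`, `"weibull"`, `"gompertz"` or
#'   `"piecewise_delayed"`.
#' @param shape Shape parameter (Weibull `k` > 0 or Gompertz `b` != 0);
#'   ignored otherwise.
#' @param median Median survival, months (> 0).
#' @return Rate per month.
#' @examples
#' rate_from_median("exponential", NA, 12) # log(2)/12
#' @export
rate_from_median <- function(family, shape, median) {
  if (any(median <= 0)) stop("`median` must be positive.", call. = FALSE)
  switch(family,
    exponential = ,
    piecewise_delayed = log(2) / median,
    weibull = {
      stopifnot(shape > 0)
      log(2) / median^shape
    },
    gompertz = {
      stopifnot(shape != 0)
      shape * log(2) / (exp(shape * median) - 1)
    },
    stop("unknown family: ", family, call. = FALSE))
}

# Failure-time draws for one arm. `hr` is the proportional-hazards multiplier
# applied to the control rate (1 for the control arm).  For the delayed
# family the treatment hazard equals the control hazard before the onset and
# hr times it afterwards; draws invert the piecewise cumulative hazard.
# Gompertz with negative shape has a cure fraction: such draws are +Inf and
# end up administratively censored.
r_failure <- function(n, family, shape, rate_c, hr, start_t = NA) {
  switch(family,
    exponential = rexp(n, rate_c * hr),
    weibull = rweibull(n, shape = shape, scale = (rate_c * hr)^(-1 / shape)),
    gompertz = flexsurv::rgompertz(n, shape = shape, rate = rate_c * hr),
    piecewise_delayed = {
      if (hr == 1) {
        rexp(n, rate_c)
      } else {
        h <- rexp(n) # cumulative hazard at the failure time
        h0 <- rate_c * start_t
        ifelse(h <= h0, h / rate_c, start_t + (h - h0) / (rate_c * hr))
      }
    },
    stop("unknown family: ", family, call. = FALSE))
}

#' Draw failure times for one arm of a design
#'
#' @param design One design row (list or one-row data frame) from
#'   [build_design_grid()].
#' @param arm `"control"` or `"treatment"`.
#' @param n Number of draws.
#' @return Numeric vector of failure times in months (possibly `Inf` for the
#'   Gompertz cure fraction).
#' @export
sample_failure_times <- function(design, arm = c("control", "treatment"), n) {
  design <- as.list(design)
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  rate_c <- rate_from_median(design$family, design$shape, design$medC)
  hr <- if (arm == "control") 1 else design$trueHR
  r_failure(n, design$family, design$shape, rate_c, hr, design$startT)
}

#' Draw censoring times for a design
#'
#' Per patient the censoring time is the minimum of an exponential draw with
#' the design's calibrated rate and the administrative censoring time
#' `accrual + followup - entry`, with entry uniform on `[0, accrual]`.
#'
#' @inheritParams sample_failure_times
#' @return Numeric vector of censoring times, months.
#' @export
sample_censoring <- function(design, n) {
  design <- as.list(design)
  if (isTRUE(design$excluded)) {
    stop("design is excluded (", design$exclude_reason,
         "); refusing to simulate.", call. = FALSE)
  }
  stopifnot(n >= 1, !is.null(design$censor_rate), !is.na(design$censor_rate))
  admin <- design$accrual + design$followup - runif(n, 0, design$accrual)
  if (design$censor_rate > 0) {
    pmin(rexp(n, design$censor_rate), admin)
  } else {
    admin
  }
}

# fast internal path: plain vectors, no tibble
sim_trial_raw <- function(design) {
  n2 <- design$n_total %/% 2L
  rate_c <- rate_from_median(design$family, design$shape, design$medC)
  fail <- c(
    r_failure(n2, design$family, design$shape, rate_c, 1, design$startT),
    r_failure(n2, design$family, design$shape, rate_c, design$trueHR,
              design$startT))
  cens <- sample_censoring(design, 2L * n2)
  list(arm = rep(0:1, each = n2),
       time = pmin(fail, cens),
       event = as.integer(fail <= cens))
}

#' Simulate one phase-III trial under a design
#'
#' Draws failure and censoring times for `n_total` patients (1:1 allocation)
#' and returns the observed patient-level data.
#'
#' @inheritParams sample_failure_times
#' @param seed Optional integer seed for a reproducible single trial.
#' @return A tibble with columns `arm` (factor control/treatment), `time`
#'   (observed months) and `event` (`TRUE` if death observed).
#' @examples
#' design <- build_design_grid(scenario_spec("standard"))[101, ]
#' trial <- simulate_trial(design, seed = 1)
#' @export
simulate_trial <- function(design, seed = NULL) {
  design <- as.list(design)
  if (isTRUE(design$excluded)) {
    stop("design is excluded (", design$exclude_reason,
         "); refusing to simulate.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  raw <- sim_trial_raw(design)
  tibble::tibble(
    arm = factor(ifelse(raw$arm == 0, "control", "treatment"),
                 levels = c("control", "treatment")),
    time = raw$time,
    event = raw$event == 1L)
}
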
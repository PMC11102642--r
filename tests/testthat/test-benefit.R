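test_that("VanderWeele conversion reproduces the published thresholds", {
  expect_equal(vanderweele_rr_to_hr(0.85), 0.79)
  expect_equal(vanderweele_rr_to_hr(0.95), 0.93)
  expect_equal(vanderweele_rr_to_hr(1.0), 1.0)
  # round trip without rounding
  hr <- vanderweele_rr_to_hr(0.85, digits = NA)
  expect_equal(vanderweele_hr_to_rr(hr), 0.85, tolerance = 1e-8)
  expect_error(vanderweele_rr_to_hr(1.2))
})

test_that("ASCO score is the clinical benefit plus tail bonus", {
  no_tail <- tibble::tibble(hr_pe = 0.59, s2med_C = 0.10, s2med_T = 0.12)
  expect_equal(asco_nhb_score(no_tail)$asco, 41)
  expect_false(asco_nhb_score(no_tail)$asco_tail)
  null <- tibble::tibble(hr_pe = 1.0, s2med_C = 0.1, s2med_T = 0.1)
  expect_equal(asco_nhb_score(null)$asco, 0)
  # relative reading: 0.40 / 0.25 = 1.6 >= 1.5 with control floor cleared
  rel <- tibble::tibble(hr_pe = 0.30, s2med_C = 0.25, s2med_T = 0.40)
  expect_equal(asco_nhb_score(rel, tail_rule = "relative")$asco, 90)
  # absolute reading: +0.15 < 0.50 percentage points, no bonus
  expect_equal(asco_nhb_score(rel, tail_rule = "absolute")$asco, 70)
  abs_hit <- tibble::tibble(hr_pe = 0.30, s2med_C = 0.25, s2med_T = 0.80)
  expect_equal(asco_nhb_score(abs_hit, tail_rule = "absolute")$asco, 90)
  # control floor: 20% surviving is not enough even with a huge improvement
  floor <- tibble::tibble(hr_pe = 0.30, s2med_C = 0.20, s2med_T = 0.90)
  expect_equal(asco_nhb_score(floor)$asco, 70)
  # strictly decreasing in hr_pe at fixed tail flag
  hrs <- seq(0.2, 1.2, by = 0.1)
  sc <- asco_nhb_score(tibble::tibble(hr_pe = hrs, s2med_C = 0.1,
                                      s2med_T = 0.1))$asco
  expect_true(all(diff(sc) < 0))
})

test_that("IQWiG categories follow the half-open threshold intervals", {
  expect_identical(as.character(iqwig_category(0.84)), "major")
  expect_identical(as.character(iqwig_category(0.85)), "considerable")
  expect_identical(as.character(iqwig_category(0.9499)), "considerable")
  expect_identical(as.character(iqwig_category(0.95)), "minor")
  expect_identical(as.character(iqwig_category(0.96)), "minor")
  # modified thresholds are exactly the converted pair
  expect_identical(as.character(iqwig_category(0.78, c(0.79, 0.93))), "major")
  expect_identical(as.character(iqwig_category(0.79, c(0.79, 0.93))),
                   "considerable")
  expect_identical(as.character(iqwig_category(0.93, c(0.79, 0.93))), "minor")
  # monotone: a smaller upper limit never lowers the category
  u <- sort(runif(50, 0.5, 1.2), decreasing = TRUE)
  cats <- as.integer(iqwig_category(u))
  expect_true(all(diff(cats) >= 0))
})

test_that("ESMO grading follows the dual rule with milestone upgrade", {
  base <- tibble::tibble(
    hr_lo = 0.99, gain = 0.2, med_hat_C = 10,
    s24_C = 0.2, s24_T = 0.2, s36_C = 0.1, s36_T = 0.1)
  expect_identical(esmo_grade(base), 1L)
  # milestone increase >= 10 percentage points grants grade 4 on its own
  ms <- base
  ms$s24_T <- ms$s24_C + 0.12
  expect_identical(esmo_grade(ms), 4L)
  # a grade-4 joint rule in the short band
  g4 <- tibble::tibble(hr_lo = 0.60, gain = 3.5, med_hat_C = 10,
                       s24_C = 0.2, s24_T = 0.2, s36_C = 0, s36_T = 0)
  expect_identical(esmo_grade(g4), 4L)
  # same estimates, long band: gain 3.5 < 5 with no milestone -> grade 3
  g3 <- g4
  g3$med_hat_C <- 20
  expect_identical(esmo_grade(g3), 3L)
  # band-specific milestone: 3-year survival governs the long band
  g4l <- g3
  g4l$s36_C <- 0.2
  g4l$s36_T <- 0.31
  expect_identical(esmo_grade(g4l), 4L)
})

test_that("ESMO grade is monotone in each direction of benefit", {
  set.seed(55)
  table <- esmo_thresholds()
  for (i in 1:200) {
    est <- tibble::tibble(
      hr_lo = runif(1, 0.4, 1.1), gain = runif(1, 0, 8),
      med_hat_C = sample(c(6, 10, 14, 20, 30), 1),
      s24_C = runif(1, 0, 0.6), s36_C = runif(1, 0, 0.5))
    est$s24_T <- est$s24_C + runif(1, 0, 0.3)
    est$s36_T <- est$s36_C + runif(1, 0, 0.3)
    g <- esmo_grade(est, table)
    better <- est
    better$hr_lo <- est$hr_lo - 0.05
    better$gain <- est$gain + 0.5
    better$s24_T <- est$s24_T + 0.02
    better$s36_T <- est$s36_T + 0.02
    expect_gte(esmo_grade(better, table), g)
  }
})

test_that("threshold table is well-formed and monotone across grades", {
  tab <- esmo_thresholds()
  expect_true(all(c("band", "grade", "hr_lo_max", "gain_min") %in%
                    names(tab)))
  for (b in unique(tab$band)) {
    sub <- tab[tab$band == b, ]
    sub <- sub[order(sub$grade), ]
    # higher grades never have weaker requirements
    expect_true(all(diff(sub$hr_lo_max) <= 0))
    expect_true(all(diff(sub$gain_min) >= 0))
  }
})

test_that("assess_benefit scores a whole estimates table consistently", {
  reps <- scaled_run("standard")
  pool <- significant_pool(reps)
  expect_equal(pool$asco,
               100 * (1 - pool$hr_pe) + 20 * pool$asco_tail)
  expect_true(all(!is.na(pool$esmo)))
  i <- sample(nrow(pool), 50)
  expect_identical(esmo_grade(pool[i, ]), pool$esmo[i])
  expect_identical(iqwig_category(pool$hr_hi[i]), pool$iqwig_rr[i])
  expect_identical(iqwig_category(pool$hr_hi[i], c(0.79, 0.93)),
                   pool$mod_iqwig[i])
})
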
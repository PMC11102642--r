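test_that("rank correlations handle ties and degenerate input", {
  expect_equal(spearman_rho(1:10, rep(1:5, each = 2)), cor(
    1:10, rep(1:5, each = 2), method = "spearman"))
  expect_equal(spearman_rho(1:4, c(1, 1, 2, 2)), 0.8944272, tolerance = 1e-6)
  expect_equal(spearman_rho(sort(runif(20)), 1:20), 1.0)
  expect_true(is.na(spearman_rho(1:10, rep(2, 10))))
  expect_error(spearman_rho(1:3, 1:4), "length")

  expect_equal(kendall_tau_b(sort(runif(15)), 1:15), 1.0)
  expect_true(is.na(kendall_tau_b(1:10, rep(1, 10))))
  # brute-force tau-b oracle on a small tied instance
  set.seed(66)
  x <- sample(1:6, 25, TRUE)
  y <- sample(1:3, 25, TRUE)
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    conc <- conc + (s > 0)
    disc <- disc + (s < 0)
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), choose, k = 2))
  ty <- sum(sapply(table(y), choose, k = 2))
  tau_oracle <- (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  expect_equal(kendall_tau_b(x, y), tau_oracle, tolerance = 1e-12)
})

test_that("weighted kappa matches a direct evaluation and its fixed points", {
  expect_equal(weighted_kappa(diag(c(5, 3, 2))), 1.0)
  # exact independence: observed = outer product of margins
  m <- outer(c(10, 20, 10), c(5, 10, 25))
  expect_equal(weighted_kappa(m), 0.0)
  # worked 3x3 matrix, frozen from a spreadsheet-style evaluation of
  # 1 - sum(w*x)/sum(w*m) with quadratic weights
  conf <- rbind(c(20, 5, 1), c(4, 30, 6), c(2, 3, 29))
  expect_equal(weighted_kappa(conf), 0.7508306, tolerance = 1e-6)
  # both raters constant -> undefined
  z <- matrix(0, 2, 2); z[1, 1] <- 10
  expect_true(is.na(weighted_kappa(z)))
  expect_lte(weighted_kappa(conf), 1)
})

test_that("kappa cutoffs recover a deterministic discretization exactly", {
  set.seed(77)
  scores <- runif(400, 0, 100)
  cats <- cut(scores, c(-Inf, 30, 60, Inf), labels = FALSE)
  sol <- kappa_optimal_cutoffs(scores, cats)
  expect_identical(sol$method, "kappa")
  expect_equal(sol$cutoffs, c(30, 60))
  expect_equal(sol$criterion, 1.0)
  expect_error(kappa_optimal_cutoffs(scores, rep(1, 400)), "distinct")
})

test_that("kappa cutoff search equals exhaustive brute force", {
  set.seed(78)
  scores <- round(runif(200, 0, 40), 1)
  cats <- pmin(3, pmax(1, findInterval(scores + rnorm(200, 0, 6),
                                       c(12, 25)) + 1))
  grid <- 0:40
  sol <- kappa_optimal_cutoffs(scores, cats, grid = grid)
  # brute force over all candidate pairs with table()-based kappa
  best <- -Inf; best_cut <- NULL
  for (c1 in grid) for (c2 in grid) {
    if (c2 <= c1) next
    cls <- findInterval(scores, c(c1, c2)) + 1
    conf <- table(factor(cls, 1:3), factor(cats, 1:3))
    kap <- weighted_kappa(conf)
    if (!is.na(kap) && kap > best + 1e-12) {
      best <- kap; best_cut <- c(c1, c2)
    }
  }
  expect_equal(sol$cutoffs, best_cut)
  expect_equal(sol$criterion, best, tolerance = 1e-12)
})

test_that("ROC cutoff minimizes the distance to the top-left corner", {
  # perfectly separated classes
  sep <- roc_cutoff(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(as.numeric(sep), 10)
  expect_equal(attr(sep, "distance"), 0)
  # overlapping instance: compare with exhaustive evaluation
  set.seed(88)
  sc <- c(rnorm(60, 0), rnorm(60, 1.2))
  lb <- rep(c(FALSE, TRUE), each = 60)
  got <- roc_cutoff(sc, lb)
  cand <- sort(unique(sc))
  d <- sapply(cand, function(th) {
    sqrt(mean(sc[!lb] >= th)^2 + (1 - mean(sc[lb] >= th))^2)
  })
  expect_equal(attr(got, "distance"), min(d), tolerance = 1e-12)
  expect_equal(as.numeric(got), max(cand[d <= min(d) + 1e-12]))
  expect_error(roc_cutoff(sc, rep(TRUE, 120)), "non-empty")
})

test_that("Svensson cutoffs match the ordinal marginals within 1/n", {
  set.seed(99)
  n <- 400
  scores <- runif(n, 0, 100)
  cats <- sample(1:3, n, TRUE, prob = c(0.25, 0.25, 0.5))
  sol <- svensson_cutoffs(scores, cats)
  cls <- benefitsim:::discretize_scores(scores, sol$cutoffs)
  marg_s <- tabulate(cls, 3) / n
  marg_c <- tabulate(cats, 3) / n
  expect_lt(max(abs(cumsum(marg_s) - cumsum(marg_c))), 1 / n + 1e-12)
  # uniform integer scores, 50/50 split -> cutoff near the 50th percentile
  sol2 <- svensson_cutoffs(1:100, rep(1:2, each = 50))
  expect_lte(abs(sol2$cutoffs - 50), 1)
  expect_error(
    svensson_cutoffs(scores, factor(rep(c(1, 3), n / 2), levels = 1:3)),
    "degenerate")
})

test_that("correlations are invariant to monotone score transforms", {
  reps <- scaled_run("standard")
  pool <- significant_pool(reps)[1:2000, ]
  r1 <- spearman_rho(pool$asco, pool$esmo)
  r2 <- spearman_rho(exp(pool$asco / 25), pool$esmo)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("scenario summaries aggregate a hand-built pool correctly", {
  reps <- tibble::tibble(
    scenario = "toy", subscenario = "toy_1", replicate = 1:10,
    status = c(rep("significant", 8), "non_significant", "degenerate"),
    asco = c(10, 20, 30, 40, 50, 60, 70, 80, NA, NA),
    iqwig_rr = factor(c(rep("minor", 2), rep("considerable", 3),
                        rep("major", 3), "minor", NA),
                      levels = benefitsim:::iqwig_levels, ordered = TRUE),
    mod_iqwig = factor(c(rep("minor", 4), rep("considerable", 2),
                         rep("major", 2), "minor", NA),
                       levels = benefitsim:::iqwig_levels, ordered = TRUE),
    esmo = c(1, 1, 2, 3, 4, 4, 4, 4, 1, NA))
  s <- summarize_scenario(reps)
  expect_equal(s$n_pool, 8)
  props <- s$proportions[s$proportions$method == "esmo", ]
  expect_equal(props$prop[props$category == "4"], 0.5)
  expect_equal(sum(props$prop), 1)
  expect_equal(s$asco$asco_median[s$asco$method == "overall"], 45)
  expect_equal(
    s$asco$asco_median[s$asco$method == "iqwig_rr" &
                         s$asco$category == "considerable"], 40)
  acct <- setNames(s$accounting$n, s$accounting$status)
  expect_equal(acct[["significant"]], 8)
  expect_equal(acct[["degenerate"]], 1)
  g <- glance(s)
  expect_equal(g$asco_median, 45)
  # single replicate: proportions are indicators
  one <- summarize_scenario(reps[5, ])
  expect_true(all(one$proportions$prop == 1))
})
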
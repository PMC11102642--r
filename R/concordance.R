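#' Rank correlations between a continuous score and an ordinal grading
#'
#' Tie-aware Spearman rank correlation / Kendall tau-b.  When either vector
#' is constant the correlation is undefined and `NA` is returned (this
#' happens in subscenarios with very large effects, where an ordinal method
#' assigns a single category throughout).
#'
#' @param x Continuous scores.
#' @param y Ordinal categories (factor or numeric).
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch.", call. = FALSE)
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @export
kendall_tau_b <- function(x, y) {
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch.", call. = FALSE)
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y, method = "kendall")
}

# quadratic (Fleiss-Cohen) disagreement weights, w_ii = 0
fleiss_cohen_weights <- function(k) {
  outer(seq_len(k), seq_len(k), function(i, j) ((i - j) / (k - 1))^2)
}

#' Weighted Cohen's kappa with quadratic (Fleiss-Cohen) weights
#'
#' `kappa = 1 - sum(w * x) / sum(w * m)` where `x` is the observed
#' probability matrix, `m` the expected matrix under independence of the two
#' raters, and `w` the quadratic disagreement weights growing with the
#' squared category distance.  Returns `NA` when the expected disagreement
#' is zero (both raters constant).
#'
#' @param confusion Square non-negative count matrix (rows: first rater,
#'   columns: second rater).
#' @return Kappa, at most 1; 0 under exact independence.
#' @examples
#' weighted_kappa(diag(c(5, 3, 2))) # 1
#' @export
weighted_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  k <- nrow(confusion)
  stopifnot(k == ncol(confusion), all(confusion >= 0), sum(confusion) > 0)
  n <- sum(confusion)
  w <- fleiss_cohen_weights(k)
  x <- confusion / n
  m <- outer(rowSums(x), colSums(x))
  denom <- sum(w * m)
  if (denom == 0) return(NA_real_)
  1 - sum(w * x) / denom
}

new_cutoff_solution <- function(method, cutoffs, criterion, criterion_name,
                                k, n) {
  structure(list(method = method, cutoffs = cutoffs, criterion = criterion,
                 criterion_name = criterion_name, k = k, n = n),
            class = "cutoff_solution")
}

#' @export
print.cutoff_solution <- function(x, ...) {
  cat("<cutoff_solution> method = ", x$method, ", k = ", x$k,
      ", n = ", x$n, "\n", sep = "")
  cat("  cutoffs: ", paste(x$cutoffs, collapse = ", "), "\n", sep = "")
  if (!is.null(x$criterion) && is.finite(x$criterion)) {
    cat("  ", x$criterion_name, " = ", format(x$criterion, digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}

# counts of scores < g per category for every grid value; rows = grid,
# cols = categories
counts_below <- function(scores, cat_int, k, grid) {
  vapply(seq_len(k), function(j) {
    s <- sort(scores[cat_int == j])
    findInterval(grid, s, left.open = TRUE)
  }, numeric(length(grid)))
}

#' ASCO cutoffs maximizing weighted kappa against an ordinal grading
#'
#' Exhaustively searches all strictly increasing (k-1)-vectors of candidate
#' cutoffs (integers 0-100 by default), discretizes the continuous score by
#' them (class j when `cutoff[j-1] <= score < cutoff[j]`), and returns the
#' vector maximizing the quadratic-weighted Cohen's kappa against the
#' ordinal categories.  Ties are broken toward the lexicographically
#' smallest cutoff vector.
#'
#' @param scores Continuous scores.
#' @param categories Ordinal categories with k >= 2 levels (factor or
#'   integer).
#' @param grid Candidate cutoff values (default integers 0-100).
#' @return A `cutoff_solution` with the cutoffs and the achieved kappa.
#' @export
kappa_optimal_cutoffs <- function(scores, categories, grid = 0:100) {
  categories <- as.factor(categories)
  cat_int <- as.integer(categories)
  stopifnot(length(scores) == length(cat_int), length(grid) >= 2,
            !is.unsorted(grid, strictly = TRUE))
  k <- nlevels(categories)
  if (k < 2 || length(unique(cat_int)) < 2) {
    stop("`categories` must take at least two distinct values.",
         call. = FALSE)
  }
  if (length(unique(scores)) < k) {
    stop("need at least k distinct scores.", call. = FALSE)
  }
  n <- length(scores)
  cb <- counts_below(scores, cat_int, k, grid)     # |grid| x k
  n_j <- tabulate(cat_int, k)
  combos <- utils::combn(length(grid), k - 1)      # (k-1) x Ncombo, indices
  nc <- ncol(combos)

  # class counts per category for every combo, via cumulative differences
  w <- fleiss_cohen_weights(k)
  obs <- numeric(nc)   # sum w * x * n
  rowm <- matrix(0, nc, k)
  for (i in seq_len(k)) {
    lo <- if (i == 1) matrix(0, nc, k) else cb[combos[i - 1, ], , drop = FALSE]
    hi <- if (i == k) matrix(n_j, nc, k, byrow = TRUE) else
      cb[combos[i, ], , drop = FALSE]
    cell <- hi - lo                                 # counts in score-class i
    rowm[, i] <- rowSums(cell)
    obs <- obs + cell %*% w[i, ]
  }
  exp_dis <- (rowm %*% w) %*% n_j / n               # sum w * m * n
  kap <- 1 - as.vector(obs) / as.vector(exp_dis)
  kap[as.vector(exp_dis) == 0] <- NA_real_
  best <- max(kap, na.rm = TRUE)
  cand <- which(kap >= best - 1e-12)
  # lexicographically smallest cutoff vector among maximizers; combn emits
  # combinations in lexicographic order already
  pick <- cand[1]
  new_cutoff_solution("kappa", grid[combos[, pick]], kap[pick], "kappa", k, n)
}

#' ROC-based cutoff closest to the top-left corner
#'
#' For a binary split of the categories, scans all achievable thresholds
#' (classifying scores at or above the threshold as the higher class) and
#' returns the one whose (false-positive rate, true-positive rate) point is
#' closest in Euclidean distance to (0, 1).  Ties are broken toward the
#' higher threshold, i.e. higher specificity.
#'
#' @param scores Continuous scores.
#' @param positive Logical vector, `TRUE` for the higher (positive) class.
#' @return The cutoff value, with the achieved distance, true- and
#'   false-positive rate as attributes.
#' @export
roc_cutoff <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive))
  if (!any(positive) || all(positive)) {
    stop("both classes must be non-empty.", call. = FALSE)
  }
  thr <- sort(unique(scores))
  np <- sum(positive)
  nn <- sum(!positive)
  # counts >= each threshold
  sp <- sort(scores[positive])
  sn <- sort(scores[!positive])
  tpr <- (np - findInterval(thr, sp, left.open = TRUE)) / np
  fpr <- (nn - findInterval(thr, sn, left.open = TRUE)) / nn
  d <- sqrt(fpr^2 + (1 - tpr)^2)
  best <- min(d)
  pick <- max(which(d <= best + 1e-12))  # tie: higher cutoff / specificity
  structure(thr[pick], distance = d[pick], tpr = tpr[pick], fpr = fpr[pick])
}

#' @rdname roc_cutoff
#' @param categories Ordinal categories; one cutoff is derived per pairwise
#'   split (category <= j versus > j).
#' @export
roc_cutoffs <- function(scores, categories) {
  categories <- as.factor(categories)
  k <- nlevels(categories)
  ci <- as.integer(categories)
  cuts <- vapply(seq_len(k - 1),
                 function(j) as.numeric(roc_cutoff(scores, ci > j)),
                 numeric(1))
  new_cutoff_solution("roc", cuts, NA_real_, "distance", k, length(scores))
}

#' Svensson marginal-matching cutoffs
#'
#' Places the cutoffs at the empirical score quantiles matching the
#' cumulative category proportions, so that discretizing the continuous
#' score reproduces the ordinal method's marginal distribution to within
#' 1/n.
#'
#' @inheritParams kappa_optimal_cutoffs
#' @return A `cutoff_solution`.
#' @export
svensson_cutoffs <- function(scores, categories) {
  categories <- as.factor(categories)
  k <- nlevels(categories)
  n <- length(scores)
  stopifnot(length(scores) == n, n >= k)
  counts <- tabulate(as.integer(categories), k)
  if (any(counts == 0)) {
    stop("degenerate category: every ordinal level must be observed.",
         call. = FALSE)
  }
  s <- sort(scores)
  cum <- cumsum(counts)[-k]
  cuts <- s[cum + 1]  # number of scores strictly below each cutoff ~ cum
  new_cutoff_solution("svensson", cuts, NA_real_, "", k, n)
}

# discretize scores by cutoffs with the package-wide convention:
# class j when cutoff[j-1] <= s < cutoff[j]
discretize_scores <- function(scores, cutoffs) {
  findInterval(scores, cutoffs, left.open = FALSE) + 1L
}

#' Summarize a pool of scored replicates
#'
#' Computes the descriptive comparison tables for one scenario's pooled
#' replicates: per-method category proportions, the ASCO median overall and
#' conditional on each ordinal category, pairwise rank correlations between
#' ASCO and the ordinal methods, and the replicate accounting
#' (significant / non-significant / degenerate).
#'
#' @param replicates Scored replicate tibble from [run_scenario()].
#' @param conditional Summarize significant replicates only (the default,
#'   matching benefit assessment after a significant trial) or all
#'   non-degenerate replicates.
#' @param kendall Also compute Kendall tau-b (quadratic in pool size;
#'   off by default).
#' @return A list of class `scenario_summary` with tibbles `proportions`,
#'   `asco`, `correlations`, `accounting`.
#' @export
summarize_scenario <- function(replicates, conditional = TRUE,
                               kendall = FALSE) {
  stopifnot(nrow(replicates) > 0)
  accounting <- replicates |>
    dplyr::count(.data$status, name = "n") |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
  pool <- if (conditional) {
    dplyr::filter(replicates, .data$status == "significant")
  } else {
    dplyr::filter(replicates, .data$status != "degenerate")
  }
  if (nrow(pool) == 0) stop("empty pool after conditioning.", call. = FALSE)

  long <- pool |>
    dplyr::select("asco", "iqwig_rr", "mod_iqwig", "esmo") |>
    dplyr::mutate(esmo = factor(.data$esmo, levels = 1:4, ordered = TRUE)) |>
    tidyr::pivot_longer(c("iqwig_rr", "mod_iqwig", "esmo"),
                        names_to = "method", values_to = "category",
                        values_transform = as.character)
  proportions <- long |>
    dplyr::count(.data$method, .data$category, name = "n") |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  asco <- dplyr::bind_rows(
    tibble::tibble(method = "overall", category = NA_character_,
                   n = nrow(pool), asco_median = median(pool$asco)),
    long |>
      dplyr::group_by(.data$method, .data$category) |>
      dplyr::summarize(n = dplyr::n(), asco_median = median(.data$asco),
                       .groups = "drop"))
  cor_one <- function(y, fun) fun(pool$asco, y)
  correlations <- tibble::tibble(
    method = c("esmo", "iqwig_rr", "mod_iqwig"),
    spearman = c(cor_one(pool$esmo, spearman_rho),
                 cor_one(pool$iqwig_rr, spearman_rho),
                 cor_one(pool$mod_iqwig, spearman_rho)))
  if (kendall) {
    correlations$kendall <- c(cor_one(pool$esmo, kendall_tau_b),
                              cor_one(pool$iqwig_rr, kendall_tau_b),
                              cor_one(pool$mod_iqwig, kendall_tau_b))
  }
  structure(list(proportions = proportions, asco = asco,
                 correlations = correlations, accounting = accounting,
                 conditional = conditional, n_pool = nrow(pool)),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("<scenario_summary> ", x$n_pool, " pooled replicates (",
      if (x$conditional) "significant only" else "unconditional", ")\n",
      sep = "")
  cat("\nCategory proportions:\n")
  print(x$proportions, n = Inf)
  cat("\nASCO medians:\n")
  print(x$asco, n = Inf)
  cat("\nSpearman correlations with ASCO:\n")
  print(x$correlations)
  invisible(x)
}

#' ASCO cutoffs concordant with each ordinal method, by each cutoff method
#'
#' Convenience wrapper deriving, for every ordinal method in the pool, the
#' ASCO cutoffs by weighted-kappa maximization and optionally by the
#' ROC closest-to-corner and Svensson marginal-matching sensitivity
#' methods.
#'
#' @inheritParams summarize_scenario
#' @param methods Cutoff methods to apply.
#' @param grid Candidate cutoff grid for the kappa search.
#' @return Tibble with one row per (ordinal method, cutoff method, cutoff
#'   index).
#' @export
cutoff_table <- function(replicates, methods = c("kappa", "roc", "svensson"),
                         grid = 0:100) {
  methods <- match.arg(methods, several.ok = TRUE)
  pool <- dplyr::filter(replicates, .data$status == "significant")
  ordinal <- list(esmo = pool$esmo, iqwig_rr = pool$iqwig_rr,
                  mod_iqwig = pool$mod_iqwig)
  purrr::imap(ordinal, function(cats, nm) {
    cats <- droplevels(as.factor(cats))
    purrr::map(methods, function(m) {
      # a pool where an ordinal method assigns a single category has no
      # defined cutoffs (mirrors the missing-correlation convention)
      sol <- tryCatch(switch(m,
        kappa = kappa_optimal_cutoffs(pool$asco, cats, grid),
        roc = roc_cutoffs(pool$asco, cats),
        svensson = svensson_cutoffs(pool$asco, cats)),
        error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      tidy(sol) |> dplyr::mutate(ordinal_method = nm, .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
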
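#' Boxplots of the ASCO score within each ordinal category
#'
#' The package's analogue of the score-versus-category comparison figures:
#' for each ordinal method, the distribution of the continuous ASCO score
#' within each assigned category, optionally with vertical lines at derived
#' cutoffs.
#'
#' @param replicates Scored replicates from [run_scenario()].
#' @param method Ordinal method to plot against.
#' @param cutoffs Optional numeric cutoffs drawn as vertical reference
#'   lines (e.g. `kappa_optimal_cutoffs(...)$cutoffs`).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(replicates,
                                    method = c("esmo", "iqwig_rr",
                                               "mod_iqwig"),
                                    cutoffs = NULL) {
  method <- match.arg(method)
  pool <- dplyr::filter(replicates, .data$status == "significant")
  pool$category <- factor(pool[[method]])
  p <- ggplot2::ggplot(pool, ggplot2::aes(x = .data$asco,
                                          y = .data$category)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(x = "ASCO net-health-benefit score",
                  y = paste0(method, " category"),
                  title = paste("ASCO score by", method, "category")) +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(cutoffs),
                                 linetype = "dashed")
  }
  p
}

#' @rdname plot_score_distribution
#' @param object,... `autoplot` arguments (`object` is the scored replicate
#'   tibble's scenario summary).
#' @export
autoplot.scenario_summary <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$category, y = .data$prop)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~method, scales = "free_x") +
    ggplot2::labs(x = "category", y = "proportion of significant trials") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
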
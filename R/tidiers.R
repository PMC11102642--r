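#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cutoff solution
#'
#' @param x A `cutoff_solution` from [kappa_optimal_cutoffs()],
#'   [roc_cutoffs()] or [svensson_cutoffs()].
#' @param ... Unused.
#' @return One row per cutoff: `cutoff_method`, `index`, `cutoff`.
#' @export
tidy.cutoff_solution <- function(x, ...) {
  tibble::tibble(cutoff_method = x$method,
                 index = seq_along(x$cutoffs),
                 cutoff = as.numeric(x$cutoffs))
}

#' @rdname tidy.cutoff_solution
#' @return For `glance()`: one row with the method, number of categories,
#'   pool size and criterion value.
#' @export
glance.cutoff_solution <- function(x, ...) {
  tibble::tibble(cutoff_method = x$method, k = x$k, n = x$n,
                 criterion = x$criterion,
                 criterion_name = x$criterion_name)
}

#' @rdname tidy.cutoff_solution
#' @export
glance.scenario_summary <- function(x, ...) {
  sp <- setNames(x$correlations$spearman, x$correlations$method)
  tibble::tibble(
    n_pool = x$n_pool,
    conditional = x$conditional,
    asco_median = x$asco$asco_median[x$asco$method == "overall"][1],
    spearman_esmo = sp[["esmo"]],
    spearman_iqwig_rr = sp[["iqwig_rr"]],
    spearman_mod_iqwig = sp[["mod_iqwig"]])
}

#' @rdname tidy.cutoff_solution
#' @export
tidy.scenario_summary <- function(x, ...) x$proportions
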
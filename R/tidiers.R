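#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname path_test_tidiers
#' @title Tidiers for permutation path tests
#' @description `tidy()` returns one row per permutation (the null
#'   distribution plus the observed statistic flagged); `glance()` returns a
#'   one-row summary.
#' @param x a `path_test` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.path_test <- function(x, ...) {
  dplyr::bind_rows(
    tibble(iteration = 0L, statistic = x$observed, role = "observed"),
    tibble(iteration = seq_along(x$null), statistic = x$null, role = "null")
  )
}

#' @rdname path_test_tidiers
#' @export
glance.path_test <- function(x, ...) {
  finite_null <- x$null[is.finite(x$null)]
  tibble(
    observed = x$observed,
    null_mean = if (length(finite_null)) mean(finite_null) else NA_real_,
    null_median = if (length(finite_null)) stats::median(finite_null) else NA_real_,
    p_value = x$p_value,
    n_iter = x$n_iter,
    n_query = x$n_query,
    n_anchors = x$n_anchors,
    n_unreachable_observed = x$n_unreachable_observed
  )
}

#' Tidiers for intersection reports
#'
#' `tidy()` returns the exclusive membership-pattern counts; `glance()` a
#' one-row summary with the size of the all-lists common set.
#'
#' @param x an `intersection_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.intersection_report <- function(x, ...) x$patterns

#' @rdname tidy.intersection_report
#' @export
glance.intersection_report <- function(x, ...) {
  tibble(
    n_lists = length(x$labels),
    union_size = x$union_size,
    n_common = length(x$common)
  )
}

#' Tidiers for top-k validation results
#' @param x a `topk_validation` tibble.
#' @param ... unused.
#' @return A tibble (one row per k for `tidy()`, one row for `glance()`).
#' @export
tidy.topk_validation <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.topk_validation
#' @export
glance.topk_validation <- function(x, ...) {
  tibble(best_k = x$k[which.max(x$elfc)],
         max_elfc = max(x$elfc),
         max_hgpv = max(x$hgpv))
}
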
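check_quadruple <- function(targets_k, k, targets_N, N) {
  if (targets_N < 1 || targets_N > N) {
    abort("`targets_N` must satisfy 1 <= targets_N <= N (enrichment is undefined for an empty reference).")
  }
  if (k < 1 || k > N) abort("`k` must satisfy 1 <= k <= N.")
  if (targets_k < 0 || targets_k > min(k, targets_N)) {
    abort("`targets_k` must satisfy 0 <= targets_k <= min(k, targets_N).")
  }
  invisible(TRUE)
}

#' Enrichment log fold change (ELFC) of known targets in a top-k list
#'
#' `log2((t_k / k) / (targets_N / N))`: the log2 ratio of the known-target
#' fraction within the top k to the known-target fraction in the whole gene
#' universe. When no known target lands in the top k, `targets_k` is
#' substituted by 0.1 so the statistic stays finite.
#'
#' @param targets_k number of known targets in the top k.
#' @param k list cutoff.
#' @param targets_N number of known targets in the universe.
#' @param N universe size.
#' @return ELFC (vectorized over the first argument).
#' @export
elfc <- function(targets_k, k, targets_N, N) {
  for (t in targets_k) check_quadruple(t, k, targets_N, N)
  tk <- ifelse(targets_k > 0, targets_k, 0.1)
  log2((tk / k) / (targets_N / N))
}

#' Hypergeometric p-value score (HGPV) of a top-k list
#'
#' `-log10 P(X >= targets_k)` where X is hypergeometric: the number of known
#' targets among k draws, without replacement, from a universe of N genes of
#' which `targets_N` are known targets. The tail is computed through the
#' log survival function so values stay accurate for p near 0. The literal
#' strict-tail variant `-log10 P(X > targets_k)` (i.e. `1 - cdf(targets_k)`)
#' is available with `strict = TRUE`.
#'
#' @inheritParams elfc
#' @param strict use the strict tail `P(X > targets_k)` instead of the
#'   default `P(X >= targets_k)`.
#' @return Non-negative HGPV; p-values are floored at the smallest
#'   representable double before the log, so the score is always finite.
#' @export
hgpv <- function(targets_k, k, targets_N, N, strict = FALSE) {
  for (t in targets_k) check_quadruple(t, k, targets_N, N)
  q <- if (strict) targets_k else targets_k - 1
  log_p <- stats::phyper(q, m = targets_N, n = N - targets_N, k = k,
                         lower.tail = FALSE, log.p = TRUE)
  log_p <- pmax(log_p, log(.Machine$double.xmin))
  -log_p / log(10)
}

#' Top-k validation of a ranked gene list against a reference target set
#'
#' For each cutoff k, counts how many reference targets appear among the
#' first k ranked symbols and reports ELFC and HGPV.
#'
#' @param ranked a `ranked_genes` tibble (or any tibble with a `symbol`
#'   column in rank order).
#' @param reference character vector of known target symbols (must lie
#'   within the universe).
#' @param ks cutoffs to evaluate (default `c(50, 100, 200)`).
#' @param N universe size; defaults to the number of ranked genes.
#' @return A `topk_validation` tibble with columns `k`, `targets_k`,
#'   `targets_N`, `N`, `elfc`, `hgpv`.
#' @export
topk_validate <- function(ranked, reference, ks = c(50L, 100L, 200L),
                          N = nrow(ranked)) {
  if (length(ks) == 0) abort("`ks` must be non-empty.")
  symbols <- ranked$symbol
  if (any(ks > length(symbols))) {
    abort(sprintf("k = %d exceeds the ranking length (%d).",
                  max(ks), length(symbols)))
  }
  reference <- unique(toupper(trimws(reference)))
  targets_N <- length(reference)
  out <- purrr::map_dfr(sort(as.integer(ks)), function(k) {
    t_k <- sum(symbols[seq_len(k)] %in% reference)
    tibble(
      k = k,
      targets_k = t_k,
      targets_N = targets_N,
      N = as.integer(N),
      elfc = elfc(t_k, k, targets_N, N),
      hgpv = hgpv(t_k, k, targets_N, N)
    )
  })
  class(out) <- c("topk_validation", class(out))
  out
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the observed overlap between a candidate list and a
#' reference set is larger than expected by chance when drawing
#' `|list_a|` genes from a universe of size N containing `|reference|`
#' reference genes: `P(X >= overlap)`.
#'
#' @param list_a character vector (e.g. a top-200 list).
#' @param reference character vector of reference symbols.
#' @param N universe size (>= both list sizes).
#' @return An `overlap_test` tibble row: `overlap`, `size_a`,
#'   `size_reference`, `N`, `p_value`.
#' @export
overlap_test <- function(list_a, reference, N) {
  list_a <- unique(toupper(trimws(list_a)))
  reference <- unique(toupper(trimws(reference)))
  if (N < length(list_a) || N < length(reference)) {
    abort("`N` must be at least as large as both sets.")
  }
  ov <- length(intersect(list_a, reference))
  log_p <- stats::phyper(ov - 1, m = length(reference),
                         n = N - length(reference), k = length(list_a),
                         lower.tail = FALSE, log.p = TRUE)
  out <- tibble(
    overlap = ov,
    size_a = length(list_a),
    size_reference = length(reference),
    N = as.integer(N),
    p_value = exp(log_p)
  )
  class(out) <- c("overlap_test", class(out))
  out
}
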
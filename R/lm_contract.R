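#' Construct a causal language model interface
#'
#' Every part of the pipeline talks to a language model only through this
#' minimal behavioral contract: tokenize text, return the full next-token
#' probability distribution given a context, and return per-token embedding
#' vectors. Adapters for real models must hand over *probabilities* (not
#' logits) over the complete vocabulary and must be deterministic; the
#' pipeline never samples.
#'
#' @param tokenize function(text) returning an integer vector of token ids
#'   (ids are 1-based indices into the vocabulary).
#' @param next_token_distribution function(ids) returning a numeric vector of
#'   length `vocab_size`; element `i` is the probability that token `i`
#'   follows the context `ids`.
#' @param token_embeddings function(ids) returning a numeric matrix with one
#'   row per token in `ids` and `embedding_dim` columns.
#' @param vocab_size integer vocabulary size.
#' @param embedding_dim integer embedding dimension (model-specific; e.g.
#'   1024 for a BioGPT-sized model, small for toys).
#' @param name optional label used in printing and run manifests.
#'
#' @return An object of class `causal_lm`.
#' @export
causal_lm <- function(tokenize, next_token_distribution, token_embeddings,
                      vocab_size, embedding_dim, name = "causal_lm") {
  stopifnot(is.function(tokenize), is.function(next_token_distribution),
            is.function(token_embeddings))
  vocab_size <- as.integer(vocab_size)
  embedding_dim <- as.integer(embedding_dim)
  if (vocab_size < 1L) abort("`vocab_size` must be >= 1.")
  structure(
    list(
      tokenize = tokenize,
      next_token_distribution = next_token_distribution,
      token_embeddings = token_embeddings,
      vocab_size = vocab_size,
      embedding_dim = embedding_dim,
      name = name
    ),
    class = "causal_lm"
  )
}

#' @export
print.causal_lm <- function(x, ...) {
  cat(sprintf("<causal_lm: %s> vocab %d, embedding dim %d\n",
              x$name, x$vocab_size, x$embedding_dim))
  invisible(x)
}

#' Check a language model against the contract
#'
#' Probes the model with the supplied contexts and verifies, for each, that
#' the next-token distribution is non-negative, sums to one within
#' tolerance, has the declared vocabulary length, and that repeated calls
#' (distributions and embeddings) are bit-identical. Any violation raises a
#' contract error naming the failing property; on success a diagnostic
#' tibble is returned invisibly, and downstream code may assume the
#' distribution invariants.
#'
#' @param lm a [causal_lm()] object.
#' @param probe_sequences list of integer token-id vectors (at least one).
#' @param tol tolerance on the probability sum (default `1e-6`).
#'
#' @return (invisibly) a tibble with one row per probe and property checked.
#' @export
validate_lm <- function(lm, probe_sequences, tol = 1e-6) {
  stopifnot(inherits(lm, "causal_lm"))
  if (!is.list(probe_sequences) || length(probe_sequences) == 0) {
    abort("`probe_sequences` must be a non-empty list of token-id vectors.")
  }
  rows <- purrr::imap(probe_sequences, function(ids, i) {
    ids <- as.integer(ids)
    if (length(ids) == 0) abort("probe sequences must be non-empty.")
    p1 <- lm$next_token_distribution(ids)
    if (length(p1) != lm$vocab_size) {
      abort(sprintf("contract violation [wrong length]: probe %d returned %d probabilities, vocab_size is %d",
                    i, length(p1), lm$vocab_size))
    }
    if (any(p1 < 0)) {
      abort(sprintf("contract violation [negative probability]: probe %d", i))
    }
    s <- sum(p1)
    if (abs(s - 1) > tol) {
      abort(sprintf("contract violation [not normalized]: probe %d sums to %.8f", i, s))
    }
    p2 <- lm$next_token_distribution(ids)
    if (!identical(p1, p2)) {
      abort(sprintf("contract violation [non-deterministic]: probe %d distribution differs across calls", i))
    }
    e1 <- lm$token_embeddings(ids)
    e2 <- lm$token_embeddings(ids)
    if (!is.matrix(e1) || nrow(e1) != length(ids) || ncol(e1) != lm$embedding_dim) {
      abort(sprintf("contract violation [embedding shape]: probe %d", i))
    }
    if (!identical(e1, e2)) {
      abort(sprintf("contract violation [non-deterministic]: probe %d embeddings differ across calls", i))
    }
    tibble(probe = i, n_context = length(ids), prob_sum = s,
           min_prob = min(p1), deterministic = TRUE)
  })
  report <- dplyr::bind_rows(rows)
  inform(sprintf("validate_lm: %d probes passed all contract checks.", nrow(report)))
  invisible(report)
}
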
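#' Prompt template for disease-target scoring
#'
#' The default is the prompt found to work best for next-word gene
#' prediction: it ends in an article so that the gene symbol is scored as
#' the natural continuation.
#'
#' @param template string containing the placeholder `{DISEASE}` exactly once.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(template = "human gene targeted by a drug for treating {DISEASE} is the") {
  n <- lengths(regmatches(template, gregexpr("{DISEASE}", template, fixed = TRUE)))
  if (n != 1L) {
    abort("`template` must contain the placeholder {DISEASE} exactly once.")
  }
  structure(template, class = "prompt_template")
}

#' Fill and tokenize the disease prompt
#'
#' @param lm a [causal_lm()] object.
#' @param disease non-empty disease name substituted for `{DISEASE}`.
#' @param template a [prompt_template()].
#' @return Integer vector of prompt token ids.
#' @export
build_prompt <- function(lm, disease, template = prompt_template()) {
  stopifnot(inherits(lm, "causal_lm"))
  if (!inherits(template, "prompt_template")) template <- prompt_template(template)
  disease <- trimws(as.character(disease))
  if (length(disease) != 1L || !nzchar(disease)) {
    abort("`disease` must be a single non-empty string.")
  }
  text <- sub("{DISEASE}", disease, unclass(template), fixed = TRUE)
  as.integer(lm$tokenize(trimws(text)))
}

#' Scoring configuration
#'
#' @param step_scheme per-iteration normalization of next-token
#'   probabilities over the allowed (gene-continuing) token set:
#'   `"total_sum"` divides by the summed mass of all allowed tokens;
#'   `"separate_sum"` renormalizes gene-completing and gene-continuing
#'   tokens independently; `"none"` keeps raw probabilities.
#' @param final_scheme correction of the final token-probability product
#'   for name length: `"length_division"` divides by `L^alpha`,
#'   `"geometric_mean"` takes the L-th root, `"none"` leaves the product.
#' @param alpha positive exponent for `length_division` (best-performing
#'   value 1).
#' @param max_token_length optional pre-scoring filter on token length
#'   (`NULL` = no filter; e.g. 5 when known targets tokenize short).
#' @param top_k number of entries reported by default (200).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(step_scheme = c("total_sum", "separate_sum", "none"),
                           final_scheme = c("length_division", "geometric_mean", "none"),
                           alpha = 1,
                           max_token_length = NULL,
                           top_k = 200L) {
  step_scheme <- match.arg(step_scheme)
  final_scheme <- match.arg(final_scheme)
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  top_k <- as.integer(top_k)
  if (top_k < 1L) abort("`top_k` must be >= 1.")
  if (!is.null(max_token_length)) {
    max_token_length <- as.integer(max_token_length)
    if (max_token_length < 1L) abort("`max_token_length` must be >= 1.")
  }
  structure(list(step_scheme = step_scheme, final_scheme = final_scheme,
                 alpha = alpha, max_token_length = max_token_length,
                 top_k = top_k),
            class = "scoring_config")
}

#' Read a scoring configuration from a key-value text file
#'
#' The file is YAML-formatted with keys mirroring the [scoring_config()]
#' fields (`step_scheme`, `final_scheme`, `alpha`, `max_token_length`,
#' `top_k`); missing keys fall back to the defaults. Entries in `overrides`
#' (e.g. command-line flags) take precedence over file values.
#'
#' @param path path to the config file.
#' @param overrides named list of field overrides.
#' @return A `scoring_config`.
#' @export
read_scoring_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path) %||% list()
  if (!is.list(vals)) abort("config file must contain key-value pairs.")
  vals[names(overrides)] <- overrides
  allowed <- c("step_scheme", "final_scheme", "alpha", "max_token_length",
               "top_k")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(scoring_config, vals[intersect(names(vals), allowed)])
}

# Internal step normalization over the allowed token set. `probs` is the
# full-vocabulary distribution; completing/continuing are integer id sets
# (a token may be in both when one gene ends where another continues).
# Returns list(completing=, continuing=) of numeric vectors named by id.
# Zero allowed mass in a class yields zeros, never NaN.
step_normalize_sets <- function(probs, completing, continuing, scheme) {
  allowed <- union(completing, continuing)
  if (length(allowed) == 0) abort("empty allowed token set.")
  p_comp <- probs[completing]
  p_cont <- probs[continuing]
  if (scheme == "none") {
    # raw probabilities restricted to the allowed set
  } else if (scheme == "total_sum") {
    total <- sum(probs[allowed])
    if (total > 0) {
      p_comp <- p_comp / total
      p_cont <- p_cont / total
    } else {
      p_comp[] <- 0
      p_cont[] <- 0
    }
  } else if (scheme == "separate_sum") {
    sc <- sum(p_comp)
    p_comp <- if (sc > 0) p_comp / sc else rep(0, length(p_comp))
    sn <- sum(p_cont)
    p_cont <- if (sn > 0) p_cont / sn else rep(0, length(p_cont))
  } else {
    abort(sprintf("unknown step scheme '%s'.", scheme))
  }
  list(
    completing = stats::setNames(as.numeric(p_comp), as.character(completing)),
    continuing = stats::setNames(as.numeric(p_cont), as.character(continuing))
  )
}

#' Normalize next-token probabilities over the allowed gene-token set
#'
#' At each trie-expansion step only a small subset of the vocabulary can
#' extend a gene name; this renormalizes the model's probabilities over
#' that subset. Under `"separate_sum"` a token that both completes one gene
#' and continues another receives a value in each role.
#'
#' @param probs full-vocabulary probability vector (element i = token id i).
#' @param completing integer ids of tokens that complete a gene at this step.
#' @param continuing integer ids of tokens that continue some longer gene.
#' @param scheme `"total_sum"`, `"separate_sum"` or `"none"`.
#' @return A tibble with columns `token_id`, `role`
#'   (`"completing"`/`"continuing"`) and `prob`.
#' @export
step_normalize <- function(probs, completing, continuing,
                           scheme = c("total_sum", "separate_sum", "none")) {
  scheme <- match.arg(scheme)
  completing <- as.integer(completing)
  continuing <- as.integer(continuing)
  res <- step_normalize_sets(probs, completing, continuing, scheme)
  dplyr::bind_rows(
    tibble(token_id = completing, role = "completing",
           prob = unname(res$completing)),
    tibble(token_id = continuing, role = "continuing",
           prob = unname(res$continuing))
  )
}

#' Final (token-length) normalization of a gene's probability product
#'
#' @param raw raw probability product in `[0, 1]`.
#' @param L token length of the gene name (>= 1).
#' @param scheme `"length_division"` (`raw / L^alpha`),
#'   `"geometric_mean"` (`raw^(1/L)`) or `"none"`.
#' @param alpha exponent for `length_division`.
#' @return Final score(s); vectorized over `raw`/`L`.
#' @export
final_normalize <- function(raw, L,
                            scheme = c("length_division", "geometric_mean", "none"),
                            alpha = 1) {
  scheme <- match.arg(scheme)
  if (any(L < 1)) abort("`L` must be >= 1.")
  switch(scheme,
    none = raw,
    geometric_mean = raw^(1 / L),
    length_division = raw / L^alpha
  )
}

# log-domain version used by the scorer (safe for products down to
# exp(-5000) and below).
final_normalize_log <- function(log_raw, L, scheme, alpha = 1) {
  switch(scheme,
    none = log_raw,
    geometric_mean = log_raw / L,
    length_division = log_raw - alpha * log(L)
  )
}

#' Score every lexicon gene as a continuation of a disease prompt
#'
#' The core ranking method: breadth-first expansion of the token trie. At
#' each frontier prefix the model is queried for the next-token distribution
#' given prompt + prefix; the trie children of that prefix form the allowed
#' set (children that terminate a gene are "completing", children with
#' descendants are "continuing"; a terminal child with descendants is both);
#' step normalization is applied; log-probabilities accumulate along each
#' path; at each terminal the gene's raw probability is recorded. Final
#' normalization corrects for token length and the genes are ranked.
#'
#' @param lm a [causal_lm()] object.
#' @param trie a [build_trie()] token trie.
#' @param prompt integer prompt token ids from [build_prompt()].
#' @param config a [scoring_config()].
#' @param lexicon optional tokenized `gene_lexicon`; when supplied (or when
#'   `config$max_token_length` is set) it is used to apply the token-length
#'   filter before scoring.
#' @return A `ranked_genes` tibble with columns `rank`, `symbol`,
#'   `raw_probability`, `final_score`, `token_length`, `log_raw`,
#'   `log_final`, ordered by descending `final_score` (ties broken by
#'   symbol). All comparisons happen in the log domain.
#' @export
score_genes <- function(lm, trie, prompt, config = scoring_config(),
                        lexicon = NULL) {
  stopifnot(inherits(lm, "causal_lm"), inherits(trie, "token_trie"))
  if (!is.null(config$max_token_length)) {
    if (is.null(lexicon)) {
      abort("`lexicon` is required when `config$max_token_length` is set.")
    }
    lexicon <- filter_by_token_length(lexicon, config$max_token_length)
    trie <- build_trie(lexicon)
  }
  if (trie$n_genes == 0) abort("trie is empty.")
  prompt <- as.integer(prompt)
  if (length(prompt) == 0) abort("prompt must be non-empty.")

  symbols <- character(trie$n_genes)
  log_raw <- numeric(trie$n_genes)
  lengths_out <- integer(trie$n_genes)
  n_found <- 0L

  # frontier entries: node, accumulated log prob, prefix token ids, depth
  frontier <- list(list(node = trie$root, logp = 0, prefix = integer(0)))
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    next_frontier <- list()
    for (fr in frontier) {
      kids <- trie_children(fr$node)
      if (length(kids) == 0) next
      kid_ids <- vapply(kids, function(k) k$token, integer(1))
      is_term <- vapply(kids, function(k) !is.null(k$symbol), logical(1))
      has_desc <- vapply(kids, function(k) length(ls(k$children)) > 0, logical(1))
      completing <- kid_ids[is_term]
      continuing <- kid_ids[has_desc]
      dist <- lm$next_token_distribution(c(prompt, fr$prefix))
      norm <- step_normalize_sets(dist, completing, continuing,
                                  config$step_scheme)
      for (j in seq_along(kids)) {
        kid <- kids[[j]]
        key <- as.character(kid_ids[j])
        if (is_term[j]) {
          n_found <- n_found + 1L
          symbols[n_found] <- kid$symbol
          log_raw[n_found] <- fr$logp + log(norm$completing[[key]])
          lengths_out[n_found] <- depth
        }
        if (has_desc[j]) {
          next_frontier[[length(next_frontier) + 1L]] <- list(
            node = kid,
            logp = fr$logp + log(norm$continuing[[key]]),
            prefix = c(fr$prefix, kid_ids[j])
          )
        }
      }
    }
    frontier <- next_frontier
  }

  scores <- tibble(
    symbol = symbols[seq_len(n_found)],
    token_length = lengths_out[seq_len(n_found)],
    log_raw = log_raw[seq_len(n_found)]
  )
  scores$log_final <- final_normalize_log(scores$log_raw, scores$token_length,
                                          config$final_scheme, config$alpha)
  scores$raw_probability <- exp(scores$log_raw)
  scores$final_score <- exp(scores$log_final)
  rank_genes(scores, top_k = NULL, config = config)
}

#' Rank scored genes
#'
#' Orders by descending final score with deterministic lexicographic
#' tie-breaking on the symbol, assigns 1-based ranks, and optionally
#' truncates to the top k (the full ranking is kept in the
#' `"full_ranking"` attribute).
#'
#' @param scores tibble with at least `symbol` and `log_final` (or
#'   `final_score`) columns.
#' @param top_k truncate the returned list (`NULL` = full list).
#' @param config optional `scoring_config` stored as an attribute.
#' @param disease optional disease label stored as an attribute.
#' @return A `ranked_genes` tibble.
#' @export
rank_genes <- function(scores, top_k = NULL, config = NULL, disease = NULL) {
  if (nrow(scores) == 0) abort("`scores` must be non-empty.")
  key <- if ("log_final" %in% names(scores)) scores$log_final else log(scores$final_score)
  ord <- order_score_symbol(key, scores$symbol)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  cols <- intersect(c("rank", "symbol", "raw_probability", "final_score",
                      "token_length", "log_raw", "log_final"), names(out))
  out <- out[, cols]
  full <- out
  if (!is.null(top_k) && top_k < nrow(out)) {
    out <- out[seq_len(top_k), , drop = FALSE]
  }
  out <- tibble::as_tibble(out)
  class(out) <- c("ranked_genes", class(out))
  attr(out, "full_ranking") <- tibble::as_tibble(full)
  attr(out, "config") <- config
  attr(out, "disease") <- disease
  out
}

#' Re-score a single gene by direct trie walk (test oracle)
#'
#' Walks one gene's token sequence from the trie root, recomputing the
#' allowed set and step normalization at each prefix, and multiplies the
#' per-step probabilities directly on the probability scale. Defined so
#' that [score_genes()] must agree with it for every gene; kept independent
#' of the breadth-first accumulation path.
#'
#' @param lm a [causal_lm()] object.
#' @param token_ids the gene's token-id sequence.
#' @param trie the token trie the gene belongs to.
#' @param prompt prompt token ids.
#' @param config a [scoring_config()] (only `step_scheme` is used).
#' @return The raw probability product.
#' @export
brute_force_score <- function(lm, token_ids, trie, prompt,
                              config = scoring_config()) {
  token_ids <- as.integer(token_ids)
  node <- trie$root
  acc <- 1
  for (t in seq_along(token_ids)) {
    kids <- trie_children(node)
    kid_ids <- vapply(kids, function(k) k$token, integer(1))
    is_term <- vapply(kids, function(k) !is.null(k$symbol), logical(1))
    has_desc <- vapply(kids, function(k) length(ls(k$children)) > 0, logical(1))
    dist <- lm$next_token_distribution(c(as.integer(prompt),
                                         token_ids[seq_len(t - 1L)]))
    norm <- step_normalize_sets(dist, kid_ids[is_term], kid_ids[has_desc],
                                config$step_scheme)
    key <- as.character(token_ids[t])
    child <- node$children[[key]]
    if (is.null(child)) abort("gene token sequence not found in trie.")
    last <- t == length(token_ids)
    p <- if (last) unname(norm$completing[key]) else unname(norm$continuing[key])
    if (length(p) != 1L || is.na(p)) {
      abort("gene token sequence inconsistent with trie structure.")
    }
    acc <- acc * p
    node <- child
  }
  if (is.null(node$symbol)) abort("sequence does not end at a terminal node.")
  acc
}
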
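# Shared fixtures: all built in code, no files.

# A hand-specified deterministic LM. `dists` maps a context key (token ids
# joined by ",") to a full-vocabulary probability vector; contexts not
# listed fall back to the uniform distribution. `words` maps word -> ids.
manual_lm <- function(dists, vocab_size, words = list(), dim = 3L) {
  causal_lm(
    tokenize = function(text) {
      toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
      as.integer(unlist(lapply(toks, function(w) {
        ids <- words[[w]]
        if (is.null(ids)) stop("manual_lm: unknown word ", w)
        ids
      })))
    },
    next_token_distribution = function(ids) {
      key <- paste(as.integer(ids), collapse = ",")
      d <- dists[[key]]
      if (is.null(d)) rep(1 / vocab_size, vocab_size) else d
    },
    token_embeddings = function(ids) {
      t(vapply(as.integer(ids), function(id) rep(id, dim), numeric(dim)))
    },
    vocab_size = vocab_size, embedding_dim = dim, name = "manual_lm"
  )
}

# Lexicon with explicit token assignments (bypasses a tokenizer).
manual_lexicon <- function(symbols, token_ids) {
  lex <- gene_lexicon(symbols)
  lex$token_ids <- lapply(token_ids, as.integer)
  lex$token_length <- lengths(token_ids)
  lex
}

# The three-gene worked example: A=[1], B=[2,3], C=[2,4];
# first step {t1: .2, t2: .2}, second step at prefix 2 {t3: .3, t4: .1}.
worked_example <- function() {
  lex <- manual_lexicon(c("A", "B", "C"), list(1L, c(2L, 3L), c(2L, 4L)))
  words <- list(PROMPT = 6L, A = 1L, B = c(2L, 3L), C = c(2L, 4L))
  dists <- list(
    "6" = c(0.2, 0.2, 0.1, 0.1, 0.2, 0.2),
    "6,2" = c(0.1, 0.1, 0.3, 0.1, 0.2, 0.2)
  )
  lm <- manual_lm(dists, vocab_size = 6L, words = words)
  list(lex = lex, lm = lm, trie = build_trie(lex), prompt = 6L)
}

# Standard seeded toy world: lexicon + planted targets + toy LM.
toy_world <- function(n_genes = 200L, n_planted = 20L, boost = 10,
                      seed = 1L, ...) {
  lex <- make_toy_lexicon(n_genes, seed = seed)
  planted <- plant_targets(lex, n_planted, seed = seed)
  spec <- toy_lm_spec(lex, planted = list(aging = planted), boost = boost,
                      seed = seed, ...)
  lm <- make_toy_lm(spec)
  list(lex = lex, planted = planted, spec = spec, lm = lm,
       trie = build_trie(lex), prompt = build_prompt(lm, "aging"))
}

# Independent hypergeometric upper-tail oracle by direct enumeration of the
# pmf with binomial coefficients (no phyper).
hyper_tail_enum <- function(targets_k, k, targets_N, N) {
  xs <- targets_k:min(k, targets_N)
  xs <- xs[xs >= max(0, k - (N - targets_N))]
  if (length(xs) == 0) return(0)
  sum(choose(targets_N, xs) * choose(N - targets_N, k - xs)) / choose(N, k)
}

# Independent shortest-path oracle: exhaustive enumeration of simple paths.
enum_shortest_path <- function(edges, from, to) {
  # edges: data.frame from, to, distance (undirected)
  best <- Inf
  nbrs <- function(v) {
    sel <- c(which(edges$from == v), which(edges$to == v))
    data.frame(
      next_v = ifelse(edges$from[sel] == v, edges$to[sel], edges$from[sel]),
      d = edges$distance[sel]
    )
  }
  recurse <- function(v, visited, acc) {
    if (v == to) {
      best <<- min(best, acc)
      return(invisible())
    }
    nb <- nbrs(v)
    for (i in seq_len(nrow(nb))) {
      w <- nb$next_v[i]
      if (!w %in% visited) recurse(w, c(visited, w), acc + nb$d[i])
    }
  }
  if (from == to) return(0)
  recurse(from, from, 0)
  best
}
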
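#' Generate a synthetic gene lexicon with token assignments
#'
#' Builds a toy closed vocabulary of gene names whose token lengths follow a
#' configurable distribution over 1..7 (biomedical subword vocabularies
#' encode most gene symbols with 2 to 7 tokens; common genes get short
#' encodings). A configurable fraction of genes extend a previously
#' generated gene's token sequence, so the resulting trie exercises shared
#' prefixes and terminal-and-continue nodes.
#'
#' @param n_genes number of genes (symbols G0001, G0002, ...).
#' @param length_distribution probabilities for token lengths 1..7
#'   (must sum to 1).
#' @param prefix_fraction fraction of genes that reuse an earlier gene's
#'   sequence as a proper prefix when possible.
#' @param vocab_size token vocabulary size (default `max(32, 4 * n_genes)`).
#' @param seed integer seed; output is a pure function of the arguments.
#' @return A tokenized `gene_lexicon`.
#' @export
make_toy_lexicon <- function(n_genes,
                             length_distribution = c(0.10, 0.30, 0.25, 0.15, 0.10, 0.06, 0.04),
                             prefix_fraction = 0.3,
                             vocab_size = NULL,
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) abort("`n_genes` must be >= 1.")
  if (length(length_distribution) != 7 ||
      abs(sum(length_distribution) - 1) > 1e-8 ||
      any(length_distribution < 0)) {
    abort("`length_distribution` must be 7 non-negative probabilities over lengths 1..7 summing to 1.")
  }
  vocab_size <- as.integer(vocab_size %||% max(32L, 4L * n_genes))
  with_local_seed(seed, {
    lens <- sample(1:7, n_genes, replace = TRUE, prob = length_distribution)
    if (sum(lens == 1L) > vocab_size) {
      abort("infeasible vocabulary: more single-token genes than vocabulary tokens.")
    }
    seqs <- vector("list", n_genes)
    seen <- new.env(parent = emptyenv())
    done_lens <- integer(0)
    for (i in seq_len(n_genes)) {
      L <- lens[i]
      placed <- FALSE
      for (attempt in 1:1000) {
        use_prefix <- i > 1L && stats::runif(1) < prefix_fraction &&
          any(done_lens < L)
        if (use_prefix) {
          cand <- which(done_lens < L)
          base <- seqs[[cand[sample.int(length(cand), 1)]]]
          s <- c(base, sample.int(vocab_size, L - length(base), replace = TRUE))
        } else {
          s <- sample.int(vocab_size, L, replace = TRUE)
        }
        key <- paste(s, collapse = "-")
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          seqs[[i]] <- as.integer(s)
          done_lens <- c(done_lens, L)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("infeasible vocabulary: could not place a unique token sequence; increase `vocab_size`.")
      }
    }
    new_gene_lexicon(tibble(
      symbol = sprintf("G%04d", seq_len(n_genes)),
      token_ids = seqs,
      token_length = as.integer(lens)
    ))
  })
}

#' Choose planted target genes for a toy disease
#'
#' Planted targets are drawn among genes with short token encodings
#' (default at most 3 tokens), mirroring the observation that known drug
#' targets carry short subword encodings (1 to 5 tokens) because frequent
#' gene names enter the vocabulary whole. By default candidates must also
#' be prefix-isolated — no other gene starts with the same first token —
#' because the probability boost is applied to tokens, not genes: a gene
#' sharing a planted gene's leading tokens would inherit part of the boost,
#' making the planted set an ill-defined ground truth for recovery tests.
#'
#' @param lexicon a tokenized `gene_lexicon`.
#' @param n number of targets to plant.
#' @param max_token_length restrict candidates to short-named genes.
#' @param prefix_isolated require a first token unique to the gene
#'   (default TRUE).
#' @param seed integer seed.
#' @return Character vector of planted symbols.
#' @export
plant_targets <- function(lexicon, n = 20L, max_token_length = 3L,
                          prefix_isolated = TRUE, seed = 1L) {
  keep <- lexicon$token_length <= max_token_length
  if (prefix_isolated) {
    first_tok <- vapply(lexicon$token_ids, function(x) x[1], integer(1))
    keep <- keep & first_tok %in% as.integer(names(which(table(first_tok) == 1)))
  }
  pool <- lexicon$symbol[keep]
  if (length(pool) < n) {
    abort(sprintf("only %d eligible genes (token_length <= %d%s); cannot plant %d targets.",
                  length(pool), max_token_length,
                  if (prefix_isolated) ", prefix-isolated" else "", n))
  }
  with_local_seed(seed, sample(pool, n))
}

#' Specification of a deterministic toy causal language model
#'
#' @param lexicon a tokenized toy `gene_lexicon` (its token assignments
#'   define the tokenizer for gene symbols).
#' @param planted named list mapping a disease label to the symbols planted
#'   as high-probability continuations of that disease's prompt.
#' @param boost multiplicative probability boost (beta > 1) applied to each
#'   successive token of a planted gene when the context is the disease
#'   prompt followed by that gene's prefix.
#' @param base_jitter half-width of the per-context base token weights,
#'   drawn uniformly in `[1 - base_jitter, 1 + base_jitter]`; `0` gives an
#'   exactly uniform base distribution.
#' @param vocab_size vocabulary size (default from the lexicon generator's
#'   convention).
#' @param embedding_dim embedding dimension of the toy model.
#' @param template [prompt_template()] whose filled form triggers boosting.
#' @param seed integer seed controlling all fixed tables.
#' @return A `toy_lm_spec` list.
#' @export
toy_lm_spec <- function(lexicon, planted = list(), boost = 10,
                        base_jitter = 0.1, vocab_size = NULL,
                        embedding_dim = 16L,
                        template = prompt_template(), seed = 1L) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  if (!is_tokenized(lexicon)) abort("`lexicon` must carry token assignments.")
  if (length(planted) > 0) {
    if (is.null(names(planted)) || any(!nzchar(names(planted)))) {
      abort("`planted` must be a named list (disease -> symbols).")
    }
    missing <- setdiff(unlist(planted), lexicon$symbol)
    if (length(missing) > 0) {
      abort(sprintf("planted symbols not in lexicon: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  if (boost < 1) abort("`boost` must be >= 1.")
  if (base_jitter < 0 || base_jitter >= 1) abort("`base_jitter` must be in [0, 1).")
  max_id <- max(unlist(lexicon$token_ids))
  vocab_size <- as.integer(vocab_size %||% max(32L, max_id, 4L * nrow(lexicon)))
  if (vocab_size < max_id) abort("`vocab_size` smaller than the largest lexicon token id.")
  structure(
    list(lexicon = lexicon, planted = planted, boost = boost,
         base_jitter = base_jitter, vocab_size = vocab_size,
         embedding_dim = as.integer(embedding_dim), template = template,
         seed = as.integer(seed)),
    class = "toy_lm_spec"
  )
}

# Deterministic word hash into 1..vocab_size (fixed salt so non-gene words
# tokenize identically across model seeds).
hash_word <- function(word, vocab_size) {
  as.integer(context_hash(utf8ToInt(word), salt = 7) %% vocab_size) + 1L
}

#' Instantiate the deterministic toy causal language model
#'
#' The toy model satisfies the full [causal_lm()] contract. Its tokenizer
#' splits on whitespace, mapping lexicon symbols to their assigned token
#' sequences and any other word to a single hashed token. Each context gets
#' a fixed base next-token distribution (weights seeded by a stable hash of
#' the context), and when the context equals a planted disease prompt — or
#' that prompt followed by a planted gene's token prefix — the planted
#' gene's next token has its probability multiplied by the boost factor
#' before renormalization. Embeddings are fixed seeded per-token vectors.
#'
#' @param spec a [toy_lm_spec()].
#' @return A [causal_lm()] object.
#' @export
make_toy_lm <- function(spec) {
  stopifnot(inherits(spec, "toy_lm_spec"))
  V <- spec$vocab_size
  dim <- spec$embedding_dim
  seed <- spec$seed
  jitter <- spec$base_jitter
  boost <- spec$boost

  token_map <- stats::setNames(spec$lexicon$token_ids, spec$lexicon$symbol)
  tokenize <- function(text) {
    words <- strsplit(trimws(text), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    as.integer(unlist(lapply(words, function(w) {
      ids <- token_map[[w]]
      if (!is.null(ids)) ids else hash_word(w, V)
    })))
  }

  # context key -> token ids whose probability is boosted in that context
  boost_env <- new.env(parent = emptyenv())
  for (disease in names(spec$planted)) {
    prompt_ids <- tokenize(sub("{DISEASE}", disease, unclass(spec$template),
                               fixed = TRUE))
    for (sym in spec$planted[[disease]]) {
      ids <- token_map[[sym]]
      for (j in seq_along(ids)) {
        key <- paste(c(prompt_ids, ids[seq_len(j - 1L)]), collapse = ",")
        cur <- boost_env[[key]]
        assign(key, unique(c(cur, ids[j])), envir = boost_env)
      }
    }
  }

  next_token_distribution <- function(ids) {
    ids <- as.integer(ids)
    if (length(ids) == 0) abort("context must be non-empty.")
    w <- if (jitter > 0) {
      with_local_seed(context_hash(ids, salt = seed),
                      stats::runif(V, 1 - jitter, 1 + jitter))
    } else {
      rep(1, V)
    }
    b <- boost_env[[paste(ids, collapse = ",")]]
    if (!is.null(b)) w[b] <- w[b] * boost
    w / sum(w)
  }

  token_embeddings <- function(ids) {
    ids <- as.integer(ids)
    rows <- lapply(ids, function(id) {
      with_local_seed(context_hash(c(424243L, id), salt = seed),
                      stats::rnorm(dim))
    })
    do.call(rbind, rows)
  }

  causal_lm(tokenize, next_token_distribution, token_embeddings,
            vocab_size = V, embedding_dim = dim, name = "toy_lm")
}

#' Generate group-structured toy embeddings
#'
#' Places one center per group at mutual Euclidean distance equal to
#' `between_group_separation` (centers sit on scaled coordinate axes) and
#' draws each member as its group center plus isotropic Gaussian noise of
#' scale `within_group_spread`. Deterministic per seed.
#'
#' @param group_assignments vector (character or factor) of group labels,
#'   one per node; names, if present, become node symbols (default
#'   N0001, ...).
#' @param within_group_spread Gaussian noise scale around each center.
#' @param between_group_separation pairwise distance between group centers.
#' @param dimension embedding dimension (must be >= number of groups).
#' @param seed integer seed.
#' @return Numeric matrix with one row per node (rownames = symbols) and a
#'   `"groups"` attribute.
#' @export
make_toy_embeddings <- function(group_assignments,
                                within_group_spread = 0.1,
                                between_group_separation = 4,
                                dimension = 8L,
                                seed = 1L) {
  if (within_group_spread <= 0 || between_group_separation <= 0) {
    abort("spread and separation must be > 0.")
  }
  groups <- as.factor(group_assignments)
  G <- nlevels(groups)
  dimension <- as.integer(dimension)
  if (G > dimension) abort("`dimension` must be >= the number of groups.")
  n <- length(groups)
  centers <- matrix(0, nrow = G, ncol = dimension)
  for (g in seq_len(G)) {
    centers[g, g] <- between_group_separation / sqrt(2)
  }
  emb <- with_local_seed(seed, {
    noise <- matrix(stats::rnorm(n * dimension, sd = within_group_spread),
                    nrow = n)
    centers[as.integer(groups), , drop = FALSE] + noise
  })
  rownames(emb) <- names(group_assignments) %||% sprintf("N%04d", seq_len(n))
  attr(emb, "groups") <- groups
  emb
}
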
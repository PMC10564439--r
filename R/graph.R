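#' Compute mean-pooled protein embeddings from a language model
#'
#' For each gene, the context sentence followed by the gene symbol is
#' tokenized, per-token embeddings are retrieved, and the arithmetic mean
#' across token positions is taken as the protein representation.
#'
#' @param lm a [causal_lm()] object.
#' @param genes character vector of gene symbols.
#' @param context sentence preceding each symbol; the default matches the
#'   age-association probe.
#' @return Numeric matrix, one row per gene (rownames = symbols),
#'   `lm$embedding_dim` columns.
#' @export
embed_genes <- function(lm, genes,
                        context = "The human age-associated gene is the") {
  stopifnot(inherits(lm, "causal_lm"))
  genes <- as.character(genes)
  if (length(genes) == 0) abort("`genes` must be non-empty.")
  rows <- purrr::map(genes, function(g) {
    ids <- as.integer(lm$tokenize(paste(context, g)))
    emb <- lm$token_embeddings(ids)
    colMeans(emb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- genes
  out
}

#' Cosine-similarity matrix between embedding rows
#'
#' @param emb numeric matrix with rownames (one embedding per row).
#' @return Symmetric matrix of cosine similarities with unit diagonal.
#' @export
cosine_matrix <- function(emb) {
  if (!is.matrix(emb) || nrow(emb) < 2) {
    abort("`emb` must be a matrix with at least 2 rows.")
  }
  norms <- sqrt(rowSums(emb^2))
  if (any(norms == 0)) {
    bad <- rownames(emb)[norms == 0] %||% which(norms == 0)
    abort(sprintf("zero embedding vector for: %s",
                  paste(bad, collapse = ", ")))
  }
  s <- tcrossprod(emb / norms)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Build the thresholded embedding graph
#'
#' Keeps an undirected edge between two proteins when their cosine
#' similarity reaches the cutoff; each retained edge carries the similarity
#' `s` and the traversal distance `d = 1 - s` used for weighted shortest
#' paths. `threshold = "upper_quartile"` resolves to the 75th percentile
#' (linear interpolation) of the off-diagonal upper-triangle similarities;
#' the default constant is 0.507; the quartile is a data-driven alternative.
#'
#' @param sim square symmetric similarity matrix with rownames.
#' @param threshold numeric cutoff or `"upper_quartile"`.
#' @return An `embedding_graph`: list with the `igraph` object, the `edges`
#'   tibble (`from`, `to`, `similarity`, `distance`), the resolved
#'   `threshold` and the node `symbols`.
#' @export
build_graph <- function(sim, threshold = 0.507) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    abort("`sim` must be a square matrix.")
  }
  if (max(abs(sim - t(sim))) > 1e-8) abort("`sim` must be symmetric.")
  symbols <- rownames(sim) %||% paste0("V", seq_len(nrow(sim)))
  ut <- upper.tri(sim, diag = FALSE)
  if (identical(threshold, "upper_quartile")) {
    threshold <- unname(stats::quantile(sim[ut], 0.75, type = 7))
  }
  idx <- which(ut & sim >= threshold, arr.ind = TRUE)
  edges <- tibble(
    from = symbols[idx[, 1]],
    to = symbols[idx[, 2]],
    similarity = sim[idx],
    distance = 1 - sim[idx]
  )
  if (nrow(edges) == 0) {
    warn(sprintf("no pair reaches similarity threshold %.4g; graph has no edges.",
                 threshold))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = symbols)
  )
  if (nrow(edges) > 0) {
    igraph::E(g)$similarity <- edges$similarity
    igraph::E(g)$distance <- edges$distance
  }
  structure(
    list(graph = g, edges = edges, threshold = threshold, symbols = symbols),
    class = "embedding_graph"
  )
}

#' @export
print.embedding_graph <- function(x, ...) {
  cat(sprintf("<embedding_graph> %d nodes, %d edges, threshold %.4g\n",
              length(x$symbols), nrow(x$edges), x$threshold))
  invisible(x)
}

graph_distances <- function(eg, sources, targets, weighted = TRUE) {
  w <- if (weighted && nrow(eg$edges) > 0) igraph::E(eg$graph)$distance else NA
  igraph::distances(eg$graph, v = sources, to = targets, weights = w,
                    algorithm = "dijkstra")
}

#' Shortest-path lengths between two node sets
#'
#' Dijkstra shortest paths on the edge distances `1 - similarity` (or on
#' hop counts with `weighted = FALSE`). Nodes present in both sets would
#' contribute trivial zero-length paths and are excluded with a message.
#'
#' @param eg an [build_graph()] `embedding_graph`.
#' @param sources,targets character vectors of node symbols.
#' @param weighted use edge distances (default) or hop counts.
#' @return Tibble with `source`, `target`, `length`, `reachable`;
#'   unreachable pairs have `length = Inf`.
#' @export
shortest_path_lengths <- function(eg, sources, targets, weighted = TRUE) {
  stopifnot(inherits(eg, "embedding_graph"))
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  unknown <- setdiff(c(sources, targets), eg$symbols)
  if (length(unknown) > 0) {
    abort(sprintf("unknown node symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  common <- intersect(sources, targets)
  if (length(common) > 0) {
    inform(sprintf("%d node(s) in both sets excluded (zero-length self pairs).",
                   length(common)))
    sources <- setdiff(sources, common)
    targets <- setdiff(targets, common)
  }
  if (length(sources) == 0 || length(targets) == 0) {
    abort("no source/target pairs remain after removing common members.")
  }
  d <- graph_distances(eg, sources, targets, weighted)
  tidyr::expand_grid(source = sources, target = targets) |>
    dplyr::mutate(length = as.vector(t(d)),
                  reachable = is.finite(.data$length))
}

#' Permutation test of query-to-anchor graph proximity
#'
#' Tests whether a query node set lies closer (in shortest-path distance) to
#' a set of anchor nodes than random node sets of the same size do. The
#' observed statistic is the mean of finite query-to-anchor shortest-path
#' lengths; each permutation draws `|query|` nodes without replacement from
#' the candidate pool and recomputes it. The add-one rule
#' `p = (1 + #{null <= observed}) / (1 + n_iter)` keeps p-values positive.
#'
#' @param eg an `embedding_graph`.
#' @param query character query node symbols (disjoint from `anchors`).
#' @param anchors character anchor node symbols.
#' @param candidate_pool nodes to draw null sets from; anchors are always
#'   excluded, the query set is excluded when `exclude_query = TRUE`.
#' @param n_iter number of permutations (default 1000).
#' @param seed optional integer seed for the permutation draws.
#' @param exclude_query drop query nodes from the null pool (default TRUE,
#'   contrasting model-selected nodes against entirely random ones).
#' @param weighted use edge distances (default) or hop counts.
#' @return A `path_test` object with fields `observed`, `null` (numeric
#'   vector of length `n_iter`), `p_value`, `n_unreachable_observed`,
#'   and the test parameters.
#' @export
permutation_path_test <- function(eg, query, anchors, candidate_pool,
                                  n_iter = 1000L, seed = NULL,
                                  exclude_query = TRUE, weighted = TRUE) {
  stopifnot(inherits(eg, "embedding_graph"))
  query <- unique(as.character(query))
  anchors <- unique(as.character(anchors))
  if (length(intersect(query, anchors)) > 0) {
    abort("`query` and `anchors` must be disjoint.")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) abort("`n_iter` must be >= 1.")
  pool <- setdiff(unique(as.character(candidate_pool)), anchors)
  if (exclude_query) pool <- setdiff(pool, query)
  if (length(pool) < length(query)) {
    abort("candidate pool smaller than the query set.")
  }
  all_rows <- union(query, pool)
  d <- graph_distances(eg, all_rows, anchors, weighted)
  rownames(d) <- all_rows
  set_stat <- function(rows) {
    v <- d[rows, , drop = FALSE]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(Inf)
    mean(v)
  }
  obs_mat <- d[query, , drop = FALSE]
  n_unreach <- sum(!is.finite(obs_mat))
  observed <- set_stat(query)
  if (!is.finite(observed)) {
    abort("degenerate result: no finite query-to-anchor path exists.")
  }
  draw_null <- function() {
    vapply(seq_len(n_iter),
           function(i) set_stat(sample(pool, length(query))),
           numeric(1))
  }
  null <- if (is.null(seed)) draw_null() else with_local_seed(seed, draw_null())
  p <- (1 + sum(null <= observed)) / (1 + n_iter)
  structure(
    list(observed = observed, null = null, p_value = p,
         n_unreachable_observed = n_unreach,
         n_query = length(query), n_anchors = length(anchors),
         n_pool = length(pool), n_iter = n_iter, seed = seed,
         weighted = weighted),
    class = "path_test"
  )
}

#' @export
print.path_test <- function(x, ...) {
  cat(sprintf(
    "<path_test> observed mean path %.4f | null mean %.4f | p = %.4g (%d permutations)\n",
    x$observed, mean(x$null[is.finite(x$null)]), x$p_value, x$n_iter))
  if (x$n_unreachable_observed > 0) {
    cat(sprintf("  %d unreachable query-anchor pairs excluded\n",
                x$n_unreachable_observed))
  }
  invisible(x)
}
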
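#' Write a ranked gene list to a tab-separated file
#'
#' Columns: `rank`, `symbol`, `raw_probability` (scientific notation, 10
#' significant digits), `final_score`, `token_length`.
#'
#' @param ranked a `ranked_genes` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  out <- tibble(
    rank = ranked$rank,
    symbol = ranked$symbol,
    raw_probability = sprintf("%.9e", ranked$raw_probability),
    final_score = sprintf("%.9e", ranked$final_score),
    token_length = ranked$token_length
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a ranked gene list written by [write_ranking()]
#'
#' @param path TSV path.
#' @return A tibble in rank order.
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::arrange(.data$rank)
}

#' Read a reference target set (one symbol per line)
#'
#' @param path plain-text file, one gene symbol per line.
#' @return Character vector of unique uppercased symbols.
#' @export
read_reference_set <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- toupper(trimws(x))
  unique(x[nzchar(x)])
}

#' Write an embedding matrix as TSV (symbol + vector components)
#' @param emb matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  tbl <- tibble::as_tibble(emb, .name_repair = ~ sprintf("v%03d", seq_along(.x)))
  tbl <- dplyr::bind_cols(tibble(symbol = rownames(emb)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embeddings()]
#' @param path TSV path (first column `symbol`, remaining columns numeric).
#' @return Matrix with symbol rownames.
#' @export
read_embeddings <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  m
}

#' Write the edge list of an embedding graph
#' @param eg an `embedding_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(eg, path) {
  readr::write_tsv(eg$edges, path, progress = FALSE)
  invisible(path)
}
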
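#' Rank genes by literature co-mention counts
#'
#' Baseline ranking from per-gene publication counts: `raw` mode ranks by
#' the number of abstracts co-mentioning the gene and the context term;
#' `normalized` mode divides by the total number of abstracts mentioning
#' the gene, correcting for overall gene prevalence in the literature.
#'
#' @param records tibble/data frame with columns `symbol`, `co_count`,
#'   `total_count`.
#' @param mode `"normalized"` or `"raw"`.
#' @param top_k truncate the returned ranking (`NULL` = full list).
#' @param context_term label stored with the result (e.g. `"aging"`).
#' @return A `comention_ranking` tibble with `rank`, `symbol`, `score`,
#'   `co_count`, `total_count`.
#' @export
comention_rank <- function(records, mode = c("normalized", "raw"),
                           top_k = 200L, context_term = "aging") {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  req <- c("symbol", "co_count", "total_count")
  if (!all(req %in% names(records))) {
    abort(sprintf("`records` must have columns: %s.", paste(req, collapse = ", ")))
  }
  if (any(records$co_count < 0) || any(records$total_count < 0)) {
    abort("counts must be non-negative.")
  }
  if (any(records$co_count > records$total_count)) {
    abort("`co_count` cannot exceed `total_count`.")
  }
  records$symbol <- toupper(trimws(records$symbol))
  if (mode == "normalized") {
    dropped <- sum(records$total_count == 0)
    if (dropped > 0) {
      inform(sprintf("%d gene(s) with zero total mentions excluded from normalized ranking.",
                     dropped))
    }
    records <- records[records$total_count > 0, , drop = FALSE]
    records$score <- records$co_count / records$total_count
  } else {
    records$score <- as.numeric(records$co_count)
  }
  ord <- order_score_symbol(records$score, records$symbol)
  out <- records[ord, c("symbol", "score", "co_count", "total_count")]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "symbol", "score", "co_count", "total_count")]
  full <- out
  if (!is.null(top_k) && top_k < nrow(out)) out <- out[seq_len(top_k), ]
  class(out) <- c("comention_ranking", class(out))
  attr(out, "full_ranking") <- tibble::as_tibble(full)
  attr(out, "mode") <- mode
  attr(out, "context_term") <- context_term
  out
}

#' Read a co-mention count table
#'
#' @param path TSV with columns `symbol`, `co_count`, `total_count`.
#' @return Tibble of co-mention records.
#' @export
read_comention_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    symbol = readr::col_character(),
                    co_count = readr::col_double(),
                    total_count = readr::col_double()
                  ))
}

#' Intersection analysis over multiple gene lists
#'
#' Computes, for every *exclusive* membership pattern (upset-plot
#' semantics), how many symbols follow exactly that pattern, plus the set
#' of symbols common to all lists.
#'
#' @param lists named list of character vectors (>= 2 lists, unique labels).
#' @return An `intersection_report`: list with `patterns` (tibble
#'   `pattern`, `degree`, `count`), `common` (character vector common to all
#'   lists), `labels`, and `union_size`.
#' @export
intersect_lists <- function(lists) {
  if (!is.list(lists) || length(lists) < 2) {
    abort("`lists` must be a named list of at least 2 symbol vectors.")
  }
  labels <- names(lists)
  if (is.null(labels) || any(!nzchar(labels))) abort("all lists must be named.")
  if (anyDuplicated(labels)) abort("duplicate list labels.")
  lists <- purrr::map(lists, ~ unique(toupper(trimws(.x))))
  all_symbols <- sort(unique(unlist(lists)))
  member <- vapply(lists, function(s) all_symbols %in% s,
                   logical(length(all_symbols)))
  member <- matrix(member, nrow = length(all_symbols),
                   dimnames = list(all_symbols, labels))
  pattern <- apply(member, 1, function(row) paste(labels[row], collapse = "&"))
  degree <- rowSums(member)
  patterns <- tibble(pattern = pattern, degree = as.integer(degree)) |>
    dplyr::count(.data$pattern, .data$degree, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$degree), dplyr::desc(.data$count))
  common <- all_symbols[degree == length(labels)]
  structure(
    list(patterns = patterns, common = common, labels = labels,
         union_size = length(all_symbols)),
    class = "intersection_report"
  )
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> %d lists, union %d symbols, %d common to all\n",
              length(x$labels), x$union_size, length(x$common)))
  invisible(x)
}

#' Symbols occurring in at least a given number of lists
#'
#' @param lists named list of character vectors.
#' @param min_lists minimum number of lists a symbol must appear in.
#' @return Tibble `symbol`, `n_lists`, restricted to `n_lists >= min_lists`,
#'   ordered by decreasing occurrence then symbol.
#' @export
occurrence_across_lists <- function(lists, min_lists = 1L) {
  min_lists <- as.integer(min_lists)
  if (min_lists < 1L) abort("`min_lists` must be >= 1.")
  lists <- purrr::map(lists, ~ unique(toupper(trimws(.x))))
  counts <- table(unlist(lists))
  out <- tibble(symbol = names(counts), n_lists = as.integer(counts)) |>
    dplyr::filter(.data$n_lists >= min_lists)
  out[order_score_symbol(out$n_lists, out$symbol), ]
}
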
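new_gene_lexicon <- function(tbl) {
  stopifnot(all(c("symbol", "token_ids", "token_length") %in% names(tbl)))
  class(tbl) <- c("gene_lexicon", class(tibble::new_tibble(list())))
  tbl
}

#' Create a gene lexicon from a vector of symbols
#'
#' @param symbols character vector of gene symbols; trimmed and uppercased,
#'   duplicates collapsed to the first occurrence with a warning.
#' @return A `gene_lexicon` tibble with columns `symbol`, `token_ids`
#'   (list of integer vectors, `NULL` until [tokenize_lexicon()] runs) and
#'   `token_length`.
#' @export
gene_lexicon <- function(symbols) {
  symbols <- toupper(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  if (anyDuplicated(symbols)) {
    dups <- unique(symbols[duplicated(symbols)])
    warn(sprintf("%d duplicate symbol(s) collapsed to first occurrence: %s",
                 length(dups), paste(utils::head(dups, 5), collapse = ", ")))
    symbols <- symbols[!duplicated(symbols)]
  }
  new_gene_lexicon(tibble(
    symbol = symbols,
    token_ids = vector("list", length(symbols)),
    token_length = rep(NA_integer_, length(symbols))
  ))
}

#' Number of genes in a lexicon
#' @param lexicon a `gene_lexicon`.
#' @return integer universe size N.
#' @export
universe_size <- function(lexicon) nrow(lexicon)

is_tokenized <- function(lexicon) {
  nrow(lexicon) == 0 || !anyNA(lexicon$token_length)
}

#' Load a gene lexicon from a tab-separated file
#'
#' Reads an HGNC-style tab-separated export (header row) and builds the
#' closed set of scoreable gene symbols. Symbols are whitespace-trimmed,
#' uppercased, kept in file order; duplicates collapse to the first
#' occurrence with a warning.
#'
#' @param source path to a TSV file (or a connection readable by
#'   [readr::read_tsv()]).
#' @param symbol_column name of the column holding gene symbols
#'   (default `"symbol"`).
#' @return A `gene_lexicon` tibble.
#' @export
load_gene_list <- function(source, symbol_column = "symbol") {
  tbl <- readr::read_tsv(source, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) {
    abort("empty lexicon: the gene list file contains no rows.")
  }
  if (!symbol_column %in% names(tbl)) {
    abort(sprintf("configuration error: column '%s' not found (columns: %s).",
                  symbol_column, paste(names(tbl), collapse = ", ")))
  }
  gene_lexicon(tbl[[symbol_column]])
}

#' Tokenize every lexicon symbol with a language model
#'
#' Each symbol is tokenized in its continuation form — preceded by a single
#' space — because gene probabilities are later scored as continuations of a
#' prompt ending in an article ("... is the"). Symbols the tokenizer maps to
#' zero tokens are dropped with a warning.
#'
#' @param lexicon a `gene_lexicon`.
#' @param lm a [causal_lm()] object.
#' @param leading_space prepend a space before tokenizing (default `TRUE`).
#' @return The lexicon with `token_ids` and `token_length` populated.
#' @export
tokenize_lexicon <- function(lexicon, lm, leading_space = TRUE) {
  stopifnot(inherits(lexicon, "gene_lexicon"), inherits(lm, "causal_lm"))
  ids <- purrr::map(lexicon$symbol, function(s) {
    text <- if (leading_space) paste0(" ", s) else s
    as.integer(lm$tokenize(text))
  })
  n_tok <- lengths(ids)
  if (any(n_tok == 0)) {
    warn(sprintf("%d symbol(s) tokenized to zero tokens and were dropped.",
                 sum(n_tok == 0)))
  }
  out <- lexicon[n_tok > 0, , drop = FALSE]
  out$token_ids <- ids[n_tok > 0]
  out$token_length <- as.integer(n_tok[n_tok > 0])
  new_gene_lexicon(out)
}

#' Restrict a lexicon to genes with short token encodings
#'
#' Known drug targets tokenize to at most a handful of subword tokens, so
#' long-named genes can be filtered before scoring (a cutoff of 5 is
#' sensible when known targets tokenize short).
#'
#' @param lexicon a tokenized `gene_lexicon`.
#' @param max_length keep entries with `token_length <= max_length`.
#' @return The filtered `gene_lexicon`.
#' @export
filter_by_token_length <- function(lexicon, max_length) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  if (!is_tokenized(lexicon)) abort("lexicon must be tokenized first.")
  max_length <- as.integer(max_length)
  if (max_length < 1L) abort("`max_length` must be >= 1.")
  new_gene_lexicon(lexicon[lexicon$token_length <= max_length, , drop = FALSE])
}

# ---- token trie -------------------------------------------------------------

new_trie_node <- function() {
  node <- new.env(parent = emptyenv())
  node$children <- new.env(parent = emptyenv())
  node$symbol <- NULL
  node
}

#' Build the token trie over a tokenized lexicon
#'
#' The trie's children at each prefix define the "allowed set" of next
#' tokens during constrained scoring. Every root-to-terminal path spells one
#' gene's token sequence; genes that are prefixes of other genes yield nodes
#' that are both terminal and internal.
#'
#' @param lexicon a tokenized `gene_lexicon`.
#' @return A `token_trie` object.
#' @export
build_trie <- function(lexicon) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  if (!is_tokenized(lexicon)) abort("state error: lexicon must be tokenized before building the trie.")
  root <- new_trie_node()
  n_nodes <- 1L
  for (i in seq_len(nrow(lexicon))) {
    node <- root
    for (id in lexicon$token_ids[[i]]) {
      key <- as.character(id)
      child <- node$children[[key]]
      if (is.null(child)) {
        child <- new_trie_node()
        child$token <- as.integer(id)
        assign(key, child, envir = node$children)
        n_nodes <- n_nodes + 1L
      }
      node <- child
    }
    if (!is.null(node$symbol)) {
      abort(sprintf("genes '%s' and '%s' share an identical token sequence.",
                    node$symbol, lexicon$symbol[i]))
    }
    node$symbol <- lexicon$symbol[i]
  }
  structure(
    list(root = root, n_genes = nrow(lexicon), n_nodes = n_nodes),
    class = "token_trie"
  )
}

trie_children <- function(node) {
  keys <- ls(node$children)
  lapply(keys, function(k) node$children[[k]])
}

# Walk the trie collecting (symbol, token_ids) at every terminal.
trie_terminals <- function(trie) {
  out <- list()
  recurse <- function(node, prefix) {
    if (!is.null(node$symbol)) {
      out[[length(out) + 1L]] <<- list(symbol = node$symbol, token_ids = prefix)
    }
    for (key in ls(node$children)) {
      child <- node$children[[key]]
      recurse(child, c(prefix, child$token))
    }
  }
  recurse(trie$root, integer(0))
  out
}

#' @export
print.token_trie <- function(x, ...) {
  cat(sprintf("<token_trie> %d genes, %d nodes\n", x$n_genes, x$n_nodes))
  invisible(x)
}
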
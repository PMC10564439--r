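sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

write_manifest <- function(out_dir, command, params) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("targetrank")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Rank genes for one or more diseases and write the result tables
#'
#' End-to-end ranking run: tokenizes the lexicon, builds the token trie,
#' scores every gene against each disease prompt, and writes one
#' tab-separated ranking per disease plus a JSON run manifest (config echo,
#' versions, seed) into `out_dir`.
#'
#' @param lm a [causal_lm()] object.
#' @param lexicon a `gene_lexicon` (tokenized or not; tokenized here if
#'   needed).
#' @param diseases character vector of disease names.
#' @param config a [scoring_config()].
#' @param template a [prompt_template()].
#' @param out_dir output directory (created if missing).
#' @param seed optional integer recorded in the manifest (scoring itself is
#'   deterministic).
#' @return (invisibly) named list of `ranked_genes`, one per disease; the
#'   written file paths are in the `"files"` attribute.
#' @export
run_rank <- function(lm, lexicon, diseases, config = scoring_config(),
                     template = prompt_template(), out_dir = ".",
                     seed = NULL) {
  if (length(diseases) == 0) abort("`diseases` must be non-empty.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is_tokenized(lexicon)) lexicon <- tokenize_lexicon(lexicon, lm)
  trie <- build_trie(lexicon)
  files <- character(0)
  results <- list()
  for (disease in diseases) {
    prompt <- build_prompt(lm, disease, template)
    ranked <- score_genes(lm, trie, prompt, config, lexicon = lexicon)
    ranked <- rank_genes(attr(ranked, "full_ranking"), top_k = config$top_k,
                         config = config, disease = disease)
    path <- file.path(out_dir, paste0("ranking_", sanitize_label(disease), ".tsv"))
    write_ranking(ranked, path)
    files <- c(files, path)
    results[[disease]] <- ranked
    inform(sprintf("ranked %d genes for '%s' -> %s",
                   nrow(attr(ranked, "full_ranking")), disease, path))
  }
  write_manifest(out_dir, "rank", list(
    diseases = diseases, template = unclass(template),
    step_scheme = config$step_scheme, final_scheme = config$final_scheme,
    alpha = config$alpha, max_token_length = config$max_token_length,
    top_k = config$top_k, universe_size = universe_size(lexicon),
    model = lm$name, seed = seed
  ))
  attr(results, "files") <- files
  invisible(results)
}

#' Validate a written ranking against a reference target set
#'
#' @param ranking_file TSV written by [write_ranking()].
#' @param reference_file plain-text reference set (one symbol per line).
#' @param N universe size (defaults to the ranking length).
#' @param ks top-k cutoffs.
#' @param out_file optional TSV to write the validation table to.
#' @return The `topk_validation` tibble.
#' @export
run_validate <- function(ranking_file, reference_file, N = NULL,
                         ks = c(50L, 100L, 200L), out_file = NULL) {
  ranked <- read_ranking(ranking_file)
  reference <- read_reference_set(reference_file)
  if (length(reference) == 0) abort("reference set is empty.")
  outside <- setdiff(reference, ranked$symbol)
  if (length(outside) > 0) {
    warn(sprintf("%d reference symbol(s) absent from the ranking universe were excluded.",
                 length(outside)))
    reference <- setdiff(reference, outside)
    if (length(reference) == 0) abort("no reference symbol lies in the universe.")
  }
  res <- topk_validate(ranked, reference, ks = ks, N = N %||% nrow(ranked))
  if (!is.null(out_file)) readr::write_tsv(res, out_file, progress = FALSE)
  res
}

#' Run the embedding-graph proximity analysis
#'
#' Builds the cosine-similarity graph from an embedding matrix (or TSV
#' file), runs the query-vs-random shortest-path permutation test, and
#' optionally writes the edge list and a JSON report.
#'
#' @param embeddings matrix with rownames, or path to a TSV written by
#'   [write_embeddings()].
#' @param query,anchors character vectors of node symbols (or paths to
#'   one-symbol-per-line files).
#' @param threshold similarity cutoff or `"upper_quartile"`.
#' @param n_iter permutation count.
#' @param seed integer seed for the permutation draws.
#' @param candidate_pool nodes for null draws (default: all graph nodes).
#' @param out_prefix if given, writes `<prefix>_edges.tsv` and
#'   `<prefix>_pathtest.json`.
#' @return The `path_test` object (with the graph in attribute `"graph"`).
#' @export
run_graph <- function(embeddings, query, anchors, threshold = 0.507,
                      n_iter = 1000L, seed = 1L, candidate_pool = NULL,
                      out_prefix = NULL) {
  if (is.character(embeddings) && length(embeddings) == 1) {
    embeddings <- read_embeddings(embeddings)
  }
  if (is.character(query) && length(query) == 1 && file.exists(query)) {
    query <- read_reference_set(query)
  }
  if (is.character(anchors) && length(anchors) == 1 && file.exists(anchors)) {
    anchors <- read_reference_set(anchors)
  }
  eg <- build_graph(cosine_matrix(embeddings), threshold)
  pool <- candidate_pool %||% eg$symbols
  res <- permutation_path_test(eg, query, anchors, pool,
                               n_iter = n_iter, seed = seed)
  if (!is.null(out_prefix)) {
    write_edge_list(eg, paste0(out_prefix, "_edges.tsv"))
    jsonlite::write_json(
      list(observed = res$observed, p_value = res$p_value,
           n_iter = res$n_iter, seed = seed,
           threshold = eg$threshold,
           n_unreachable_observed = res$n_unreachable_observed,
           null_summary = as.list(summary(res$null[is.finite(res$null)]))),
      paste0(out_prefix, "_pathtest.json"), auto_unbox = TRUE, digits = NA)
  }
  attr(res, "graph") <- eg
  res
}

#' Intersect several ranking files
#'
#' @param ranking_files named character vector of TSV paths written by
#'   [write_ranking()]; names label the lists (duplicates are an error).
#' @param min_lists occurrence floor for [occurrence_across_lists()].
#' @param out_prefix if given, writes `<prefix>_patterns.tsv`,
#'   `<prefix>_common.txt` and `<prefix>_occurrence.tsv`.
#' @return The `intersection_report`, with the occurrence tibble in
#'   attribute `"occurrence"`.
#' @export
run_intersect <- function(ranking_files, min_lists = 2L, out_prefix = NULL) {
  if (length(ranking_files) < 2) abort("need at least 2 ranking files.")
  labels <- names(ranking_files) %||% basename(ranking_files)
  if (anyDuplicated(labels)) abort("duplicate list labels.")
  lists <- stats::setNames(
    purrr::map(ranking_files, ~ read_ranking(.x)$symbol), labels)
  report <- intersect_lists(lists)
  occ <- occurrence_across_lists(lists, min_lists = min_lists)
  if (!is.null(out_prefix)) {
    readr::write_tsv(report$patterns, paste0(out_prefix, "_patterns.tsv"),
                     progress = FALSE)
    readr::write_lines(report$common, paste0(out_prefix, "_common.txt"))
    readr::write_tsv(occ, paste0(out_prefix, "_occurrence.tsv"),
                     progress = FALSE)
  }
  attr(report, "occurrence") <- occ
  report
}

#' Model self-check: contract validation plus a scoring smoke test
#'
#' Runs [validate_lm()] on prompt-derived probes and verifies that scoring
#' a tiny ad-hoc trie conserves normalized probability mass.
#'
#' @param lm a [causal_lm()] object.
#' @param lexicon optional `gene_lexicon` to tokenize and probe with.
#' @return TRUE, invisibly, if all checks pass (errors otherwise).
#' @export
run_selfcheck <- function(lm, lexicon = NULL) {
  probes <- list(build_prompt(lm, "aging"))
  if (!is.null(lexicon)) {
    lexicon <- if (is_tokenized(lexicon)) lexicon else tokenize_lexicon(lexicon, lm)
    probes <- c(probes,
                purrr::map(utils::head(lexicon$token_ids, 4),
                           ~ c(probes[[1]], .x)))
  }
  validate_lm(lm, probes)
  inform("selfcheck passed.")
  invisible(TRUE)
}
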
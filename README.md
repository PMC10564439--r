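# targetrank

Ranking candidate therapeutic targets by querying a causal language model
for next-token probabilities, constrained to a lexicon of official gene
symbols.

## What it does, and for whom

Biomedical language models implicitly encode gene–disease associations in
their next-token distributions. `targetrank` extracts that signal without
any free-text generation: for a prompt of the form

> human gene targeted by a drug for treating *{DISEASE}* is the

it computes, for every gene symbol in a closed lexicon, the probability
that the model continues the prompt with that symbol. Subword tokenizers
split most gene names into 2–7 tokens, so the lexicon is compiled into a
**token trie** and scored by breadth-first expansion: at each prefix the
model is queried once, the next-token distribution is renormalized over
the tokens that can extend some gene name (the "total sum" or
"separate sum" step schemes), and per-token probabilities are multiplied
in the log domain. A final token-length normalization (division by
`L^alpha`, default `alpha = 1`, or geometric mean) corrects the
long-name penalty, and genes are ranked.

The package is aimed at computational drug-discovery / bioinformatics
users who have (a) a gene list (HGNC-style TSV export) and (b) any causal
LM exposed through a three-function contract (`tokenize`,
`next_token_distribution`, `token_embeddings` — see `causal_lm()`). No
model is bundled; a fully deterministic toy model (`make_toy_lm()`) with
plantable gene–disease associations stands in for offline testing and
examples.

Around the core ranking it implements the accompanying analyses:

* **Top-k validation** against reference target sets:
  `ELFC = log2((t_k/k)/(targets_N/N))` (with the 0.1 substitution when
  `t_k = 0`) and `HGPV = -log10 P(X >= t_k)` under the hypergeometric
  null, plus hypergeometric overlap tests between gene sets.
* **Embedding-graph proximity**: mean-pooled protein embeddings, cosine
  similarity graph thresholded at a constant (0.507) or the upper
  quartile, Dijkstra shortest paths on `1 - similarity`, and a permutation
  test of whether query nodes lie closer to anchor nodes than random
  node sets (add-one p-values).
* **Baselines and intersections**: literature co-mention ranking (raw or
  prevalence-normalized) and multi-disease list intersection with
  upset-style exclusive pattern counts and occurrence floors.

## Worked example

Plant 20 target genes for "aging" among 200 toy genes (probability boost
10 on each planted token) and recover them:

```r
library(targetrank)

lex     <- make_toy_lexicon(200, seed = 1)
planted <- plant_targets(lex, 20, seed = 1)
lm      <- make_toy_lm(toy_lm_spec(lex, planted = list(aging = planted),
                                   boost = 10, seed = 1))
trie    <- build_trie(lex)
ranked  <- score_genes(lm, trie, build_prompt(lm, "aging"), scoring_config())

head(ranked, 5)
#>   rank symbol raw_probability final_score token_length
#> 1    1  G0046         0.03082     0.03082            1
#> 2    2  G0188         0.03015     0.03015            1
#> 3    3  G0079         0.02911     0.02911            1
#> 4    4  G0169         0.02822     0.02822            1
#> 5    5  G0069         0.03309     0.01654            2

topk_validate(ranked, planted, ks = c(20, 50), N = 200)
#>    k targets_k targets_N   N  elfc  hgpv
#> 1 20        20        20 200 3.322 27.21
#> 2 50        20        20 200 2.000 13.53
```

All 20 planted genes occupy the top 20 ranks. At `k = 50` the enrichment
log fold change is exactly `log2((20/50)/(20/200)) = 2`, and the
hypergeometric score `HGPV = 13.5` says a draw this enriched has
probability `10^-13.5` under the null. `autoplot()` methods render
rankings, validation curves and permutation-test contrasts; `tidy()` /
`glance()` return results as tibbles.

A thin command-line wrapper over the same functions lives at
`inst/cli/targetrank.R` (`rank`, `validate`, `graph`, `intersect`,
`selfcheck` subcommands; every run writes a JSON manifest with config and
seed).

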
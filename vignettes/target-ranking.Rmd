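---
title: "Ranking therapeutic targets with next-token probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking therapeutic targets with next-token probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetrank)
```

## The problem and the method

Causal language models trained on biomedical text assign a probability to
every next token given a context. `targetrank` turns that distribution into
a ranking of candidate therapeutic targets: given a prompt such as

> human gene targeted by a drug for treating *aging* is the

each gene symbol in a fixed lexicon is scored by the probability that the
model continues the prompt with that symbol. Because subword tokenizers
split most gene names into several tokens (typically 2–7), a gene's
probability is the product of its token probabilities, obtained by
iteratively extending the prompt with each successive token and querying
the model again. The package never samples from the model; it only reads
distributions.

The gene lexicon is compiled once into a **token trie**: a prefix tree over
the tokenized symbols. Scoring is a breadth-first walk of this trie. At a
given prefix, the trie's children are the only tokens that can extend some
gene name — the *allowed set*. Children that end a gene there are
*completing*; children with descendants are *continuing*; a child can be
both when one gene's name is a prefix of another's (both genes are
retained, and the shorter gene's probability is read off at the completing
step while expansion continues through the same node).

## Normalization

Gene tokens carry a tiny share of the model's probability mass, and
products of several probabilities penalize long names. Two normalization
stages address this:

* **Step normalization** (`step_scheme`), applied to each next-token
  distribution restricted to the allowed set:
  * `total_sum` — divide by the summed mass of all allowed tokens, so the
    allowed set sums to 1 (the best-performing choice);
  * `separate_sum` — renormalize the completing and continuing classes to 1
    independently. The name admits more than one formula; independent
    per-class renormalization is the most direct reading, and a token
    belonging to both classes receives one value per role;
  * `none` — raw probabilities.
* **Final normalization** (`final_scheme`), applied to the product for a
  gene of token length $L$:
  * `length_division` — divide by $L^\alpha$; the exponent family is the
    simplest one containing the reported best setting $\alpha = 1$, which
    is the default;
  * `geometric_mean` — take the $L$-th root;
  * `none`.

The default configuration is `total_sum` + `length_division` with
$\alpha = 1$, no token-length filter, and `top_k = 200`. A pre-scoring
filter `max_token_length` is available (a cutoff of 5 is sensible when
reference targets are known to tokenize short).

All accumulation happens in the log domain: a 7-token gene whose tokens
each carry probability $10^{-300}$ still orders correctly even though the
probability-scale product underflows. Results carry both scales
(`log_raw`/`raw_probability`, `log_final`/`final_score`); ranking compares
log values, and a consequence is that reported probabilities can differ
from exact rational arithmetic by about one unit in the last place — unit
tests for worked examples therefore assert at $10^{-12}$ relative
tolerance rather than bitwise. Ties in the final score are broken by the
gene symbol in C-locale order so output is deterministic.

## Validation statistics

Given a reference set of known targets (`targets_N` of the `N` universe
genes), a ranking is evaluated at a cutoff $k$ by:

* **ELFC** — enrichment log fold change,
  $\log_2\frac{t_k / k}{\mathrm{targets}_N / N}$, where $t_k$ is the
  number of known targets in the top $k$, substituted by $0.1$ when zero
  so the statistic stays finite.
* **HGPV** — $-\log_{10} P(X \ge t_k)$ for $X$ hypergeometric with
  population $N$, successes $\mathrm{targets}_N$ and draws $k$, computed
  through the log survival function (`phyper(..., lower.tail = FALSE,
  log.p = TRUE)`) so extreme tails do not underflow. This score is often
  written as $-\log_{10}(1 - \mathrm{cdf}(t_k))$, which taken literally is
  the strict tail $P(X > t_k)$; the default implements the "at least
  $t_k$" reading, and `strict = TRUE` gives the literal variant. P-values
  are floored at the smallest representable double before the logarithm.

`overlap_test()` applies the same hypergeometric tail to the overlap of
two gene sets (draws = first-list size, successes = reference size).

## Embedding graphs and the proximity test

`embed_genes()` represents each protein by the mean of its per-token
embedding vectors for the text "context sentence + symbol" (default
context: *The human age-associated gene is the*). Pairwise cosine
similarities define a graph: an edge is kept when similarity reaches a
cutoff — either a fixed constant (default 0.507) or the
upper quartile of the off-diagonal similarity distribution, computed with
linear interpolation (R's type-7 quantile; the six-value worked example
$\{0.1,\dots,0.5,0.9\}$ resolves to 0.475 and keeps two edges).

Shortest paths run Dijkstra's algorithm on edge distances $1 - s$:
similarity itself is not a cost, and $1-s$ is the natural monotone
transform; an unweighted (hop-count) mode is provided for comparison. `permutation_path_test()`
asks whether a query node set lies closer to anchor nodes than random
same-size sets drawn from a candidate pool: the statistic is the mean of
finite query-to-anchor path lengths (unreachable pairs are excluded and
counted; a draw with no finite path scores infinite), and the p-value uses
the add-one rule $p = (1 + \#\{\text{null} \le \text{observed}\}) /
(1 + n_{\text{iter}})$, so $p$ is never zero and its floor at 1000
iterations is $1/1001$. Null draws always exclude the anchors; excluding
the query set as well is the default (the model-selected vs random
contrast) and is switchable for calibration studies, where the expected
uniformity of $p$ under exchangeable draws is verified by a
Kolmogorov–Smirnov screen.

## Baselines and intersections

`comention_rank()` ranks genes by literature co-mention counts, either raw
or normalized by each gene's total mention count (correcting for overall
literature prevalence); both modes are kept because either may be the one
used for a given comparison list. `intersect_lists()` computes exclusive
membership-pattern counts (upset semantics: the pattern counts sum to the
union size) and the set common to all lists; `occurrence_across_lists()`
applies an occurrence floor such as "present in more than 10 disease
lists".

## The synthetic test bed

No real language model ships with the package; `make_toy_lm()` builds a
fully deterministic stand-in that satisfies the same contract, so every
pipeline stage is testable offline.

* `make_toy_lexicon()` draws token lengths from a configurable
  distribution over 1..7 (default mass concentrated on 2–4, echoing how
  subword vocabularies encode gene symbols) and makes a configurable
  fraction of genes (default 0.3) extend another gene's sequence, so tries
  with shared prefixes and terminal-and-continue nodes are exercised.
* The toy model's base next-token distribution is a fixed table per
  context: weights drawn uniformly in $[1 - j, 1 + j]$ with jitter
  $j = 0.1$ by default, seeded by a stable polynomial hash of the context
  token ids. The jitter is kept mild so that planted signal, not base
  noise, dominates rankings; $j = 0$ gives an exactly uniform base, which
  makes boost arithmetic checkable in closed form (one token boosted by
  $\beta = 5$ among 10 uniform tokens yields $0.5/1.4$).
* **Planted targets**: for a chosen disease, each planted gene's next
  token is multiplied by a boost factor $\beta$ (then renormalized)
  whenever the context is the disease prompt followed by that gene's
  token prefix. `plant_targets()` selects planted genes among those with
  at most 3 tokens — known targets tokenize short — and, importantly,
  only among genes whose first token no other gene shares. The boost acts
  on tokens, not genes: a gene sharing a planted gene's leading tokens
  would inherit the boost (a gene that *is* a prefix of a planted gene
  would outrank it at any $\beta$), so prefix isolation is what makes the
  planted set a well-defined ground truth for recovery tests.
* `make_toy_embeddings()` places group centers on scaled coordinate axes
  at a fixed mutual distance and adds isotropic Gaussian noise, giving
  high within-group and low between-group cosine similarity.

What the toy world does *not* emulate: real subword token statistics,
correlations between a model's probabilities and its embedding geometry,
and the long-tailed probability mass of a trained transformer. Passing
tests therefore demonstrate correctness of the extraction machinery and
statistics, not predictive power on real literature-trained models — the
latter requires plugging a real adapter into the `causal_lm()` contract
(probabilities, not logits; deterministic; full-vocabulary
distributions, which `validate_lm()` checks).

## Problem sizes and numerical choices

The test suite and the reproduction script run, by choice, at desk scale:
lexicons of 100–200 genes over vocabularies of a few hundred tokens,
embedding graphs of 24–40 nodes, 99–1000 permutation iterations, and
exhaustive oracles on graphs of at most 8 nodes and hypergeometric
universes of at most 12. These sizes keep every independent oracle
(brute-force trie walks, exhaustive path enumeration, combinatorial tail
sums) cheap while exercising all structural cases. Graph-oracle checks
draw edge distances on a $1/64$ grid so path sums are exact in binary
floating point and equality can be asserted bitwise.

Degenerate inputs are handled explicitly: an empty allowed token set is an
error; zero allowed mass normalizes to zeros rather than NaN; genes with a
zero-probability token score 0 and sort to the tail; a graph whose every
pair falls below the threshold is returned edgeless with a warning; a
query with no finite path to any anchor is a degenerate-result error.

## A worked example

```{r worked}
lex <- make_toy_lexicon(200, seed = 1)
planted <- plant_targets(lex, 20, seed = 1)
lm <- make_toy_lm(toy_lm_spec(lex, planted = list(aging = planted),
                              boost = 10, seed = 1))
trie <- build_trie(lex)
ranked <- score_genes(lm, trie, build_prompt(lm, "aging"), scoring_config())
head(ranked, 5)
topk_validate(ranked, planted, ks = c(20, 50), N = 200)
```

With 20 planted among 200 genes and all 20 recovered in the top 50, the
top-50 ELFC is exactly $\log_2((20/50)/(20/200)) = 2$.

## Limitations

* Results are only as meaningful as the model behind the contract; the
  package quantifies enrichment against reference sets but cannot detect a
  model's biases (literature frequency, tokenizer artifacts).
* The `separate_sum` scheme and the distance transform $1-s$ are stated
  design choices among admissible alternatives; variants (per-class
  formula choices, unweighted paths) are either implemented or
  configurable.
* Symbol handling is purely lexical (uppercase, trimmed); aliasing and
  synonym resolution are out of scope.
```
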
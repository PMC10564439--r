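test_that("embedding retrieval mean-pools token vectors", {
  # manual_lm embeds token id t as rep(t, dim); mean pooling is the mean id
  lm <- manual_lm(list(), vocab_size = 10L,
                  words = list(The = 5L, gene = 7L, AAA = 2L, BBB = c(4L, 8L)))
  emb <- embed_genes(lm, c("AAA", "BBB"), context = "The gene")
  expect_equal(unname(emb["AAA", ]), rep(mean(c(5, 7, 2)), 3))
  expect_equal(unname(emb["BBB", ]), rep(mean(c(5, 7, 4, 8)), 3))
  # single token input pools to the token's own vector
  emb1 <- embed_genes(lm, "AAA", context = "")
  expect_equal(unname(emb1["AAA", ]), rep(2, 3))
  # determinism
  expect_identical(embed_genes(lm, "AAA", context = "The gene"),
                   embed_genes(lm, "AAA", context = "The gene"))
})

test_that("cosine similarities hit the trivial geometry cases", {
  emb <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  s <- cosine_matrix(emb)
  expect_equal(s["a", "b"], 1)      # identical direction
  expect_equal(s["a", "c"], 0)      # orthogonal
  expect_equal(s["a", "d"], -1)     # opposite
  expect_equal(diag(s), setNames(rep(1, 4), rownames(emb)))
  expect_true(isSymmetric(s, tol = 1e-12))
  expect_error(cosine_matrix(rbind(a = c(0, 0), b = c(1, 0))), "zero embedding.*a")
})

test_that("graph thresholding keeps edges at or above the cutoff", {
  sim <- diag(4)
  rownames(sim) <- colnames(sim) <- c("P", "Q", "R", "S")
  sim["P", "Q"] <- sim["Q", "P"] <- 0.6
  sim["P", "R"] <- sim["R", "P"] <- 0.4
  sim["P", "S"] <- sim["S", "P"] <- 0.507
  sim["Q", "R"] <- sim["R", "Q"] <- 0.1
  sim["Q", "S"] <- sim["S", "Q"] <- 0.2
  sim["R", "S"] <- sim["S", "R"] <- 0.3
  eg <- build_graph(sim, threshold = 0.507)
  # edge iff similarity >= 0.507: {P-Q at 0.6, P-S at exactly the cutoff}
  expect_equal(nrow(eg$edges), 2L)
  expect_setequal(paste(eg$edges$from, eg$edges$to),
                  c("P Q", "P S"))
  expect_equal(eg$edges$distance, 1 - eg$edges$similarity)

  # worked upper-quartile example: {.1,.2,.3,.4,.5,.9} -> threshold 0.475
  sim2 <- diag(4)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.9)
  sim2[upper.tri(sim2)] <- vals
  sim2 <- pmax(sim2, t(sim2)); diag(sim2) <- 1
  rownames(sim2) <- colnames(sim2) <- LETTERS[1:4]
  eg2 <- build_graph(sim2, threshold = "upper_quartile")
  expect_equal(eg2$threshold, 0.475)
  expect_equal(sort(eg2$edges$similarity), c(0.5, 0.9))

  expect_warning(build_graph(diag(2), threshold = 2), "no pair")
})

test_that("upper quartile keeps 20-30% of pairs on continuous similarities", {
  set.seed(99)
  for (i in 1:3) {
    n <- 30 + 5 * i
    emb <- matrix(rnorm(n * 6), nrow = n,
                  dimnames = list(sprintf("N%02d", 1:n), NULL))
    eg <- build_graph(cosine_matrix(emb), threshold = "upper_quartile")
    frac <- nrow(eg$edges) / choose(n, 2)
    expect_gte(frac, 0.20)
    expect_lte(frac, 0.30)
  }
})

test_that("weighted shortest paths match the 3-node worked example", {
  # direct edge 0.10 vs two-hop 0.05 + 0.04 = 0.09
  sim <- diag(3)
  rownames(sim) <- colnames(sim) <- c("X", "Y", "Z")
  sim["X", "Y"] <- sim["Y", "X"] <- 0.90   # d = 0.10
  sim["X", "Z"] <- sim["Z", "X"] <- 0.95   # d = 0.05
  sim["Z", "Y"] <- sim["Y", "Z"] <- 0.96   # d = 0.04
  eg <- build_graph(sim, threshold = 0.5)
  sp <- shortest_path_lengths(eg, "X", "Y")
  expect_equal(sp$length, 0.09)
  # a node in both sets is excluded as a zero-length self pair
  expect_message(sp2 <- shortest_path_lengths(eg, c("X", "Z"), c("Z", "Y")),
                 "excluded")
  expect_equal(nrow(sp2), 1L)
  expect_error(shortest_path_lengths(eg, "X", "W"), "unknown")
})

test_that("Dijkstra equals exhaustive path enumeration on small graphs", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    syms <- sprintf("V%d", 1:n)
    # distances on a 1/64 grid so all path sums are exact in binary floating
    # point and equality can be tested exactly
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.6
    if (!any(keep)) next
    edges <- data.frame(
      from = syms[pairs[keep, 1]],
      to = syms[pairs[keep, 2]],
      distance = sample(1:63, sum(keep), replace = TRUE) / 64
    )
    sim <- matrix(-1, n, n)
    diag(sim) <- 1
    rownames(sim) <- colnames(sim) <- syms
    for (e in seq_len(nrow(edges))) {
      sim[edges$from[e], edges$to[e]] <- 1 - edges$distance[e]
      sim[edges$to[e], edges$from[e]] <- 1 - edges$distance[e]
    }
    eg <- build_graph(sim, threshold = 0)
    src <- sample(syms, 1)
    tgt <- sample(setdiff(syms, src), 1)
    got <- shortest_path_lengths(eg, src, tgt)$length
    want <- enum_shortest_path(eg$edges, src, tgt)
    expect_identical(got, want)
  }
})

test_that("unreachable pairs are flagged and counted", {
  sim <- diag(4)
  rownames(sim) <- colnames(sim) <- LETTERS[1:4]
  sim["A", "B"] <- sim["B", "A"] <- 0.9
  sim["C", "D"] <- sim["D", "C"] <- 0.9
  eg <- build_graph(sim, threshold = 0.5)
  sp <- shortest_path_lengths(eg, "A", c("B", "C"))
  expect_equal(sp$reachable, c(TRUE, FALSE))
  expect_equal(sp$length[2], Inf)
})

test_that("permutation test p-values follow the add-one rule", {
  # two clusters: A* near each other, B far away
  groups <- rep(c("a", "b"), c(8, 12))
  emb <- make_toy_embeddings(groups, within_group_spread = 0.2,
                             between_group_separation = 6, seed = 5)
  eg <- build_graph(cosine_matrix(emb), threshold = 0.5)
  syms <- rownames(emb)
  query <- syms[1:4]; anchors <- syms[5:8]; pool <- syms[9:20]
  res <- permutation_path_test(eg, query, anchors, pool, n_iter = 100,
                               seed = 3)
  expect_s3_class(res, "path_test")
  expect_equal(res$p_value, 1 / 101)     # observed beats every null draw
  expect_length(res$null, 100L)
  expect_gt(res$p_value, 0)
  # n_iter = 1 with null >= observed -> p = 1/2
  res1 <- permutation_path_test(eg, query, anchors, pool, n_iter = 1, seed = 3)
  expect_equal(res1$p_value, 1 / 2)
  # determinism under a fixed seed
  res2 <- permutation_path_test(eg, query, anchors, pool, n_iter = 100,
                                seed = 3)
  expect_identical(res$null, res2$null)
  expect_error(permutation_path_test(eg, query, query, pool), "disjoint")
  expect_error(permutation_path_test(eg, syms, anchors, pool), "disjoint")
})

test_that("permutation p-values are calibrated under the null", {
  # one homogeneous cloud; query drawn from the same pool as the null draws
  emb <- make_toy_embeddings(rep("g", 40), within_group_spread = 0.8,
                             between_group_separation = 4, seed = 21)
  eg <- build_graph(cosine_matrix(emb), threshold = "upper_quartile")
  syms <- rownames(emb)
  anchors <- syms[1:6]
  pool <- syms[7:40]
  set.seed(404)
  pvals <- replicate(200, {
    query <- sample(pool, 5)
    permutation_path_test(eg, query, anchors, pool,
                          n_iter = 99, seed = sample.int(1e6, 1),
                          exclude_query = FALSE)$p_value
  })
  # Kolmogorov-Smirnov screen against uniform(0, 1)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
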
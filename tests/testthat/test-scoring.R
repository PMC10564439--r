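test_that("prompt building fills the template and is deterministic", {
  world <- toy_world(n_genes = 30L, n_planted = 3L, seed = 2L)
  p1 <- build_prompt(world$lm, "aging")
  p2 <- build_prompt(world$lm, "aging")
  expect_identical(p1, p2)
  # the filled default template has 11 words -> 11 hashed tokens for the toy
  expect_length(p1, 11L)
  expect_error(build_prompt(world$lm, ""), "non-empty")
  expect_error(prompt_template("no placeholder"), "exactly once")
  expect_error(prompt_template("{DISEASE} and {DISEASE}"), "exactly once")
})

test_that("step normalization implements the three schemes", {
  probs <- c(0.2, 0.2, 0.1, 0.1, 0.2, 0.2)

  # total_sum over allowed {1, 2}: equal mass -> 0.5 / 0.5
  ts <- step_normalize(probs, completing = 1L, continuing = 2L, "total_sum")
  expect_equal(ts$prob[ts$token_id == 1], 0.5)
  expect_equal(ts$prob[ts$token_id == 2], 0.5)
  expect_equal(sum(ts$prob), 1)

  # none: raw restriction
  rw <- step_normalize(probs, 1L, 2L, "none")
  expect_equal(rw$prob, c(0.2, 0.2))

  # separate_sum worked case: completing {a=.1}, continuing {b=.3, c=.1}
  p2 <- c(0.1, 0.3, 0.1, 0.5)
  ss <- step_normalize(p2, completing = 1L, continuing = c(2L, 3L),
                       scheme = "separate_sum")
  expect_equal(ss$prob[ss$token_id == 1 & ss$role == "completing"], 1.0)
  expect_equal(ss$prob[ss$token_id == 2], 0.75)
  expect_equal(ss$prob[ss$token_id == 3], 0.25)

  # a token in both classes gets one value per role under separate_sum
  p3 <- c(0.1, 0.3, 0.2, 0.4)
  both <- step_normalize(p3, completing = c(1L, 2L), continuing = c(2L, 3L),
                         scheme = "separate_sum")
  expect_equal(both$prob[both$token_id == 2 & both$role == "completing"],
               0.3 / 0.4)
  expect_equal(both$prob[both$token_id == 2 & both$role == "continuing"],
               0.3 / 0.5)

  # zero allowed mass -> zeros, not NaN
  z <- step_normalize(c(0, 0, 1), completing = 1L, continuing = 2L,
                      scheme = "total_sum")
  expect_equal(z$prob, c(0, 0))

  expect_error(step_normalize(probs, integer(0), integer(0)), "empty allowed")
})

test_that("conservation holds for random steps under both sum schemes", {
  set.seed(42)
  for (i in 1:250) {
    V <- sample(5:40, 1)
    probs <- stats::runif(V)
    probs <- probs / sum(probs)
    allowed <- sample(V, sample(2:min(8, V), 1))
    split_at <- sample(0:length(allowed), 1)
    completing <- utils::head(allowed, split_at)
    continuing <- utils::tail(allowed, length(allowed) - split_at)
    if (length(completing) + length(continuing) == 0) next

    ts <- step_normalize(probs, completing, continuing, "total_sum")
    expect_equal(sum(ts$prob), 1, tolerance = 1e-9)

    ss <- step_normalize(probs, completing, continuing, "separate_sum")
    if (length(completing) > 0) {
      expect_equal(sum(ss$prob[ss$role == "completing"]), 1, tolerance = 1e-9)
    }
    if (length(continuing) > 0) {
      expect_equal(sum(ss$prob[ss$role == "continuing"]), 1, tolerance = 1e-9)
    }
  }
})

test_that("the worked three-gene example scores exactly", {
  w <- worked_example()
  cfg <- scoring_config("total_sum", "length_division", alpha = 1)
  r <- score_genes(w$lm, w$trie, w$prompt, cfg)
  r <- r[match(c("A", "B", "C"), r$symbol), ]
  expect_equal(r$raw_probability, c(0.5, 0.375, 0.125))
  expect_equal(r$final_score, c(0.5, 0.1875, 0.0625))
  expect_equal(r$rank, 1:3)
  # brute-force oracle agrees on gene B
  expect_equal(brute_force_score(w$lm, c(2L, 3L), w$trie, w$prompt, cfg), 0.375)
})

test_that("final normalization matches its closed forms", {
  expect_equal(final_normalize(0.01, 2, "geometric_mean"), 0.1)
  expect_equal(final_normalize(0.01, 2, "length_division", alpha = 1), 0.005)
  expect_equal(final_normalize(0.01, 2, "length_division", alpha = 2), 0.0025)
  for (scheme in c("none", "geometric_mean", "length_division")) {
    expect_equal(final_normalize(0.37, 1, scheme), 0.37)
  }
  expect_error(final_normalize(0.5, 0, "none"), ">= 1")
  expect_error(scoring_config(alpha = -1), "> 0")
})

test_that("scorer agrees with the brute-force oracle for every gene and scheme", {
  world <- toy_world(n_genes = 120L, n_planted = 10L, seed = 11L)
  for (step in c("total_sum", "separate_sum", "none")) {
    cfg <- scoring_config(step_scheme = step)
    full <- attr(score_genes(world$lm, world$trie, world$prompt, cfg),
                 "full_ranking")
    got <- setNames(full$raw_probability, full$symbol)
    for (i in seq_len(nrow(world$lex))) {
      bf <- brute_force_score(world$lm, world$lex$token_ids[[i]], world$trie,
                              world$prompt, cfg)
      expect_equal(got[[world$lex$symbol[i]]], bf,
                   tolerance = 1e-12)
    }
  }
})

test_that("uniform model with single-token genes gives equal scores", {
  lex <- manual_lexicon(paste0("G", 1:8), as.list(1:8))
  lm <- manual_lm(list(), vocab_size = 10L,
                  words = setNames(as.list(1:8), paste0("G", 1:8)))
  r <- score_genes(lm, build_trie(lex), prompt = 10L,
                   scoring_config("total_sum", "none"))
  expect_equal(r$final_score, rep(1 / 8, 8))
})

test_that("raw probabilities shrink along prefixes under scheme none", {
  world <- toy_world(n_genes = 100L, n_planted = 5L, seed = 13L)
  cfg <- scoring_config(step_scheme = "none", final_scheme = "none")
  full <- attr(score_genes(world$lm, world$trie, world$prompt, cfg),
               "full_ranking")
  raw <- setNames(full$raw_probability, full$symbol)
  keys <- vapply(world$lex$token_ids, paste, character(1), collapse = ",")
  for (i in seq_len(nrow(world$lex))) {
    ids_i <- world$lex$token_ids[[i]]
    for (j in seq_len(nrow(world$lex))) {
      ids_j <- world$lex$token_ids[[j]]
      if (length(ids_j) < length(ids_i) &&
          identical(ids_i[seq_along(ids_j)], ids_j)) {
        expect_lte(raw[[world$lex$symbol[i]]], raw[[world$lex$symbol[j]]])
      }
    }
  }
})

test_that("a zero-probability token zeroes the gene and ranks it last", {
  # vocab 4; gene tokens: A=[1], B=[2,3]; token 3 has probability zero
  lex <- manual_lexicon(c("A", "B"), list(1L, c(2L, 3L)))
  dists <- list("4" = c(0.3, 0.3, 0.2, 0.2),
                "4,2" = c(0.5, 0.5, 0.0, 0.0))
  lm <- manual_lm(dists, vocab_size = 4L,
                  words = list(A = 1L, B = c(2L, 3L)))
  r <- score_genes(lm, build_trie(lex), 4L, scoring_config("total_sum", "none"))
  expect_equal(r$final_score[r$symbol == "B"], 0)
  expect_equal(r$rank[r$symbol == "B"], 2L)
})

test_that("log-domain accumulation survives 7 tokens at 1e-300 each", {
  ids <- 1:7
  lex <- manual_lexicon("LONG", list(ids))
  tiny <- 1e-300
  dists <- list()
  for (j in 0:6) {
    key <- paste(c(9L, ids[seq_len(j)]), collapse = ",")
    d <- rep(0, 9)
    d[ids[j + 1]] <- tiny
    d[9] <- 1 - tiny
    dists[[key]] <- d
  }
  lm <- manual_lm(dists, vocab_size = 9L, words = list(LONG = ids))
  r <- score_genes(lm, build_trie(lex), 9L, scoring_config("none", "none"))
  expect_equal(r$log_raw, 7 * log(tiny))
  expect_true(is.finite(r$log_raw))
  # geometric mean recovers the per-token scale in the log domain
  r2 <- score_genes(lm, build_trie(lex), 9L,
                    scoring_config("none", "geometric_mean"))
  expect_equal(r2$log_final, log(tiny))
})

test_that("ranking is descending with lexicographic tie-breaks and top-k", {
  scores <- tibble::tibble(
    symbol = c("B", "A", "C", "D"),
    token_length = 1L,
    log_final = log(c(0.2, 0.2, 0.5, 0.1))
  )
  scores$final_score <- exp(scores$log_final)
  scores$log_raw <- scores$log_final
  scores$raw_probability <- scores$final_score
  r <- rank_genes(scores)
  expect_equal(r$symbol, c("C", "A", "B", "D"))
  expect_equal(r$rank, 1:4)
  r2 <- rank_genes(scores, top_k = 2)
  expect_equal(nrow(r2), 2L)
  expect_equal(nrow(attr(r2, "full_ranking")), 4L)
  r3 <- rank_genes(scores, top_k = 10)
  expect_equal(nrow(r3), 4L)
})

test_that("planted genes dominate the ranking once the boost is strong", {
  for (seed in 1:5) {
    world <- toy_world(n_genes = 150L, n_planted = 12L, boost = 25,
                       seed = seed)
    full <- attr(score_genes(world$lm, world$trie, world$prompt,
                             scoring_config()), "full_ranking")
    expect_setequal(utils::head(full$symbol, 12L), world$planted)
  }
  # beta = 1: no signal, planted genes do not cluster at the top
  world1 <- toy_world(n_genes = 150L, n_planted = 12L, boost = 1, seed = 1L)
  full1 <- attr(score_genes(world1$lm, world1$trie, world1$prompt,
                            scoring_config()), "full_ranking")
  expect_lt(sum(utils::head(full1$symbol, 12L) %in% world1$planted), 12L)
})

test_that("max_token_length in the config filters before scoring", {
  world <- toy_world(n_genes = 80L, n_planted = 5L, seed = 4L)
  cfg <- scoring_config(max_token_length = 2L)
  r <- score_genes(world$lm, world$trie, world$prompt, cfg,
                   lexicon = world$lex)
  expect_setequal(r$symbol, world$lex$symbol[world$lex$token_length <= 2L])
  expect_error(score_genes(world$lm, world$trie, world$prompt, cfg),
               "lexicon")
})
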
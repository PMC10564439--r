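#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Run code under a temporary RNG state, restoring the caller's state after.
# Used so toy-LM queries and seeded generators never disturb user RNG.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable polynomial hash of an integer vector into [0, 2^31 - 2].
# Horner scheme mod a Mersenne prime; pure integer-free double arithmetic
# keeps every intermediate exactly representable.
context_hash <- function(ids, salt = 0) {
  m <- 2147483647
  h <- (salt %% m)
  for (id in ids) {
    h <- (h * 31 + as.numeric(id)) %% m
  }
  h
}

# C-locale lexicographic tie-break used by every ranking in the package,
# so ordering does not depend on the session collation.
order_score_symbol <- function(score, symbol) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(-score, symbol)
}
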
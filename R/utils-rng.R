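# Seed plumbing: every stochastic entry point takes an integer seed and
# evaluates under a locally set RNG state, restoring the caller's stream.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a deterministic sub-seed
#'
#' Maps a master seed and a stream index to a reproducible 31-bit sub-seed,
#' so that simulated participants (or blocks) get independent but fully
#' deterministic random streams.
#'
#' @param seed integer master seed.
#' @param k non-negative integer stream index.
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647 # 2^31 - 1, Mersenne prime (minstd modulus)
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (mult in c(48271, 16807)) {
    s <- (s * mult + as.numeric(k) + 1) %% m
  }
  as.integer(s + 1)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
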
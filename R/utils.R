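# Internal helpers: local RNG scope, deterministic sub-seeding, smoothed
# empirical p-values.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# A master seed spawns one sub-seed per replicate so any replicate can be
# reproduced in isolation. Seeds stay below 2^31.
spawnSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}

# (r + 1)/(n + 1) smoothing avoids p = 0 at finite replicate counts.
empiricalP <- function(nullValues, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  r <- if (tail == "ge") sum(nullValues >= observed) else sum(nullValues <= observed)
  (r + 1) / (length(nullValues) + 1)
}

classifySignificance <- function(z, zSig = -1.96, zMarg = -1.645) {
  if (is.na(z)) return("ns")
  if (z < zSig) "significant" else if (z < zMarg) "marginal" else "ns"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
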
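# Shared internals.

# Evaluate `code` under a fixed RNG state (Mersenne-Twister, the package's
# declared generator) and restore the caller's state afterwards. All seeded
# stages funnel through this so that determinism is a property of the seed
# alone, never of call order.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

HG_RNG_KIND <- "Mersenne-Twister/Inversion"
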
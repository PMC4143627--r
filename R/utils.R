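# Seed substreams: one master seed, fixed multiplicative offsets, so that
# per-stage and per-individual draws are reproducible independently of the
# order in which other stages run. Kept below 2^31 - 1.
substreamSeed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset)
  as.integer(s %% 2147483647)
}

# stage offsets used by the simulator and pipeline
.STAGE <- c(props = 1, covariates = 2, traits = 3, individuals = 1000,
            panel = 11, aims = 12, perm = 13)

stopIfNot01 <- function(x, what) {
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}
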
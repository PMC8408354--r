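# Seed derivation. A Horner-scheme integer hash over a modulus below 2^31:
# every intermediate product stays under 2^53, so the arithmetic is exact in
# doubles and the stream is reproducible across platforms. Used to give each
# (scenario, replication) its own substream of the master seed, making grid
# results independent of execution order and worker count.
seed_stream <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 69069 + as.double(x) %% 2147483629 + 1) %% 2147483629
  as.integer(s)
}

# Scenario key: a deterministic function of the scenario's scientific
# content only (not of n_reps or the master seed).
scenario_key <- function(config) {
  seed_stream(round(1000 * config$r2_target), round(1000 * config$skewness),
              as.integer(config$linear), as.integer(config$differential),
              round(1000 * config$val_fraction), config$n)
}
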
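# Internal helpers shared across modules.

# Metabolic power per unit VO2 (W per L·min⁻¹) at a given RER:
# (4940·RER + 16040)/60.
.metp_coef <- function(rer) (4940 * rer + 16040) / 60

# Deterministic per-stream seed derived from a master seed and a key, so
# each (participant, workload, condition) trial has its own RNG stream and
# removing one trial does not shift the others. Polynomial string hash mod
# a prime below 2^31; exact in double arithmetic.
.stream_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Draw from a normal and clamp into a plausible physiological range.
.rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}
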
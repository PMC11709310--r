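# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divide by n); pinned so scores are
# bit-reproducible regardless of R's sample-sd default
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# multiplicative lognormal noise factors with mean 1 and coefficient of
# variation cv; cv = 0 returns exact ones (no RNG draw would still be
# deterministic, but exactness matters for noise-free invariants)
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

ratio_cols <- c("r_pi", "r_mi", "r_dp", "r_ly")

epi_key_cols <- c("location", "year", "sex", "age", "measure", "metric")

epi_col_order <- c("location", "location_level", "year", "sex", "age",
                   "measure", "metric", "value", "lower", "upper")
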
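# fixtures and independent oracles shared across the suite

# one observation unit with all six measures, canonical long format
toy_epi <- function(values = c(incidence = 10, prevalence = 70, deaths = 1,
                               DALYs = 35, YLLs = 20, YLDs = 15),
                    location = "Testland", year = 2019L, sex = "both",
                    age = "Age-standardized", metric = "rate") {
  data.frame(location = location, location_level = "country",
             year = as.integer(year), sex = sex, age = age,
             measure = names(values), metric = metric,
             value = unname(values),
             lower = unname(values) * 0.9, upper = unname(values) * 1.1,
             stringsAsFactors = FALSE)
}

# random positive ratio table with plausible scales per ratio
rand_ratios <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(r_pi = rlnorm(n, 3, 0.5), r_mi = rlnorm(n, -2, 0.5),
             r_dp = rlnorm(n, -1, 0.4), r_ly = rlnorm(n, 0, 0.6))
}

# independent full-pipeline oracle: explicit standardization, SVD for the
# first component (different route from the implementation's eigen on the
# crossproduct), explicit orientation and min-max rescale
brute_qci <- function(x) {
  m <- as.matrix(x[c("r_pi", "r_mi", "r_dp", "r_ly")])
  mu <- colMeans(m)
  sdv <- apply(m, 2, function(cc) sqrt(mean((cc - mean(cc))^2)))
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  v1 <- svd(z)$v[, 1]
  k <- which.max(abs(v1))
  if (v1[k] < 0) v1 <- -v1
  s <- drop(z %*% v1)
  r <- cor(s, z[, 2])
  if (r == 0) r <- cor(s, z[, 3])
  s <- sign(r) * s
  100 * (max(s) - s) / (max(s) - min(s))
}

# brute-force dominant eigenvector by power iteration
power_iter_pc1 <- function(cmat, iters = 5000) {
  v <- rep(1, ncol(cmat)) / sqrt(ncol(cmat))
  for (i in seq_len(iters)) {
    w <- cmat %*% v
    v <- w / sqrt(sum(w^2))
  }
  drop(v)
}
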
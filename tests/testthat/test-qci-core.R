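# standardization, PCA, orientation and 0-100 scoring

test_that("standardization is the population z-score", {
  two <- data.frame(r_pi = c(1, 3), r_mi = c(2, 4), r_dp = c(0, 1),
                    r_ly = c(5, 9))
  z <- standardize_ratios(two)$z
  expect_equal(unname(z[, "r_pi"]), c(-1, 1))
  expect_true(all(abs(colMeans(z)) < 1e-9))

  x <- rand_ratios(20, seed = 11)
  std <- standardize_ratios(x)
  for (j in c("r_pi", "r_mi", "r_dp", "r_ly")) {
    mu <- mean(x[[j]])
    sdv <- sqrt(mean((x[[j]] - mu)^2))
    expect_equal(unname(std$z[, j]), (x[[j]] - mu) / sdv)
  }
  const <- x
  const$r_dp <- 2
  expect_error(standardize_ratios(const), "r_dp")
})

test_that("duplicated columns receive equal PC1 weight", {
  set.seed(5)
  n <- 200
  a <- rnorm(n)
  z <- standardize_ratios(data.frame(r_pi = a, r_mi = a,
                                     r_dp = rnorm(n), r_ly = rnorm(n)))$z
  p <- fit_ratio_pca(z)
  expect_lt(abs(p$loadings["r_pi", 1] - p$loadings["r_mi", 1]), 1e-6)
  expect_gt(p$explained_variance[1], 2 - 1e-6)
})

test_that("independent columns give a near-isotropic spectrum", {
  set.seed(8)
  z <- standardize_ratios(as.data.frame(matrix(rnorm(2000 * 4), ncol = 4,
                dimnames = list(NULL, c("r_pi", "r_mi", "r_dp", "r_ly")))))$z
  p <- fit_ratio_pca(z)
  expect_true(all(abs(p$explained_variance - 1) < 0.15))
})

test_that("PC1 matches the power-iteration oracle up to sign", {
  for (seed in c(2, 9)) {
    z <- standardize_ratios(rand_ratios(50, seed = seed))$z
    p <- fit_ratio_pca(z)
    cmat <- crossprod(z) / nrow(z)
    v <- power_iter_pc1(cmat)
    err <- min(sqrt(sum((p$loadings[, 1] - v)^2)),
               sqrt(sum((p$loadings[, 1] + v)^2)))
    expect_lt(err, 1e-8)
    # loadings are orthonormal, variance ordered and sums to 4
    expect_equal(crossprod(p$loadings), diag(4), ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_true(all(diff(p$explained_variance) <= 1e-12))
    expect_equal(sum(p$explained_variance), 4)
  }
})

test_that("orientation follows the deaths/incidence anchor", {
  # columns aligned with r_mi: PC1 already points the "worse" way
  set.seed(4)
  n <- 300
  lat <- rnorm(n)
  mk <- function(s) data.frame(r_pi = s[1] * lat + rnorm(n, sd = .3),
                               r_mi = s[2] * lat + rnorm(n, sd = .3),
                               r_dp = s[3] * lat + rnorm(n, sd = .3),
                               r_ly = s[4] * lat + rnorm(n, sd = .3))
  z_pos <- standardize_ratios(mk(c(1, 1, 1, 1)))$z
  m_pos <- orient_pc1(fit_ratio_pca(z_pos), z_pos)
  s_pos <- m_pos$orientation_sign * drop(z_pos %*% m_pos$loadings[, 1])
  expect_gt(cor(s_pos, z_pos[, "r_mi"]), 0)

  # r_mi anti-aligned with the dominant direction: sign must flip so the
  # oriented score still tracks r_mi upward
  z_neg <- standardize_ratios(mk(c(1, -1, 1, 1)))$z
  m_neg <- orient_pc1(fit_ratio_pca(z_neg), z_neg)
  s_neg <- m_neg$orientation_sign * drop(z_neg %*% m_neg$loadings[, 1])
  expect_gt(cor(s_neg, z_neg[, "r_mi"]), 0)
  expect_equal(m_neg$orientation_sign * sign(m_neg$loadings["r_mi", 1]), 1)
})

test_that("min-max scoring maps oriented scores onto 0-100 with clamping", {
  loadings <- diag(4)
  dimnames(loadings) <- list(c("r_pi", "r_mi", "r_dp", "r_ly"),
                             paste0("PC", 1:4))
  model <- structure(list(
    means = setNames(rep(0, 4), rownames(loadings)),
    sds = setNames(rep(1, 4), rownames(loadings)),
    loadings = loadings, explained_variance = c(4, 0, 0, 0),
    orientation_sign = 1, scale_min = 2, scale_max = 6
  ), class = "qci")
  nd <- data.frame(r_pi = c(2, 4, 6, 8, 0), r_mi = 0, r_dp = 0, r_ly = 0)
  out <- predict(model, nd)
  expect_equal(out$qci, c(100, 50, 0, 0, 100))  # last two clamped
  expect_equal(out$pc1_score, c(2, 4, 6, 8, 0))
})

test_that("the pooled best row scores 100 and the worst 0", {
  x <- rand_ratios(40, seed = 21)
  fit <- qci(x)
  expect_true(all(fit$scores$qci >= 0 & fit$scores$qci <= 100))
  expect_equal(max(fit$scores$qci), 100)
  expect_equal(min(fit$scores$qci), 0)
  best <- x[which.max(fit$scores$qci), ]
  expect_equal(predict(fit, best)$qci, 100)
})

test_that("full pipeline agrees with the brute-force oracle", {
  for (n in c(10, 37, 100)) {
    x <- rand_ratios(n, seed = n)
    fit <- qci(x)
    expect_lt(max(abs(fit$scores$qci - brute_qci(x))), 1e-8)
  }
})

test_that("column rescaling and row permutation leave the QCI unchanged", {
  x <- rand_ratios(60, seed = 13)
  ref <- qci(x)$scores$qci
  for (j in c("r_pi", "r_mi", "r_dp", "r_ly")) {
    xs <- x
    xs[[j]] <- xs[[j]] * 1000
    expect_lt(max(abs(qci(xs)$scores$qci - ref)), 1e-8)
  }
  set.seed(99)
  perm <- sample(nrow(x))
  expect_lt(max(abs(qci(x[perm, ])$scores$qci - ref[perm])), 1e-8)
})

test_that("with all-nonnegative oriented loadings, raising every ratio of an
           out-of-pool row cannot raise its QCI", {
  set.seed(6)
  n <- 200
  lat <- abs(rnorm(n))
  x <- data.frame(r_pi = 2 * lat + abs(rnorm(n, sd = .2)),
                  r_mi = 0.5 * lat + abs(rnorm(n, sd = .1)),
                  r_dp = lat + abs(rnorm(n, sd = .15)),
                  r_ly = 3 * lat + abs(rnorm(n, sd = .3)))
  fit <- qci(x)
  expect_true(all(coef(fit) >= 0))
  row <- data.frame(r_pi = 2, r_mi = 0.5, r_dp = 1, r_ly = 3)
  for (k in c(1.1, 2, 10)) {
    expect_lte(predict(fit, row * k)$qci, predict(fit, row)$qci + 1e-10)
  }
})

test_that("incomplete rows propagate NA scores and are excluded from fit", {
  x <- rand_ratios(30, seed = 17)
  x$r_mi[4] <- NA
  x$r_pi[9] <- Inf
  fit <- qci(x)
  expect_equal(fit$n_fit, 28)
  expect_equal(fit$n_dropped, 2)
  expect_true(all(is.na(fit$scores$qci[c(4, 9)])))
  expect_true(all(!is.na(fit$scores$qci[-c(4, 9)])))
})

test_that("a model survives a JSON round trip and rescoring", {
  x <- rand_ratios(25, seed = 31)
  fit <- qci(x)
  f <- tempfile(fileext = ".json")
  write_qci_model(fit, f)
  back <- read_qci_model(f)
  expect_equal(predict(back, x)$qci, fit$scores$qci)
  expect_equal(back$orientation_sign, fit$orientation_sign)
})

test_that("the QCI recovers the generator's latent care quality", {
  sim <- simulate_gbd(synthetic_config())
  fit <- qci(compute_ratios(sim$epi))
  m <- merge(fit$scores, sim$truth, by = c("location", "year", "sex"))
  rho <- cor(m$qci, m$q, method = "spearman")
  expect_gte(rho, 0.9)
  # oriented "badness" score anti-tracks quality
  expect_lt(cor(m$pc1_score, m$q, method = "spearman"), -0.9)
})
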
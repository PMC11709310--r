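#' Correlate fitted QCI with an external reference index
#'
#' Pearson correlation between the QCI and an external location-year
#' reference index (e.g. a healthcare access and quality index on a 0-100
#' scale), computed on the overlapping `(location, year)` pairs.
#'
#' @param x A `"qci"` object or scores data.frame.
#' @param panel Data.frame with columns `location`, `year`,
#'   `reference_index` and unique `(location, year)` keys.
#' @param sex Which sex series of the QCI to correlate (default `"both"`).
#' @return List with `r` (Pearson correlation) and `n` (overlap size).
#' @export
correlate_with_reference <- function(x, panel, sex = "both") {
  sc <- if (inherits(x, "qci")) x$scores else as.data.frame(x)
  stopifnot(all(c("location", "year", "reference_index") %in% names(panel)))
  key <- paste(panel$location, panel$year, sep = "\r")
  if (anyDuplicated(key)) stop("panel has duplicated (location, year) keys")
  sub <- sc[sc$sex == sex & !is.na(sc$qci), c("location", "year", "qci")]
  m <- merge(sub, panel[c("location", "year", "reference_index")],
             by = c("location", "year"))
  m <- m[is.finite(m$reference_index), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("insufficient data: need at least 3 overlapping location-years, ",
         "got ", nrow(m))
  }
  list(r = stats::cor(m$qci, m$reference_index), n = nrow(m))
}

#' Random-intercept linear model by the two-stage moment method
#'
#' Fits a country-random-intercept linear model
#' `y_ij = mu + x_ij' beta + alpha_i + e_ij` with a transparent two-stage
#' moment estimator rather than full likelihood:
#'
#' 1. slopes `beta` by the within-group (fixed-effects) estimator — OLS on
#'    group-demeaned outcome and covariates;
#' 2. group intercepts `alpha_i + mu` as the mean group residual
#'    `mean(y_i - X_i beta)`; the residual variance from the within fit;
#'    the intercept variance by moment decomposition,
#'    `var(alpha) = var(intercepts) - sigma_e^2 * mean(1/n_i)` (truncated
#'    at zero).
#'
#' Covariates with no within-group variation (including an identically
#' zero column) cannot be identified by the within estimator; they get a
#' zero slope and their group-level effect is absorbed into the
#' intercepts.  Collinear sets among the remaining covariates raise an
#' error naming the aliased columns.  Results are deterministic given the
#' inputs.
#'
#' @param formula Model formula, e.g. `qci ~ utilization + mortality`.
#' @param data Data.frame holding the outcome, covariates and the grouping
#'   column.
#' @param group Name of the grouping column (default `"location"`).
#' @return Object of class `"qci_ranef"`: `coefficients` (fixed intercept
#'   and slopes), `intercepts` (per-group level `mu + alpha_i`), `ranef`
#'   (centred `alpha_i`), `sigma` (named vector: intercept and residual
#'   SDs), `n_obs`, `n_groups`, `dropped_groups`.
#' @examples
#' d <- expand.grid(location = letters[1:6], t = 1:8)
#' d$x <- rnorm(nrow(d))
#' d$y <- 2 + 0.5 * d$x + rep(rnorm(6), times = 8) + rnorm(nrow(d), sd = .1)
#' fit_random_intercept(y ~ x, d)
#' @export
fit_random_intercept <- function(formula, data, group = "location") {
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  vars <- all.vars(formula)
  use <- stats::complete.cases(data[c(vars, group)])
  d <- data[use, , drop = FALSE]
  g <- factor(d[[group]])

  n_g <- table(g)
  small <- names(n_g)[n_g < 2L]
  if (length(small)) {
    warning("dropping ", length(small), " group(s) with fewer than 2 ",
            "observations: ", paste(utils::head(small, 5L), collapse = ", "))
    keep <- !(as.character(g) %in% small)
    d <- d[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 observations")

  mf <- stats::model.frame(formula, data = d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]

  demean <- function(v) v - stats::ave(v, g)
  yw <- demean(y)
  Xw <- apply(X, 2L, demean)
  if (!is.matrix(Xw)) Xw <- matrix(Xw, ncol = ncol(X),
                                   dimnames = list(NULL, colnames(X)))

  active <- apply(Xw, 2L, function(cc) max(abs(cc)) > 1e-10)
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  p_active <- sum(active)
  if (p_active > 0L) {
    Xa <- Xw[, active, drop = FALSE]
    qd <- qr(Xa)
    if (qd$rank < p_active) {
      aliased <- colnames(Xa)[qd$pivot[(qd$rank + 1L):p_active]]
      stop("rank-deficient covariates; collinear set includes: ",
           paste(aliased, collapse = ", "))
    }
    beta[active] <- drop(qr.coef(qd, yw))
  }

  resid_unit <- y - drop(X %*% beta)
  intercepts <- tapply(resid_unit, g, mean)
  ew <- yw - if (p_active > 0L) drop(Xw %*% beta) else 0
  df_resid <- length(y) - nlevels(g) - p_active
  sigma2_e <- if (df_resid > 0L) sum(ew^2) / df_resid else 0
  mu <- mean(intercepts)
  v_raw <- stats::var(as.numeric(intercepts))
  sigma2_a <- max(0, v_raw - sigma2_e * mean(1 / as.numeric(table(g))))

  structure(list(
    coefficients = c("(Intercept)" = mu, beta),
    intercepts = intercepts,
    ranef = intercepts - mu,
    sigma = c(intercept = sqrt(sigma2_a), residual = sqrt(sigma2_e)),
    n_obs = length(y),
    n_groups = nlevels(g),
    dropped_groups = length(small),
    inactive = colnames(X)[!active],
    call = match.call(), formula = formula
  ), class = "qci_ranef")
}

#' @export
print.qci_ranef <- function(x, digits = 4, ...) {
  cat("Random-intercept linear model (two-stage moment estimator)\n")
  cat(sprintf("  %d observations in %d groups\n", x$n_obs, x$n_groups))
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  if (length(x$inactive)) {
    cat("  (no within-group variation, slope fixed at 0: ",
        paste(x$inactive, collapse = ", "), ")\n", sep = "")
  }
  cat(sprintf("Random intercept SD: %.4g; residual SD: %.4g\n",
              x$sigma["intercept"], x$sigma["residual"]))
  invisible(x)
}

#' @export
coef.qci_ranef <- function(object, ...) object$coefficients
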
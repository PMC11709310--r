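#' Standardize the four ratio columns
#'
#' Z-scores each ratio column over the complete rows using the column mean
#' and the population standard deviation (divide by n, not n - 1; the
#' convention is pinned so scores are bit-reproducible).  Incomplete rows
#' (any non-finite ratio) are excluded from the fitting pool and reported.
#'
#' @param ratios Ratio table from [compute_ratios()], or any data.frame /
#'   matrix with the four columns `r_pi`, `r_mi`, `r_dp`, `r_ly`.
#' @return List with `z` (n x 4 standardized matrix over complete rows),
#'   `means`, `sds` (named 4-vectors), and `keep` (logical vector marking
#'   the complete rows of the input).
#' @export
standardize_ratios <- function(ratios) {
  x <- as.data.frame(ratios)
  miss <- setdiff(ratio_cols, names(x))
  if (length(miss)) stop("missing ratio column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(x[ratio_cols])
  storage.mode(m) <- "double"
  keep <- rowSums(!is.finite(m)) == 0L
  if ("complete" %in% names(x)) keep <- keep & x$complete
  if (sum(keep) < 2L) stop("need at least 2 complete rows to standardize")
  m <- m[keep, , drop = FALSE]
  means <- colMeans(m)
  sds <- apply(m, 2L, sd_pop)
  degen <- sds <= 0 | !is.finite(sds)
  if (any(degen)) {
    stop("degenerate input: constant ratio column(s): ",
         paste(ratio_cols[degen], collapse = ", "))
  }
  z <- sweep(sweep(m, 2L, means, "-"), 2L, sds, "/")
  list(z = z, means = means, sds = sds, keep = keep)
}

#' Principal component analysis of the standardized ratio matrix
#'
#' Eigendecomposition of the 4 x 4 covariance of the standardized matrix
#' (equal to the ratio correlation matrix under the population-sd
#' convention).  Components are ordered by explained variance.  Before the
#' semantic orientation step ([orient_pc1()]) each loading column is given
#' a deterministic sign: its largest-magnitude element is made positive, so
#' results do not depend on the linear-algebra backend's sign choice.
#'
#' @param z Standardized matrix from [standardize_ratios()].
#' @return List with `loadings` (4 x 4 orthonormal matrix, columns =
#'   components) and `explained_variance` (non-increasing 4-vector summing
#'   to 4 for correlation-scale input).
#' @export
fit_ratio_pca <- function(z) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("validation error: non-finite values in input")
  if (nrow(z) < ncol(z)) stop("need at least as many rows as columns")
  cmat <- crossprod(z) / nrow(z)
  e <- eigen(cmat, symmetric = TRUE)
  loadings <- e$vectors
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(z), paste0("PC", seq_len(ncol(z))))
  list(loadings = loadings, explained_variance = e$values)
}

#' Orient the first principal component along the "worse care" direction
#'
#' The sign of a principal component is arbitrary; the index needs a
#' semantic direction.  The deaths/incidence ratio is the one ratio whose
#' direction is unambiguous (lower is better care), so the orientation sign
#' is chosen to make the oriented PC1 score correlate positively with the
#' standardized `r_mi` column: larger oriented score = worse care.  If that
#' correlation is exactly zero the DALYs/prevalence column is the fallback
#' anchor; if both are zero the component is un-orientable and an error is
#' raised.
#'
#' @param model List from [fit_ratio_pca()].
#' @param z The standardized matrix the model was fitted on.
#' @return `model` with an `orientation_sign` element (+1 or -1).
#' @export
orient_pc1 <- function(model, z) {
  s <- drop(as.matrix(z) %*% model$loadings[, 1L])
  anchors <- c("r_mi", "r_dp")
  sign_out <- 0
  for (a in anchors) {
    r <- stats::cor(s, z[, a])
    if (is.finite(r) && r != 0) {
      sign_out <- if (r > 0) 1 else -1
      break
    }
  }
  if (sign_out == 0) {
    stop("cannot orient PC1: zero correlation with both anchor ratios ",
         "(r_mi, r_dp)")
  }
  model$orientation_sign <- sign_out
  model
}

#' Fit the Quality of Care Index
#'
#' Fits the PCA-based 0-100 Quality of Care Index (QCI) to a table of the
#' four care-quality ratios (or directly to a canonical burden table, in
#' which case [compute_ratios()] is applied first).  The procedure:
#'
#' 1. z-score each ratio over the complete rows (correlation-scale PCA;
#'    the four ratios live on very different scales);
#' 2. eigendecompose the 4 x 4 correlation matrix and take the first
#'    principal component;
#' 3. orient it so that larger scores mean worse care ([orient_pc1()]);
#' 4. min-max rescale to `qci = 100 * (max - score) / (max - min)` using
#'    the pooled score extrema, so the pooled worst observation scores 0,
#'    the best scores 100, and higher QCI = better care.
#'
#' The fitting pool is everything in `x` at once; to place countries,
#' years and sexes on one common scale, pool them all into a single fit
#' and read scores from the result (or score new rows against a frozen
#' model with [predict.qci()], which clamps to `[0, 100]`).
#'
#' Incomplete rows (missing measure or zero denominator upstream) are
#' excluded from the fit and carry `NA` scores in the result — they are
#' propagated, never silently dropped.
#'
#' @param x A ratio table ([compute_ratios()] output or any data.frame or
#'   matrix with columns `r_pi`, `r_mi`, `r_dp`, `r_ly`), or a canonical
#'   long-format burden table (recognised by its `measure` column).
#' @param ... Passed to methods.
#' @return An object of class `"qci"`: a list with the model parameters
#'   (`means`, `sds`, `loadings`, `explained_variance`,
#'   `orientation_sign`, `scale_min`, `scale_max`), the fitted `scores`
#'   data.frame (identifier columns plus `pc1_score`, `qci`), and fit
#'   metadata (`n_fit`, `n_dropped`, `call`).
#' @examples
#' ratios <- data.frame(
#'   location = letters[1:6], year = 2019L, sex = "both",
#'   r_pi = c(7, 6, 5, 4, 3, 2), r_mi = c(.1, .2, .3, .4, .5, .6),
#'   r_dp = c(.5, .6, .7, .8, .9, 1), r_ly = c(1, 2, 3, 4, 5, 6)
#' )
#' fit <- qci(ratios)
#' fit$scores
#' @export
qci <- function(x, ...) UseMethod("qci")

#' @rdname qci
#' @export
qci.data.frame <- function(x, ...) {
  if ("measure" %in% names(x)) x <- compute_ratios(x)
  std <- standardize_ratios(x)
  model <- fit_ratio_pca(std$z)
  model <- orient_pc1(model, std$z)
  s <- model$orientation_sign * drop(std$z %*% model$loadings[, 1L])
  scale_min <- min(s)
  scale_max <- max(s)
  if (scale_max - scale_min <= 0) {
    stop("degenerate fit: all pooled PC1 scores identical")
  }
  qvals <- 100 * (scale_max - s) / (scale_max - scale_min)

  id_cols <- intersect(c("location", "year", "sex"), names(x))
  scores <- if (length(id_cols)) x[id_cols] else
    data.frame(obs = seq_len(nrow(x)))
  scores$pc1_score <- NA_real_
  scores$qci <- NA_real_
  scores$pc1_score[std$keep] <- s
  scores$qci[std$keep] <- qvals
  rownames(scores) <- NULL

  structure(list(
    means = std$means, sds = std$sds,
    loadings = model$loadings,
    explained_variance = model$explained_variance,
    orientation_sign = model$orientation_sign,
    scale_min = scale_min, scale_max = scale_max,
    scores = scores,
    n_fit = sum(std$keep), n_dropped = sum(!std$keep),
    call = match.call()
  ), class = "qci")
}

#' @rdname qci
#' @export
qci.matrix <- function(x, ...) {
  if (is.null(colnames(x))) colnames(x) <- ratio_cols
  qci.data.frame(as.data.frame(x), ...)
}

#' Score new observations on a fitted QCI scale
#'
#' Applies a frozen QCI model to new ratio rows: z-scores with the stored
#' means/sds, projects onto the oriented first component, and min-max
#' rescales with the stored pooled anchors.  Out-of-pool rows can fall
#' outside the anchors and are clamped to `[0, 100]`.  Rows with any
#' non-finite ratio get `NA` scores.
#'
#' @param object A fitted `"qci"` object.
#' @param newdata Ratio table or matrix with columns `r_pi`, `r_mi`,
#'   `r_dp`, `r_ly`; a canonical burden table is converted with
#'   [compute_ratios()].  Defaults to re-returning the fitted scores.
#' @param ... Unused.
#' @return Data.frame of identifier columns plus `pc1_score` and `qci`.
#' @export
predict.qci <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  x <- as.data.frame(newdata)
  if ("measure" %in% names(x)) x <- compute_ratios(x)
  if (is.null(names(x)) || !all(ratio_cols %in% names(x))) {
    if (ncol(x) == 4L) names(x) <- ratio_cols else
      stop("newdata must contain columns ", paste(ratio_cols, collapse = ", "))
  }
  m <- as.matrix(x[ratio_cols])
  storage.mode(m) <- "double"
  ok <- rowSums(!is.finite(m)) == 0L
  z <- sweep(sweep(m, 2L, object$means, "-"), 2L, object$sds, "/")
  s <- object$orientation_sign * drop(z %*% object$loadings[, 1L])
  q <- 100 * (object$scale_max - s) / (object$scale_max - object$scale_min)
  q <- clamp(q, 0, 100)
  id_cols <- intersect(c("location", "year", "sex"), names(x))
  out <- if (length(id_cols)) x[id_cols] else
    data.frame(obs = seq_len(nrow(x)))
  out$pc1_score <- ifelse(ok, s, NA_real_)
  out$qci <- ifelse(ok, q, NA_real_)
  rownames(out) <- NULL
  out
}

#' @export
print.qci <- function(x, digits = 3, ...) {
  cat("Quality of Care Index (first principal component of 4 care ratios)\n")
  cat(sprintf("  observations fitted: %d (%d incomplete dropped)\n",
              x$n_fit, x$n_dropped))
  pct <- 100 * x$explained_variance[1L] / sum(x$explained_variance)
  cat(sprintf("  PC1 explains %.1f%% of standardized-ratio variance\n", pct))
  cat("  oriented PC1 loadings (larger score = worse care):\n")
  print(round(coef(x), digits))
  cat(sprintf("  score anchors: [%.*f, %.*f] -> QCI 100 (best) .. 0 (worst)\n",
              digits, x$scale_min, digits, x$scale_max))
  invisible(x)
}

#' @export
coef.qci <- function(object, ...) {
  object$orientation_sign * object$loadings[, 1L]
}

#' @export
summary.qci <- function(object, ...) {
  ev <- object$explained_variance
  structure(list(
    loadings = object$loadings,
    explained_variance = ev,
    prop_variance = ev / sum(ev),
    orientation_sign = object$orientation_sign,
    anchors = c(scale_min = object$scale_min, scale_max = object$scale_max),
    n_fit = object$n_fit, n_dropped = object$n_dropped,
    qci_summary = summary(object$scores$qci)
  ), class = "summary.qci")
}

#' @export
print.summary.qci <- function(x, digits = 3, ...) {
  cat("QCI model summary\n\nLoadings (pre-orientation sign convention):\n")
  print(round(x$loadings, digits))
  cat("\nExplained variance (of 4):\n")
  print(round(x$explained_variance, digits))
  cat(sprintf("\nPC1 share: %.1f%%; orientation sign: %+d\n",
              100 * x$prop_variance[1L], x$orientation_sign))
  cat(sprintf("Fitted on %d observations (%d dropped as incomplete)\n",
              x$n_fit, x$n_dropped))
  cat("\nQCI distribution over the fitting pool:\n")
  print(x$qci_summary)
  invisible(x)
}

#' @export
fitted.qci <- function(object, ...) object$scores$qci

#' Plot QCI trends by sex
#'
#' Base-graphics line plot of the mean QCI per year for each sex present
#' in the fitted scores.
#'
#' @param x A `"qci"` object whose scores carry `year` (and optionally
#'   `sex`) columns.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.qci <- function(x, ...) {
  sc <- x$scores
  if (!"year" %in% names(sc)) stop("fitted scores carry no year column")
  if (!"sex" %in% names(sc)) sc$sex <- "all"
  agg <- stats::aggregate(qci ~ year + sex, data = sc, FUN = mean)
  wide <- stats::reshape(agg, idvar = "year", timevar = "sex",
                         direction = "wide")
  wide <- wide[order(wide$year), , drop = FALSE]
  ys <- as.matrix(wide[, -1L, drop = FALSE])
  graphics::matplot(wide$year, ys, type = "l", lty = 1, lwd = 2,
                    xlab = "Year", ylab = "Mean QCI (0-100)", ...)
  graphics::legend("bottomright", legend = sub("^qci\\.", "", colnames(ys)),
                   lty = 1, lwd = 2, col = seq_len(ncol(ys)), bty = "n")
  invisible(x)
}

#' Save / load a fitted QCI model as JSON
#'
#' Serialises the model parameters (not the fitted scores) so that new
#' tables can be scored on exactly the same 0-100 scale later.
#'
#' @param object A `"qci"` object.
#' @param path JSON file path.
#' @return `write_qci_model` returns `path` invisibly; `read_qci_model`
#'   returns a `"qci"` object (without fitted scores) usable with
#'   [predict.qci()].
#' @export
write_qci_model <- function(object, path) {
  stopifnot(inherits(object, "qci"))
  payload <- list(
    means = as.list(object$means),
    sds = as.list(object$sds),
    loadings = object$loadings,
    explained_variance = object$explained_variance,
    orientation_sign = object$orientation_sign,
    scale_min = object$scale_min,
    scale_max = object$scale_max
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qci_model
#' @export
read_qci_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- as.matrix(p$loadings)
  dimnames(loadings) <- list(ratio_cols, paste0("PC", seq_len(ncol(loadings))))
  structure(list(
    means = unlist(p$means), sds = unlist(p$sds),
    loadings = loadings,
    explained_variance = p$explained_variance,
    orientation_sign = p$orientation_sign,
    scale_min = p$scale_min, scale_max = p$scale_max,
    scores = NULL, n_fit = NA_integer_, n_dropped = NA_integer_,
    call = NULL
  ), class = "qci")
}
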
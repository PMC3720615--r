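# Comparison of total vs basal/derived richness surfaces: Pearson
# correlations over cells, and model-II regression between Moran's I
# correlograms with one-delete jackknife standard errors.

#' Pearson correlation between two per-cell richness vectors
#'
#' Plain sample Pearson correlation, with the contracts the pipeline
#' needs spelled out: at least three cells and positive variance on both
#' sides (a zero-variance surface has no defined correlation).  Pass only
#' occupied cells (total richness >= 1); cells where the subset is absent
#' legitimately contribute zeros.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 3L) stop("need at least 3 cells")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

.model2_slope <- function(x, y, method) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0) stop("zero variance in x: model-II slope undefined")
  r <- if (sy == 0) 0 else stats::cor(x, y)
  if (method == "rma") {
    s <- if (r == 0) 1 else sign(r)   # sign convention: positive at r = 0
    s * sy / sx
  } else {
    v <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)$vectors[, 1L]
    v[2L] / v[1L]
  }
}

#' Model-II (RMA or major-axis) regression
#'
#' Fits a model-II regression of `y` on `x`, treating both variables as
#' subject to error.  `method = "rma"` (reduced major axis, the default)
#' uses `slope = sign(r) * sd(y)/sd(x)`; `method = "ma"` (major axis) takes
#' the slope of the principal eigenvector of the covariance matrix.  In
#' both cases the line passes through the centroid, and `r_squared` is the
#' squared Pearson correlation.  When `r = 0` the RMA slope's sign is
#' undefined; the positive sign is used and a warning raised.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must vary.
#' @param method `"rma"` or `"ma"`.
#' @return Object of class `model2_fit`: list with `method`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @examples
#' model2_fit(c(0, 1, 2), c(0, 4, 2))$slope  # 2
#' @export
model2_fit <- function(x, y, method = c("rma", "ma")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("`x` and `y` must be finite")
  if (stats::sd(y) > 0 && stats::sd(x) > 0 && stats::cor(x, y) == 0 &&
      method == "rma")
    warning("r = 0: RMA slope sign undefined, using positive")
  slope <- .model2_slope(x, y, method)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  structure(
    list(method = method, slope = slope,
         intercept = mean(y) - slope * mean(x),
         r_squared = r2, n = length(x),
         se_slope = NA_real_, se_r_squared = NA_real_),
    class = "model2_fit"
  )
}

#' @export
print.model2_fit <- function(x, ...) {
  se <- function(v) if (is.na(v)) "" else sprintf(" ± %.3g", v)
  cat(sprintf("Model-II regression (%s), n = %d\n",
              toupper(x$method), x$n))
  cat(sprintf("  slope = %.4g%s, intercept = %.4g\n",
              x$slope, se(x$se_slope), x$intercept))
  cat(sprintf("  R^2 = %.4g%s\n", x$r_squared, se(x$se_r_squared)))
  invisible(x)
}

#' @export
coef.model2_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' One-delete jackknife standard errors for a model-II fit
#'
#' Recomputes slope and R-squared on each leave-one-out sample and returns
#' `SE = sqrt(((n - 1)/n) * sum((theta_i - mean(theta))^2))`.  Replicates
#' whose leave-one-out sample is degenerate (zero variance in `x`) are
#' excluded and counted.
#'
#' @inheritParams model2_fit
#' @return List with `se_slope`, `se_r_squared`, `n_replicates`,
#'   `n_dropped`.
#' @export
model2_jackknife <- function(x, y, method = c("rma", "ma")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 4L) stop("need at least 4 points for the one-delete jackknife")
  reps <- lapply(seq_len(n), function(i) {
    xi <- x[-i]; yi <- y[-i]
    if (stats::sd(xi) == 0) return(NULL)
    c(slope = .model2_slope(xi, yi, method),
      r2 = if (stats::sd(yi) == 0) 0 else stats::cor(xi, yi)^2)
  })
  ok <- !vapply(reps, is.null, logical(1))
  mat <- do.call(rbind, reps[ok])
  m <- nrow(mat)
  if (m < 2L) stop("too many degenerate jackknife replicates")
  jse <- function(v) sqrt((m - 1) / m * sum((v - mean(v))^2))
  list(se_slope = jse(mat[, "slope"]),
       se_r_squared = jse(mat[, "r2"]),
       n_replicates = m,
       n_dropped = n - m)
}

#' Compare two Moran's I correlograms by model-II regression
#'
#' Regresses the Moran's I values of a subset's richness correlogram (y)
#' against those of the total-richness correlogram (x) across the shared
#' distance classes, so a slope near 1 with high R-squared means the subset
#' mirrors the total's spatial structure.  Standard errors come from the
#' one-delete jackknife over distance classes.
#'
#' @param total,subset `correlogram` data frames over identical distance
#'   classes.
#' @param method `"rma"` (default) or `"ma"`.
#' @param swap If `TRUE`, regress total on subset instead.
#' @return A `model2_fit` with jackknife `se_slope` / `se_r_squared` filled
#'   in and an `n_dropped_classes` attribute counting classes where either
#'   I was undefined.
#' @export
compare_correlograms <- function(total, subset, method = c("rma", "ma"),
                                 swap = FALSE) {
  method <- match.arg(method)
  if (nrow(total) != nrow(subset) ||
      !isTRUE(all.equal(total$class_lo_km, subset$class_lo_km)) ||
      !isTRUE(all.equal(total$class_hi_km, subset$class_hi_km)))
    stop("correlograms must share identical distance classes")
  ok <- is.finite(total$moran_i) & is.finite(subset$moran_i)
  dropped <- sum(!ok)
  if (sum(ok) < 3L)
    stop("fewer than 3 distance classes with defined Moran's I in both")
  x <- total$moran_i[ok]
  y <- subset$moran_i[ok]
  if (swap) { tmp <- x; x <- y; y <- tmp }
  fit <- model2_fit(x, y, method)
  if (sum(ok) >= 4L) {
    jk <- model2_jackknife(x, y, method)
    fit$se_slope <- jk$se_slope
    fit$se_r_squared <- jk$se_r_squared
  }
  attr(fit, "n_dropped_classes") <- dropped
  fit
}
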
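# Moran's I correlograms with a Monte-Carlo permutation null.
#
# Weights are binary and unstandardized within each distance class (the
# classical distance-class correlogram): w_ij = 1 iff the pair's distance
# falls in the class.  Distances are Euclidean in the equal-area plane (km),
# consistent with the grid construction.

#' Build distance classes over cell coordinates
#'
#' Enumerates all unordered cell pairs, computes their Euclidean distances
#' in the projected plane, and assigns each pair to one of `n_classes`
#' half-open distance classes `[e_i, e_{i+1})` (the maximum distance is
#' included in the last class).  With `rule = "equal_width"` the edges are
#' equally spaced from 0 to the maximum pairwise distance; with
#' `rule = "equal_pairs"` they sit at empirical distance quantiles so the
#' classes hold approximately equal numbers of pairs.
#'
#' @param coords Two-column matrix of cell coordinates in km (e.g.
#'   `grid$cells[, c("x_km", "y_km")]`).
#' @param n_classes Number of distance classes (default 10).
#' @param rule `"equal_width"` (default) or `"equal_pairs"`.
#' @return Object of class `distance_classes`: list with `edges` (length
#'   `n_classes + 1`), `pair_i`, `pair_j`, `pair_class`, `counts`, `n`.
#' @export
make_distance_classes <- function(coords, n_classes = 10,
                                  rule = c("equal_width", "equal_pairs")) {
  rule <- match.arg(rule)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells")
  d <- as.vector(stats::dist(coords))
  dmax <- max(d)
  if (dmax == 0) stop("all cells coincident")
  if (rule == "equal_width") {
    edges <- seq(0, dmax, length.out = n_classes + 1L)
  } else {
    edges <- unname(stats::quantile(d, probs = seq(0, 1,
                                                   length.out = n_classes + 1L),
                                    type = 7))
    edges <- unique(edges)
    if (length(edges) < n_classes + 1L)
      warning("tied distance quantiles reduced the class count to ",
              length(edges) - 1L)
  }
  cls <- findInterval(d, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  cls[cls > length(edges) - 1L] <- length(edges) - 1L
  # unordered pair indices matching stats::dist ordering (column-major)
  pair_i <- sequence((n - 1L):1L, from = 2:n)
  pair_j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  structure(
    list(edges = edges, pair_i = pair_i, pair_j = pair_j,
         pair_class = cls,
         counts = tabulate(cls, nbins = length(edges) - 1L),
         n = n),
    class = "distance_classes"
  )
}

#' @export
print.distance_classes <- function(x, ...) {
  cat(sprintf("Distance classes: %d classes over %d cells (%d pairs)\n",
              length(x$edges) - 1L, x$n, length(x$pair_class)))
  print(data.frame(lo_km = x$edges[-length(x$edges)],
                   hi_km = x$edges[-1L], pairs = x$counts))
  invisible(x)
}

#' Moran's I for one distance class
#'
#' Computes `I = (n / S0) * sum_{i != j} w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)` and binary symmetric weights marking the pairs of the
#' requested class (`S0` is the number of ordered weighted pairs).
#'
#' @param values Numeric vector of per-cell values, aligned with the
#'   coordinates used in [make_distance_classes()].
#' @param dc A `distance_classes` object.
#' @param class_index Which class to use (1-based).
#' @return Moran's I, or an error for zero-variance values / empty classes.
#' @export
morans_i <- function(values, dc, class_index) {
  stopifnot(inherits(dc, "distance_classes"))
  if (length(values) != dc$n)
    stop("`values` must have one entry per cell")
  if (!all(is.finite(values))) stop("`values` must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("zero variance: Moran's I undefined")
  sel <- dc$pair_class == class_index
  npair <- sum(sel)
  if (npair == 0L) stop("distance class ", class_index, " holds no pairs")
  cross <- sum(z[dc$pair_i[sel]] * z[dc$pair_j[sel]])
  dc$n * cross / (npair * ss)
}

#' Monte-Carlo permutation test for Moran's I
#'
#' Randomly permutes the values across cells `n_perm` times and compares
#' the observed I of one distance class against the permutation
#' distribution: `p = (1 + #extreme) / (n_perm + 1)`, two-sided by default
#' (extreme means `|I_perm| >= |I_obs|`).
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (default 200).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The permutation p-value in `(0, 1]`.
#' @export
permutation_test <- function(values, dc, class_index, n_perm = 200,
                             seed = NULL,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  i_obs <- morans_i(values, dc, class_index)
  if (!is.null(seed)) set.seed(seed)
  sel <- dc$pair_class == class_index
  pi <- dc$pair_i[sel]; pj <- dc$pair_j[sel]
  npair <- length(pi)
  z0 <- values - mean(values)
  ss <- sum(z0^2)
  i_perm <- vapply(seq_len(n_perm), function(b) {
    z <- z0[sample.int(dc$n)]
    dc$n * sum(z[pi] * z[pj]) / (npair * ss)
  }, numeric(1))
  extreme <- if (alternative == "two.sided") {
    abs(i_perm) >= abs(i_obs)
  } else {
    i_perm >= i_obs
  }
  (1 + sum(extreme)) / (n_perm + 1)
}

#' Moran's I correlogram
#'
#' Computes Moran's I and its permutation p-value for every distance class.
#' One shared set of permutations is used across classes for efficiency.
#' If the number of cells exceeds `max_cells` (guarding the quadratic pair
#' storage), a seeded random subsample of `max_cells` cells is analysed and
#' recorded in the result's attributes.
#'
#' @param values Per-cell values (finite; drop unoccupied/NA cells first).
#' @param coords Two-column matrix of the same cells' projected km
#'   coordinates.
#' @param n_classes Number of distance classes (default 10).
#' @param n_perm Number of permutations (default 200).
#' @param seed Optional integer seed (subsampling and permutations).
#' @param max_cells Cell-count cap (default 3000).
#' @param rule Binning rule, see [make_distance_classes()].
#' @param alternative Sidedness of the permutation test.
#' @return Data frame of class `latgrad_correlogram` with columns `class_lo_km`,
#'   `class_hi_km`, `pairs`, `moran_i`, `p_value`; attributes `n_cells`,
#'   `n_perm`, `seed`, `subsampled`.  Zero-variance values yield `NA`
#'   statistics with a warning.
#' @export
correlogram <- function(values, coords, n_classes = 10, n_perm = 200,
                        seed = NULL, max_cells = 3000,
                        rule = c("equal_width", "equal_pairs"),
                        alternative = c("two.sided", "greater")) {
  rule <- match.arg(rule)
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords))
    stop("`values` and `coords` must describe the same cells")
  if (!all(is.finite(values)))
    stop("`values` must be finite (drop NA cells first)")
  if (!is.null(seed)) set.seed(seed)
  subsampled <- FALSE
  if (length(values) > max_cells) {
    keep <- sort(sample.int(length(values), max_cells))
    values <- values[keep]
    coords <- coords[keep, , drop = FALSE]
    subsampled <- TRUE
  }
  dc <- make_distance_classes(coords, n_classes, rule)
  k <- length(dc$edges) - 1L
  res <- data.frame(
    class_lo_km = dc$edges[-length(dc$edges)],
    class_hi_km = dc$edges[-1L],
    pairs = dc$counts,
    moran_i = NA_real_,
    p_value = NA_real_
  )
  z0 <- values - mean(values)
  ss <- sum(z0^2)
  if (ss == 0) {
    warning("zero variance: Moran's I undefined for every class")
  } else {
    prod_obs <- z0[dc$pair_i] * z0[dc$pair_j]
    cross_obs <- .class_sums(prod_obs, dc$pair_class, k)
    i_obs <- ifelse(dc$counts > 0, dc$n * cross_obs / (dc$counts * ss), NA)
    extreme <- numeric(k)
    for (b in seq_len(n_perm)) {
      z <- z0[sample.int(dc$n)]
      cross <- .class_sums(z[dc$pair_i] * z[dc$pair_j], dc$pair_class, k)
      i_perm <- dc$n * cross / (dc$counts * ss)
      hit <- if (alternative == "two.sided") {
        abs(i_perm) >= abs(i_obs)
      } else {
        i_perm >= i_obs
      }
      extreme <- extreme + ifelse(is.na(hit), 0, hit)
    }
    res$moran_i <- i_obs
    res$p_value <- ifelse(is.na(i_obs), NA_real_,
                          (1 + extreme) / (n_perm + 1))
  }
  attr(res, "n_cells") <- dc$n
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "subsampled") <- subsampled
  class(res) <- c("latgrad_correlogram", "data.frame")
  res
}

# per-class sums of a pair-aligned vector
.class_sums <- function(v, cls, k) {
  out <- numeric(k)
  s <- rowsum(v, cls, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' @export
plot.latgrad_correlogram <- function(x, alpha = 0.05, xlab = "distance (km)",
                             ylab = "Moran's I", ...) {
  mid <- (x$class_lo_km + x$class_hi_km) / 2
  sig <- !is.na(x$p_value) & x$p_value < alpha
  graphics::plot(mid, x$moran_i, type = "b", pch = ifelse(sig, 16, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
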
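test_that("distance classes partition all pairs", {
  # two cells: a single pair in exactly one class
  dc2 <- make_distance_classes(rbind(c(0, 0), c(3, 4)), n_classes = 10)
  expect_equal(sum(dc2$counts), 1L)
  expect_equal(length(dc2$pair_class), 1L)

  # 10x10 unit grid, equal width
  g <- as.matrix(expand.grid(1:10, 1:10))
  dc <- make_distance_classes(g, n_classes = 10)
  dmax <- sqrt(2) * 9
  expect_equal(diff(dc$edges), rep(dmax / 10, 10))
  expect_equal(sum(dc$counts), choose(100, 2))

  # equal-pairs rule balances class sizes
  set.seed(601)
  pts <- matrix(runif(1000, 0, 100), ncol = 2)
  dce <- make_distance_classes(pts, n_classes = 10, rule = "equal_pairs")
  expect_true(all(abs(dce$counts / mean(dce$counts) - 1) < 0.1))

  expect_error(make_distance_classes(rbind(c(1, 1), c(1, 1))), "coincident")
})

test_that("Moran's I is exact on a checkerboard and scale invariant", {
  g <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  v <- (-1)^(g[, 1] + g[, 2])
  dc <- make_distance_classes(g, n_classes = 9)  # class 1 = distance 1 only
  expect_lt(dc$edges[2], sqrt(2))
  expect_gt(dc$edges[2], 1)
  expect_identical(morans_i(v, dc, 1), -1)
  expect_equal(morans_i(10 * v, dc, 1), morans_i(v, dc, 1))
})

test_that("Moran's I matches the naive double loop", {
  set.seed(602)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    co <- matrix(runif(2 * n, 0, 100), ncol = 2)
    vals <- rnorm(n)
    dc <- make_distance_classes(co, n_classes = 5)
    for (k in c(1, 3, 5)) {
      if (dc$counts[k] == 0) next
      expect_equal(morans_i(vals, dc, k),
                   moran_naive(vals, co, dc$edges[k], dc$edges[k + 1],
                               last = (k == 5)),
                   tolerance = 1e-12)
    }
  }
})

test_that("Moran's I is invariant under consistent cell relabelling", {
  set.seed(603)
  n <- 40
  co <- matrix(runif(80), ncol = 2)
  vals <- rnorm(n)
  perm <- sample(n)
  dc1 <- make_distance_classes(co, 5)
  dc2 <- make_distance_classes(co[perm, ], 5)
  for (k in 1:5) {
    if (dc1$counts[k] == 0) next
    expect_equal(morans_i(vals, dc1, k), morans_i(vals[perm], dc2, k),
                 tolerance = 1e-12)
  }
})

test_that("permuted Moran's I is centred near -1/(n-1)", {
  set.seed(604)
  n <- 30
  co <- matrix(runif(60), ncol = 2)
  vals <- rnorm(n)
  dc <- make_distance_classes(co, 5)
  ip <- replicate(10000, morans_i(sample(vals), dc, 2))
  expect_lt(abs(mean(ip) - (-1 / (n - 1))), 3 * stats::sd(ip) / sqrt(10000))
})

test_that("the permutation test is seeded, floored and detects structure", {
  g <- as.matrix(expand.grid(1:10, 1:10))
  dc <- make_distance_classes(g, n_classes = 10)
  # strong gradient: more extreme than every permutation -> p = 1/201
  grad <- g[, 1] + g[, 2]
  expect_equal(permutation_test(grad, dc, 1, n_perm = 200, seed = 5), 1 / 201)
  # determinism
  set.seed(605)
  vals <- rnorm(100)
  expect_identical(permutation_test(vals, dc, 1, n_perm = 200, seed = 7),
                   permutation_test(vals, dc, 1, n_perm = 200, seed = 7))
  # zero variance signalled
  expect_error(morans_i(rep(1, 100), dc, 1), "zero variance")
})

test_that("correlograms flag degenerate input and capture structure", {
  g <- as.matrix(expand.grid(1:20, 1:20))
  # all-zero residuals: undefined everywhere, flagged
  expect_warning(cg0 <- correlogram(rep(0, 400), g, n_perm = 19, seed = 1),
                 "zero variance")
  expect_true(all(is.na(cg0$moran_i)))

  # values equal to the y coordinate (latitude analogue): strong class-1 I
  cg_lat <- correlogram(g[, 2], g, n_perm = 49, seed = 2)
  expect_gt(cg_lat$moran_i[1], 0.5)
  expect_equal(cg_lat$p_value[1], 1 / 50)

  # white noise: weak autocorrelation, nothing significant at alpha = 0.01
  set.seed(606)
  cg_noise <- correlogram(rnorm(400), g, n_perm = 199, seed = 3)
  expect_true(all(abs(cg_noise$moran_i) < 0.1))
  expect_true(all(cg_noise$p_value > 0.01, na.rm = TRUE))
})

test_that("correlograms agree with per-class calls and record subsampling", {
  set.seed(607)
  n <- 60
  co <- matrix(runif(2 * n, 0, 500), ncol = 2)
  vals <- co[, 2] / 100 + rnorm(n)
  cg <- correlogram(vals, co, n_classes = 5, n_perm = 19, seed = 4)
  dc <- make_distance_classes(co, 5)
  for (k in 1:5) {
    if (dc$counts[k] == 0) next
    expect_equal(cg$moran_i[k], morans_i(vals, dc, k), tolerance = 1e-12)
  }
  expect_false(attr(cg, "subsampled"))

  cg_sub <- correlogram(vals, co, n_classes = 5, n_perm = 19, seed = 4,
                        max_cells = 30)
  expect_true(attr(cg_sub, "subsampled"))
  expect_equal(attr(cg_sub, "n_cells"), 30L)
  # same seed -> same subsample -> identical results
  cg_sub2 <- correlogram(vals, co, n_classes = 5, n_perm = 19, seed = 4,
                         max_cells = 30)
  expect_identical(cg_sub, cg_sub2)
})
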
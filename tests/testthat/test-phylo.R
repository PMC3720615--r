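test_that("root distances follow the root-counting convention", {
  tr2 <- ape::read.tree(text = "(A,B);")
  expect_equal(root_distances(tr2), c(A = 1L, B = 1L))

  tr3 <- ape::read.tree(text = "((A,B),C);")
  expect_equal(root_distances(tr3), c(A = 2L, B = 2L, C = 1L))

  # branch lengths are ignored
  trl <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
  expect_equal(root_distances(trl), root_distances(tr3))

  expect_error(root_distances(ape::read.tree(text = "(A);")), "2 tips")
})

test_that("newick reader accepts polytomies and rejects malformed input", {
  tf <- tempfile(fileext = ".nwk")
  on.exit(unlink(tf))
  writeLines("((A,B),(C,D),E);", tf)
  tr <- read_newick(tf)
  n_tip <- length(tr$tip.label)
  expect_equal(n_tip, 5L)
  root_children <- sum(tr$edge[, 1L] == n_tip + 1L)
  expect_equal(root_children, 3L)

  writeLines(c("(A,B);", "(C,D);"), tf)
  expect_error(read_newick(tf), "single tree")

  writeLines("((A,B),A);", tf)
  expect_error(read_newick(tf), "duplicate")
})

test_that("root distances match the brute-force parent walk on random trees", {
  set.seed(401)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    tr <- generate_tree(n, polytomy_prob = sample(c(0, 0.3), 1))
    expect_identical(root_distances(tr), rd_bruteforce(tr))
  }
})

test_that("root distances agree with ape's unit-branch node depths", {
  set.seed(402)
  tr <- generate_tree(40, seed = 77)
  tr$edge.length <- rep(1, nrow(tr$edge))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(root_distances(tr)), depths)
})

test_that("collapsing an internal edge lowers descendant RDs by one", {
  set.seed(403)
  tr <- generate_tree(25, seed = 5)
  n_tip <- length(tr$tip.label)
  tr$edge.length <- rep(1, nrow(tr$edge))
  internal <- which(tr$edge[, 2L] > n_tip)
  e <- internal[5L]
  below <- ape::extract.clade(tr, tr$edge[e, 2L])$tip.label
  tr2 <- tr
  tr2$edge.length[e] <- 0
  tr2 <- ape::di2multi(tr2, tol = 1e-9)
  rd1 <- root_distances(tr)
  rd2 <- root_distances(tr2)[names(rd1)]
  delta <- rd1 - rd2
  expect_true(all(delta[below] == 1L))
  expect_true(all(delta[setdiff(names(rd1), below)] == 0L))
})

test_that("species matching normalizes case and separators only", {
  rd <- c(A_b = 3L, c_D = 5L, Extra_sp = 1L)
  m <- match_species(rd, c("a_b", "C d", "no_rd"))
  expect_equal(m$rd, c(a_b = 3L, `C d` = 5L))
  expect_equal(m$drop_report$unmatched_species, "no_rd")
  expect_equal(m$drop_report$unmatched_tips, "Extra_sp")

  disjoint <- match_species(c(X = 1L), c("Y", "Z"))
  expect_length(disjoint$rd, 0L)
  expect_equal(disjoint$drop_report$n_unmatched_species, 2L)
})

test_that("per-cell MRD is the mean of matched RDs, with shift invariance", {
  pm <- rbind(c(TRUE, TRUE, FALSE),
              c(TRUE, TRUE, TRUE),
              c(FALSE, FALSE, FALSE))
  colnames(pm) <- c("a", "b", "c")
  rd <- c(a = 2, b = 4, c = 6)
  mrd <- mean_root_distance(pm, rd)
  expect_equal(mrd, c(3, 4, NA_real_))

  # every species everywhere -> constant mean RD
  pm_all <- matrix(TRUE, 4, 3, dimnames = list(NULL, names(rd)))
  expect_equal(mean_root_distance(pm_all, rd), rep(mean(rd), 4))

  # adding c to every RD shifts every defined MRD by exactly c
  shift <- mean_root_distance(pm, rd + 7)
  expect_equal(shift, mrd + 7)

  # MRD bounded by the matched RD range wherever defined
  expect_true(all(mrd[is.finite(mrd)] >= min(rd) &
                    mrd[is.finite(mrd)] <= max(rd)))
})

test_that("quartile split uses interpolated quantiles with ties included", {
  rd <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  qs <- quartile_split(rd)
  expect_equal(qs$q1, 1.75)
  expect_equal(qs$q3, 3.25)
  expect_equal(qs$basal, "s1")
  expect_equal(qs$derived, "s4")

  rd8 <- stats::setNames(c(1, 1, 2, 3, 4, 5, 6, 8), paste0("s", 1:8))
  qs8 <- quartile_split(rd8)
  expect_setequal(qs8$basal, c("s1", "s2"))
  expect_setequal(qs8$derived, c("s7", "s8"))

  tied <- stats::setNames(rep(3, 6), paste0("s", 1:6))
  qt <- quartile_split(tied)
  expect_setequal(qt$basal, names(tied))
  expect_setequal(qt$derived, names(tied))

  expect_error(quartile_split(rd[1:3]), "at least 4")
})

test_that("quartile sets cover at least a quarter each and are disjoint", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(8:80, 1)
    rd <- stats::setNames(sample(1:10, n, replace = TRUE), paste0("s", 1:n))
    qs <- quartile_split(rd)
    expect_gte(length(qs$basal), ceiling(0.25 * n))
    expect_gte(length(qs$derived), ceiling(0.25 * n))
    if (qs$q1 < qs$q3)
      expect_length(intersect(qs$basal, qs$derived), 0L)
  }
})
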
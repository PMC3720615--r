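# Independent oracles used across tests.

# Brute-force root distance: walk parent links from each tip to the root,
# counting the edges traversed.  Independent of the preorder sweep used by
# root_distances().
rd_bruteforce <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  vapply(seq_len(n_tip), function(tip) {
    steps <- 0L
    node <- tip
    while (node != root) {
      node <- parent[node]
      steps <- steps + 1L
    }
    steps
  }, integer(1)) |> stats::setNames(tree$tip.label)
}

# Naive O(n^2) Moran's I for one distance band [lo, hi) (hi inclusive when
# `last` so the maximum distance belongs to the final class).
moran_naive <- function(vals, coords, lo, hi, last = FALSE) {
  n <- length(vals)
  z <- vals - mean(vals)
  s <- 0
  S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d >= lo && (d < hi || (last && d <= hi))) {
      s <- s + z[i] * z[j]
      S0 <- S0 + 1
    }
  }
  n * s / (S0 * sum(z^2))
}

# Small scenario used by several pipeline-level tests.
tiny_scenario <- function(n_species = 30, seed = 11, ...) {
  scenario_config(n_species = n_species, bbox = c(-75, -45, -25, 25),
                  seed = seed, ...)
}
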
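# Synthetic trees and range maps with controllable latitudinal structure.
#
# The generator emulates the statistical shape of a continental range-map
# compilation plus a species-level supertree: one polygonal range per
# species over a New World-like bounding box, range sizes spanning orders
# of magnitude (log-normal half-widths), range centroids concentrating
# toward the equator (richness gradient), and a tunable correlation between
# a species' root distance and the absolute latitude of its centroid
# (negative coupling = derived species concentrate near the equator).

#' Scenario configuration for the synthetic generator
#'
#' @param n_species Number of species (tips); at least 2.
#' @param bbox Geographic bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)`; the default mimics the New World extent.
#' @param rd_latitude_coupling Target correlation, in `[-1, 1]`, between a
#'   species' root distance and the absolute latitude of its range centroid.
#'   Negative values concentrate derived (high-RD) species near the equator.
#' @param richness_gradient Non-negative strength of the equator-ward
#'   concentration of range centroids; 0 gives no latitudinal richness
#'   trend beyond edge effects.
#' @param range_halfwidth_log_mean,range_halfwidth_log_sd Log-scale mean and
#'   sd of the log-normal distribution of range half-widths (degrees).
#' @param polytomy_prob Probability in `[0, 1)` that an internal edge of the
#'   simulated tree is collapsed into its parent node.
#' @param seed Integer seed driving every random draw of the scenario.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 300,
                            bbox = c(-120, -35, -55, 55),
                            rd_latitude_coupling = -0.8,
                            richness_gradient = 1,
                            range_halfwidth_log_mean = log(2.5),
                            range_halfwidth_log_sd = 1,
                            polytomy_prob = 0,
                            seed = 1) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2)
    stop("`n_species` must be a single integer >= 2")
  .check_bbox(bbox)
  if (abs(rd_latitude_coupling) > 1)
    stop("`rd_latitude_coupling` must lie in [-1, 1]")
  if (richness_gradient < 0)
    stop("`richness_gradient` must be non-negative")
  if (range_halfwidth_log_sd < 0)
    stop("`range_halfwidth_log_sd` must be non-negative")
  if (polytomy_prob < 0 || polytomy_prob >= 1)
    stop("`polytomy_prob` must lie in [0, 1)")
  structure(
    list(n_species = as.integer(n_species),
         bbox = as.numeric(bbox),
         rd_latitude_coupling = rd_latitude_coupling,
         richness_gradient = richness_gradient,
         range_halfwidth_log_mean = range_halfwidth_log_mean,
         range_halfwidth_log_sd = range_halfwidth_log_sd,
         polytomy_prob = polytomy_prob,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Simulate a pure-birth tree topology
#'
#' Samples a Yule (pure-birth, no extinction) topology with `n_species`
#' uniquely labelled tips (`sp1`, `sp2`, ...).  With positive
#' `polytomy_prob` each internal edge is independently collapsed into its
#' parent with that probability, producing polytomies.  Branch lengths are
#' stripped: only the topology matters for root distances.
#'
#' @param n_species Number of tips (>= 2).
#' @param polytomy_prob Probability in `[0, 1)` of collapsing an internal
#'   edge.
#' @param seed Optional integer seed for reproducibility.
#' @return A `phylo` object.
#' @export
generate_tree <- function(n_species, polytomy_prob = 0, seed = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2)
    stop("`n_species` must be a single integer >= 2")
  if (polytomy_prob < 0 || polytomy_prob >= 1)
    stop("`polytomy_prob` must lie in [0, 1)")
  n_species <- as.integer(n_species)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  if (polytomy_prob > 0 && n_species > 2L) {
    n_tip <- length(tr$tip.label)
    internal_child <- tr$edge[, 2L] > n_tip
    collapse <- internal_child & stats::runif(nrow(tr$edge)) < polytomy_prob
    if (any(collapse)) {
      tr$edge.length[collapse] <- 0
      tr <- ape::di2multi(tr, tol = 1e-12)
    }
  }
  tr$edge.length <- NULL
  tr$tip.label <- paste0("sp", seq_len(length(tr$tip.label)))
  tr
}

#' Generate rectangular species ranges with latitudinal structure
#'
#' Draws one axis-aligned rectangular range per tip of `tree`, clipped to
#' the scenario's bounding box.  Centroid latitudes come from a zero-centred
#' truncated normal whose spread shrinks as `richness_gradient` grows
#' (sd = half the latitudinal span divided by `1 + richness_gradient`), so
#' ranges pile up near the equator.  The coupling between root distance and
#' absolute centroid latitude is imposed by rank-matching through a Gaussian
#' copula: RD ranks are mapped to normal scores, mixed with independent
#' noise at the target correlation, and the drawn latitudes are re-assigned
#' so their absolute-value ranks follow the mixed scores.  Longitudes are
#' uniform; half-widths are log-normal, independently for the two axes.
#'
#' @param tree A `phylo` tree with uniquely labelled tips.
#' @param scenario A [scenario_config()].
#' @return A list with `ranges` (a `range_set`) and `truth` (data frame
#'   `species`, `rd`, `centroid_lon`, `centroid_lat`, `halfwidth_lon`,
#'   `halfwidth_lat`).
#' @export
generate_ranges <- function(tree, scenario) {
  if (!inherits(scenario, "scenario_config"))
    stop("`scenario` must be a scenario_config")
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("tree tip labels must be unique")
  n <- length(tips)
  bbox <- scenario$bbox
  set.seed(scenario$seed + 1L)

  rd <- root_distances(tree)[tips]
  rho <- scenario$rd_latitude_coupling

  # centroid latitudes: truncated normal centred on 0
  halfspan <- (bbox[4L] - bbox[3L]) / 2
  sigma <- halfspan / (1 + scenario$richness_gradient)
  lat <- numeric(0)
  while (length(lat) < n) {
    draw <- stats::rnorm(2L * (n - length(lat)), mean = 0, sd = sigma)
    lat <- c(lat, draw[draw >= bbox[3L] & draw <= bbox[4L]])
  }
  lat <- lat[seq_len(n)]

  # Gaussian-copula rank matching of RD against |latitude|
  z_rd <- stats::qnorm((rank(rd, ties.method = "random") - 0.5) / n)
  z_mix <- rho * z_rd + sqrt(1 - rho^2) * stats::rnorm(n)
  lat <- lat[order(abs(lat))][rank(z_mix, ties.method = "first")]

  lon <- stats::runif(n, bbox[1L], bbox[2L])
  hw_lon <- stats::rlnorm(n, scenario$range_halfwidth_log_mean,
                          scenario$range_halfwidth_log_sd)
  hw_lat <- stats::rlnorm(n, scenario$range_halfwidth_log_mean,
                          scenario$range_halfwidth_log_sd)

  ranges <- vector("list", n)
  names(ranges) <- tips
  for (i in seq_len(n)) {
    x1 <- max(bbox[1L], lon[i] - hw_lon[i])
    x2 <- min(bbox[2L], lon[i] + hw_lon[i])
    y1 <- max(bbox[3L], lat[i] - hw_lat[i])
    y2 <- min(bbox[4L], lat[i] + hw_lat[i])
    m <- cbind(lon = c(x1, x2, x2, x1, x1),
               lat = c(y1, y1, y2, y2, y1))
    ranges[[i]] <- list(m)
  }
  truth <- data.frame(
    species = tips,
    rd = as.integer(rd),
    centroid_lon = lon,
    centroid_lat = lat,
    halfwidth_lon = hw_lon,
    halfwidth_lat = hw_lat
  )
  list(ranges = structure(ranges, class = "range_set"), truth = truth)
}

#' Generate a full synthetic scenario
#'
#' Convenience wrapper: simulates the tree with the scenario's seed, then
#' the ranges and truth table.
#'
#' @param scenario A [scenario_config()].
#' @return List with `tree`, `ranges`, `truth`.
#' @export
generate_scenario <- function(scenario) {
  tree <- generate_tree(scenario$n_species, scenario$polytomy_prob,
                        seed = scenario$seed)
  rt <- generate_ranges(tree, scenario)
  list(tree = tree, ranges = rt$ranges, truth = rt$truth)
}

#' Write a synthetic scenario to disk as a pipeline-readable fixture
#'
#' Writes `tree.nwk` (Newick), `ranges.geojson` (FeatureCollection with a
#' `species` property per feature) and `truth.csv`; the files round-trip
#' through [read_newick()] and [read_ranges()] without loss of the tip and
#' species sets.
#'
#' @param tree A `phylo` tree.
#' @param ranges A `range_set`.
#' @param truth Truth-table data frame from [generate_ranges()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the three files.
#' @export
write_fixture <- function(tree, ranges, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             ranges = file.path(dir, "ranges.geojson"),
             truth = file.path(dir, "truth.csv"))
  ape::write.tree(tree, file = paths[["tree"]])
  feats <- lapply(names(ranges), function(sp) {
    coords <- lapply(ranges[[sp]], function(m) {
      list(lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L])))
    })
    geom <- if (length(coords) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature",
         properties = list(species = sp),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, paths[["ranges"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
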
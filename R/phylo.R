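#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the input contract of
#' the root-distance pipeline: exactly one tree, uniquely labelled tips,
#' polytomies allowed.  Branch lengths, if present, are retained on the
#' returned object but play no role in root distances, which are purely
#' topological.
#'
#' A basal polytomy (root with three or more children) is accepted: the
#' top-level node of the Newick string is always treated as the root.
#'
#' @param path Path to a file containing a single Newick tree.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("could not parse Newick file: ", path)
  if (inherits(trees, "multiPhylo")) {
    if (length(trees) != 1L)
      stop("expected a single tree, found ", length(trees), " in ", path)
    trees <- trees[[1L]]
  }
  if (!inherits(trees, "phylo"))
    stop("could not parse Newick file: ", path)
  if (anyDuplicated(trees$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(trees$tip.label[duplicated(trees$tip.label)]),
               collapse = ", "))
  trees
}

#' Root distances of all tips
#'
#' The root distance (RD) of a species is the number of nodes separating its
#' tip from the root of the tree, counting the root itself and excluding the
#' tip.  Equivalently it is the number of edges on the root-to-tip path.
#' Under this convention both tips of the two-tip tree `(A,B);` have RD 1.
#' Higher RD marks a more derived lineage.  Branch lengths are ignored.
#'
#' @param tree A rooted `phylo` object with at least two tips; polytomies are
#'   allowed.
#' @return Named integer vector of root distances, one per tip.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' root_distances(tr)  # A = B = 2, C = 1
#' @export
root_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  n_node <- tree$Nnode
  depth <- integer(n_tip + n_node)
  # edges in ape preorder when reordered cladewise: parent depth known first
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(edge))) {
    depth[edge[k, 2L]] <- depth[edge[k, 1L]] + 1L
  }
  rd <- depth[seq_len(n_tip)]
  names(rd) <- tree$tip.label
  rd
}

#' Match a root-distance table to the species of a presence matrix
#'
#' Names are normalized before matching: case is folded and runs of spaces
#' are interchangeable with underscores.  No fuzzy matching is attempted —
#' unmatched species are reported, not guessed.
#'
#' @param rd Named vector of root distances (as from [root_distances()]).
#' @param species Character vector of species names (e.g. the species of a
#'   [rasterize()] presence matrix), or a presence matrix itself, in which
#'   case its column names are used.
#' @return A list with `rd`: the matched RD vector named by the *matrix*
#'   spelling of each species; and `drop_report`: a list with the matrix
#'   species lacking an RD (`unmatched_species`), the tree tips lacking
#'   ranges (`unmatched_tips`) and their counts.
#' @export
match_species <- function(rd, species) {
  if (is.matrix(species)) species <- colnames(species)
  stopifnot(is.character(species))
  norm <- function(x) tolower(gsub("[ ]+", "_", x))
  tree_key <- norm(names(rd))
  mat_key <- norm(species)
  idx <- match(mat_key, tree_key)
  matched <- !is.na(idx)
  out <- rd[idx[matched]]
  names(out) <- species[matched]
  report <- list(
    unmatched_species = species[!matched],
    unmatched_tips = names(rd)[!(tree_key %in% mat_key)],
    n_matched = sum(matched),
    n_unmatched_species = sum(!matched),
    n_unmatched_tips = sum(!(tree_key %in% mat_key))
  )
  list(rd = out, drop_report = report)
}

#' Per-cell mean root distance
#'
#' MRD of a cell is the arithmetic mean of the root distances of the
#' RD-matched species present in it.  Cells containing no matched species
#' get `NA` and are excluded from downstream model fitting.
#'
#' @param pm Presence matrix (cells x species, logical), as from
#'   [rasterize()].
#' @param rd Named RD vector; names must identify columns of `pm` (use
#'   [match_species()] first if spellings differ).
#' @return Numeric vector of MRD values, one per row of `pm`.
#' @export
mean_root_distance <- function(pm, rd) {
  if (length(rd) == 0L) stop("`rd` is empty")
  sp <- intersect(names(rd), colnames(pm))
  if (length(sp) == 0L) stop("no RD species found among presence-matrix columns")
  sub <- pm[, sp, drop = FALSE]
  storage.mode(sub) <- "double"
  tot <- as.vector(sub %*% rd[sp])
  n <- rowSums(sub)
  mrd <- tot / n
  mrd[n == 0] <- NA_real_
  mrd
}

#' Split species into basal and derived quartiles of root distance
#'
#' Species are ranked from most basal (lowest RD) to most derived (highest
#' RD).  The basal set holds species with RD at or below the 25th percentile,
#' the derived set those at or above the 75th percentile.  Quartiles are
#' empirical quantiles with linear interpolation on the sorted sample
#' (index `h = p * (n - 1)`, i.e. [stats::quantile()] type 7).  Because RD
#' values are small integers with heavy ties, ties are included on both
#' sides, so each set holds at least 25% of the species; with all RDs equal
#' both sets contain every species.
#'
#' @param rd Named RD vector of at least 4 species.
#' @return List with `basal` and `derived` character vectors of species
#'   names, plus the numeric cut points `q1` and `q3`.
#' @export
quartile_split <- function(rd) {
  if (length(rd) < 4L) stop("need at least 4 species to form quartiles")
  if (is.null(names(rd))) stop("`rd` must be named by species")
  q <- stats::quantile(as.numeric(rd), probs = c(0.25, 0.75),
                       type = 7, names = FALSE)
  list(
    basal = names(rd)[rd <= q[1L]],
    derived = names(rd)[rd >= q[2L]],
    q1 = q[1L],
    q3 = q[2L]
  )
}

#' Assemble the per-cell metrics table
#'
#' Combines richness, matched richness, MRD and basal/derived richness into
#' one data frame aligned with the grid's cells.  Cells with zero total
#' richness are retained but flagged, so callers can exclude them from
#' statistical stages (all fitting functions in this package do).
#'
#' @param pm Presence matrix from [rasterize()].
#' @param rd Matched RD vector (names must be presence-matrix species; see
#'   [match_species()]).
#' @param grid The [build_grid()] grid the matrix was rasterized on.
#' @return Data frame with columns `cell_id`, `x_km`, `y_km`,
#'   `latitude_deg`, `longitude_deg`, `richness`, `matched_richness`,
#'   `mrd`, `basal_richness`, `derived_richness`, `occupied`.
#' @export
cell_metrics <- function(pm, rd, grid) {
  stopifnot(nrow(pm) == nrow(grid$cells))
  split <- quartile_split(rd)
  sp_rd <- intersect(names(rd), colnames(pm))
  data.frame(
    cell_id = grid$cells$cell_id,
    x_km = grid$cells$x_km,
    y_km = grid$cells$y_km,
    latitude_deg = grid$cells$latitude_deg,
    longitude_deg = grid$cells$longitude_deg,
    richness = richness(pm),
    matched_richness = as.integer(rowSums(pm[, sp_rd, drop = FALSE])),
    mrd = mean_root_distance(pm, rd),
    basal_richness = richness(pm, split$basal),
    derived_richness = richness(pm, split$derived),
    occupied = richness(pm) > 0L
  )
}
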
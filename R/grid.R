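# Equal-area grid construction and range rasterization.
#
# The analysis projection is a cylindrical equal-area projection on the
# authalic sphere (R = 6371.0088 km), standard parallel 30 degrees by
# default.  Its closed form
#   x = R * cos(phi_s) * (lon - lon0)          [radians]
#   y = R * sin(lat) / cos(phi_s)
# preserves area exactly (dx dy = R^2 cos(lat) dlon dlat), so 100 x 100 km
# squares in the plane correspond to exactly (100 km)^2 on the sphere.

.EARTH_RADIUS_KM <- 6371.0088

#' Cylindrical equal-area projection
#'
#' Forward-projects geographic coordinates (degrees) to kilometres in a
#' cylindrical equal-area projection.
#'
#' @param lon,lat Numeric vectors of geographic coordinates in degrees.
#' @param lon0 Central meridian in degrees.
#' @param lat_ts Standard parallel in degrees (default 30).
#' @return A list with numeric vectors `x` and `y` in km.
#' @seealso [cea_inverse()]
#' @export
cea_project <- function(lon, lat, lon0 = 0, lat_ts = 30) {
  k <- cos(lat_ts * pi / 180)
  list(
    x = .EARTH_RADIUS_KM * k * (lon - lon0) * pi / 180,
    y = .EARTH_RADIUS_KM * sin(lat * pi / 180) / k
  )
}

#' Inverse cylindrical equal-area projection
#'
#' @param x,y Numeric vectors of projected coordinates in km.
#' @inheritParams cea_project
#' @return A list with numeric vectors `lon` and `lat` in degrees.
#' @export
cea_inverse <- function(x, y, lon0 = 0, lat_ts = 30) {
  k <- cos(lat_ts * pi / 180)
  s <- pmin(1, pmax(-1, y * k / .EARTH_RADIUS_KM))
  list(
    lon = lon0 + (x / (.EARTH_RADIUS_KM * k)) * 180 / pi,
    lat = asin(s) * 180 / pi
  )
}

.check_bbox <- function(bbox) {
  if (length(bbox) != 4L || !is.numeric(bbox) || anyNA(bbox))
    stop("`bbox` must be numeric (lon_min, lon_max, lat_min, lat_max)")
  if (bbox[1L] >= bbox[2L] || bbox[3L] >= bbox[4L])
    stop("degenerate bbox: need lon_min < lon_max and lat_min < lat_max")
  if (bbox[3L] < -90 || bbox[4L] > 90)
    stop("latitude bounds must lie in [-90, 90]")
  invisible(bbox)
}

#' Build an equal-area analysis grid
#'
#' Constructs a lattice of congruent `cell_km` x `cell_km` squares in the
#' cylindrical equal-area plane, covering the projected bounding box.  The
#' grid origin is snapped to the projection's own lattice (multiples of
#' `cell_km` from the projection origin), so grids built over nested
#' bounding boxes with the same projection parameters share cell boundaries.
#'
#' @param bbox Geographic bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)` in degrees.
#' @param cell_km Cell side in km (default 100, i.e. a 100 x 100 km grid).
#' @param lon0 Central meridian; defaults to the bbox centre.
#' @param lat_ts Standard parallel of the projection (default 30).
#' @return An object of class `ea_grid`: a list with `cells` (data frame of
#'   `cell_id`, `x_km`, `y_km` centres, `latitude_deg`, `longitude_deg`),
#'   grid dimensions `nx`, `ny`, the origin, `cell_km` and the projection
#'   parameters.
#' @examples
#' g <- build_grid(c(-120, -35, -55, 55))
#' nrow(g$cells)
#' @export
build_grid <- function(bbox, cell_km = 100, lon0 = NULL, lat_ts = 30) {
  .check_bbox(bbox)
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0)
    stop("`cell_km` must be a positive number")
  if (is.null(lon0)) lon0 <- mean(bbox[1:2])
  p_lo <- cea_project(bbox[1L], bbox[3L], lon0, lat_ts)
  p_hi <- cea_project(bbox[2L], bbox[4L], lon0, lat_ts)
  x0 <- floor(p_lo$x / cell_km) * cell_km
  y0 <- floor(p_lo$y / cell_km) * cell_km
  nx <- ceiling((p_hi$x - x0) / cell_km)
  ny <- ceiling((p_hi$y - y0) / cell_km)
  cx <- x0 + (seq_len(nx) - 0.5) * cell_km
  cy <- y0 + (seq_len(ny) - 0.5) * cell_km
  centers <- expand.grid(x_km = cx, y_km = cy, KEEP.OUT.ATTRS = FALSE)
  geo <- cea_inverse(centers$x_km, centers$y_km, lon0, lat_ts)
  cells <- data.frame(
    cell_id = seq_len(nrow(centers)),
    x_km = centers$x_km,
    y_km = centers$y_km,
    longitude_deg = geo$lon,
    latitude_deg = geo$lat
  )
  structure(
    list(cells = cells, nx = nx, ny = ny, origin = c(x0, y0),
         cell_km = cell_km, lon0 = lon0, lat_ts = lat_ts, bbox = bbox),
    class = "ea_grid"
  )
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf(
    "Equal-area grid: %d x %d cells of %g km (%d total)\n",
    x$nx, x$ny, x$cell_km, nrow(x$cells)))
  cat(sprintf("  bbox (deg): lon [%g, %g], lat [%g, %g]\n",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  cat(sprintf(
    "  cylindrical equal-area, central meridian %g, standard parallel %g\n",
    x$lon0, x$lat_ts))
  invisible(x)
}

# ---- GeoJSON range sets -----------------------------------------------------

.close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

#' Read species ranges from a GeoJSON FeatureCollection
#'
#' Each feature must carry a species-name property (default key
#' `"species"`); multiple features or MultiPolygon parts with the same name
#' are merged into one multi-polygon entry.  Only outer rings are used;
#' interior rings (holes) are dropped with a warning.  Rings with fewer than
#' three distinct vertices are rejected, naming the species.
#'
#' @param path Path to a GeoJSON file (WGS84 lon/lat).
#' @param property Name of the feature property holding the species name.
#' @return A `range_set`: a named list, one element per species, each a list
#'   of matrices with columns `lon`, `lat` (closed rings).
#' @export
read_ranges <- function(path, property = "species") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection in ", path)
  out <- list()
  holes <- 0L
  for (f in gj$features) {
    sp <- f$properties[[property]]
    if (is.null(sp))
      stop("feature without a \"", property, "\" property in ", path)
    sp <- as.character(sp)
    geom <- f$geometry
    polys <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type \"", geom$type,
           "\" for species ", sp)
    )
    for (rings in polys) {
      if (length(rings) > 1L) holes <- holes + length(rings) - 1L
      ring <- rings[[1L]]  # outer ring
      m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))))
      colnames(m) <- c("lon", "lat")
      m <- .close_ring(m)
      if (nrow(unique(m[-nrow(m), , drop = FALSE])) < 3L)
        stop("degenerate ring (fewer than 3 distinct vertices) for species ",
             sp)
      out[[sp]] <- c(out[[sp]], list(m))
    }
  }
  if (holes > 0L)
    warning(holes, " interior ring(s) (holes) ignored")
  structure(out, class = "range_set")
}

#' @export
print.range_set <- function(x, ...) {
  cat("Range set:", length(x), "species,",
      sum(lengths(x)), "polygon(s)\n")
  invisible(x)
}

# ---- polygon clipping -------------------------------------------------------

# Sutherland-Hodgman clip of a (closed or open) polygon against the
# half-plane keep(p) with boundary intersection inter(p, q).
.clip_halfplane <- function(poly, keep, inter) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2L)
  prev <- poly[n, ]
  prev_in <- keep(prev)
  for (i in seq_len(n)) {
    cur <- poly[i, ]
    cur_in <- keep(cur)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, inter(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, inter(prev, cur))
    }
    prev <- cur
    prev_in <- cur_in
  }
  out
}

# Clip polygon (matrix, open ring) to axis-aligned rectangle
# [xlo, xhi] x [ylo, yhi]; returns clipped vertex matrix (possibly 0 rows).
.clip_rect <- function(poly, xlo, xhi, ylo, yhi) {
  ix <- function(p, q, val, ax) {
    t <- (val - p[ax]) / (q[ax] - p[ax])
    p + t * (q - p)
  }
  poly <- .clip_halfplane(poly, function(p) p[1] >= xlo,
                          function(p, q) ix(p, q, xlo, 1))
  poly <- .clip_halfplane(poly, function(p) p[1] <= xhi,
                          function(p, q) ix(p, q, xhi, 1))
  poly <- .clip_halfplane(poly, function(p) p[2] >= ylo,
                          function(p, q) ix(p, q, ylo, 2))
  .clip_halfplane(poly, function(p) p[2] <= yhi,
                  function(p, q) ix(p, q, yhi, 2))
}

# Shoelace area (absolute) of an open-ring vertex matrix.
.ring_area <- function(m) {
  n <- nrow(m)
  if (n < 3L) return(0)
  x <- m[, 1]; y <- m[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# ---- rasterization ----------------------------------------------------------

.is_axis_rect <- function(m) {
  ux <- unique(m[, 1]); uy <- unique(m[, 2])
  length(ux) == 2L && length(uy) == 2L
}

#' Rasterize species ranges onto an equal-area grid
#'
#' A species is marked present in a cell if its projected range polygon
#' overlaps the cell square with positive area (the default convention for
#' presence-absence gridding of range maps); a polygon merely touching a
#' cell boundary does not count.  With `rule = "centroid"` a species is
#' present only in cells whose centre falls inside one of its polygons.
#' Geographic polygon vertices are projected into the grid's equal-area
#' plane; edges are treated as straight segments there (exact for the
#' lon/lat-aligned rectangles produced by [generate_ranges()]).
#'
#' Species whose ranges miss the grid entirely keep an all-`FALSE` column
#' and trigger a warning.
#'
#' @param ranges A `range_set` from [read_ranges()] or [generate_ranges()].
#' @param grid An `ea_grid` from [build_grid()].
#' @param rule Occupancy rule, `"area"` (default) or `"centroid"`.
#' @return Logical matrix, cells x species, with the grid's `cell_id` order
#'   as rows and species as columns.
#' @export
rasterize <- function(ranges, grid, rule = c("area", "centroid")) {
  rule <- match.arg(rule)
  if (!inherits(grid, "ea_grid")) stop("`grid` must be an ea_grid")
  if (length(ranges) == 0L) stop("`ranges` is empty")
  if (anyDuplicated(names(ranges))) stop("duplicate species in range set")
  cell <- grid$cell_km
  x0 <- grid$origin[1L]; y0 <- grid$origin[2L]
  nx <- grid$nx; ny <- grid$ny
  n_cells <- nx * ny
  pm <- matrix(FALSE, nrow = n_cells, ncol = length(ranges),
               dimnames = list(NULL, names(ranges)))
  eps <- 1e-9 * cell * cell  # area tolerance
  eps_len <- 1e-9 * cell     # length tolerance for the rectangle fast path
  missed <- character(0)
  for (s in seq_along(ranges)) {
    sp <- names(ranges)[s]
    hit <- logical(n_cells)
    for (m in ranges[[s]]) {
      pr <- cea_project(m[, 1], m[, 2], grid$lon0, grid$lat_ts)
      if (anyNA(pr$x) || anyNA(pr$y))
        stop("projection failure for species ", sp)
      pm_xy <- cbind(pr$x, pr$y)
      # drop duplicated closing vertex for clipping
      if (isTRUE(all.equal(pm_xy[1, ], pm_xy[nrow(pm_xy), ])))
        pm_xy <- pm_xy[-nrow(pm_xy), , drop = FALSE]
      # candidate cell index window
      i_lo <- max(1L, floor((min(pm_xy[, 1]) - x0) / cell) + 1L)
      i_hi <- min(nx, ceiling((max(pm_xy[, 1]) - x0) / cell))
      j_lo <- max(1L, floor((min(pm_xy[, 2]) - y0) / cell) + 1L)
      j_hi <- min(ny, ceiling((max(pm_xy[, 2]) - y0) / cell))
      if (i_lo > i_hi || j_lo > j_hi) next
      if (rule == "centroid") {
        for (j in j_lo:j_hi) for (i in i_lo:i_hi) {
          cxy <- c(x0 + (i - 0.5) * cell, y0 + (j - 0.5) * cell)
          if (.point_in_poly(cxy, pm_xy)) hit[(j - 1L) * nx + i] <- TRUE
        }
      } else if (.is_axis_rect(pm_xy)) {
        # fast path: strict-overlap index ranges for axis-aligned rectangles
        rx <- range(pm_xy[, 1]); ry <- range(pm_xy[, 2])
        ii <- i_lo:i_hi
        ii <- ii[rx[1] < x0 + ii * cell - eps_len &
                   rx[2] > x0 + (ii - 1) * cell + eps_len]
        jj <- j_lo:j_hi
        jj <- jj[ry[1] < y0 + jj * cell - eps_len &
                   ry[2] > y0 + (jj - 1) * cell + eps_len]
        if (length(ii) && length(jj))
          hit[as.vector(outer(ii, (jj - 1L) * nx, `+`))] <- TRUE
      } else {
        for (j in j_lo:j_hi) for (i in i_lo:i_hi) {
          clp <- .clip_rect(pm_xy,
                            x0 + (i - 1) * cell, x0 + i * cell,
                            y0 + (j - 1) * cell, y0 + j * cell)
          if (.ring_area(clp) > eps) hit[(j - 1L) * nx + i] <- TRUE
        }
      }
    }
    if (!any(hit)) missed <- c(missed, sp)
    pm[, s] <- hit
  }
  if (length(missed))
    warning("range(s) outside the gridded domain for: ",
            paste(missed, collapse = ", "))
  pm
}

# even-odd ray-casting point-in-polygon
.point_in_poly <- function(p, m) {
  n <- nrow(m)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((m[i, 2] > p[2]) != (m[j, 2] > p[2])) {
      xint <- m[j, 1] + (p[2] - m[j, 2]) / (m[i, 2] - m[j, 2]) *
        (m[i, 1] - m[j, 1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Per-cell species richness
#'
#' Counts the species present in each cell, optionally restricted to a
#' subset (e.g. one family, or the basal/derived quartile sets from
#' [quartile_split()]).  Richness is additive over disjoint subsets.
#'
#' @param pm Presence matrix from [rasterize()].
#' @param species Optional character vector naming a subset of the matrix's
#'   species.
#' @return Integer vector of per-cell counts.
#' @export
richness <- function(pm, species = NULL) {
  if (is.null(species)) return(as.integer(rowSums(pm)))
  unknown <- setdiff(species, colnames(pm))
  if (length(unknown))
    stop("unknown species in subset: ", paste(unknown, collapse = ", "))
  as.integer(rowSums(pm[, species, drop = FALSE]))
}
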
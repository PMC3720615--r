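test_that("the projection is equal-area and invertible", {
  # cells map back to exactly (cell_km)^2 of spherical surface
  g <- build_grid(c(-120, -35, -55, 55), cell_km = 100)
  R <- 6371.0088
  k <- cos(30 * pi / 180)
  idx <- seq(1, nrow(g$cells), by = 97)
  for (i in idx) {
    x <- g$cells$x_km[i]; y <- g$cells$y_km[i]
    lo <- cea_inverse(x - 50, y - 50, g$lon0, g$lat_ts)
    hi <- cea_inverse(x + 50, y + 50, g$lon0, g$lat_ts)
    area <- R^2 * (hi$lon - lo$lon) * pi / 180 *
      (sin(hi$lat * pi / 180) - sin(lo$lat * pi / 180))
    expect_lt(abs(area - 100^2) / 100^2, 0.005)
  }
  # round trip and equator mapping
  p <- cea_project(-70, 0, g$lon0, g$lat_ts)
  expect_equal(p$y, 0)
  inv <- cea_inverse(p$x, p$y, g$lon0, g$lat_ts)
  expect_equal(inv$lat, 0, tolerance = 1e-6)
  expect_equal(inv$lon, -70, tolerance = 1e-9)
  # grid cell latitudes match the inverse-projected centres
  expect_equal(g$cells$latitude_deg,
               cea_inverse(g$cells$x_km, g$cells$y_km, g$lon0, g$lat_ts)$lat)
})

test_that("grids over nested bboxes share cell centres", {
  big <- build_grid(c(-120, -35, -55, 55), lon0 = -77.5)
  small <- build_grid(c(-90, -60, -20, 20), lon0 = -77.5)
  key <- function(g) paste(round(g$cells$x_km, 6), round(g$cells$y_km, 6))
  expect_true(all(key(small) %in% key(big)))
})

test_that("degenerate bboxes and cell sizes are rejected", {
  expect_error(build_grid(c(-10, -10, 0, 10)), "degenerate")
  expect_error(build_grid(c(-10, 10, 5, -5)), "degenerate")
  expect_error(build_grid(c(-10, 10, 0, 5), cell_km = 0), "positive")
})

test_that("GeoJSON ranges merge features by species", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = list(species = "sp_a"),
           geometry = list(type = "Polygon", coordinates = list(list(
             c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))))),
      list(type = "Feature", properties = list(species = "sp_a"),
           geometry = list(type = "Polygon", coordinates = list(list(
             c(5, 5), c(6, 5), c(6, 6), c(5, 6), c(5, 5)))))
    )
  )
  tf <- tempfile(fileext = ".geojson")
  on.exit(unlink(tf))
  jsonlite::write_json(gj, tf, auto_unbox = TRUE, digits = NA)
  rs <- read_ranges(tf)
  expect_length(rs, 1L)
  expect_length(rs$sp_a, 2L)

  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       tf, auto_unbox = TRUE)
  expect_length(read_ranges(tf), 0L)

  gj$features[[1L]]$properties <- list(name = "x")
  jsonlite::write_json(gj, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_ranges(tf), "species")
})

test_that("synthetic fixtures round-trip through the readers", {
  syn <- generate_scenario(tiny_scenario(n_species = 20, seed = 2))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture(syn$tree, syn$ranges, syn$truth, dir)
  rs <- read_ranges(file.path(dir, "ranges.geojson"))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_length(rs, 20L)
  expect_setequal(names(rs), tr$tip.label)
  expect_setequal(names(rs), syn$truth$species)
})

test_that("rasterization obeys the positive-area occupancy rule", {
  grid <- build_grid(c(0, 4, 0, 4), cell_km = 100, lon0 = 2, lat_ts = 0)
  # covering the whole bbox
  whole <- structure(list(all = list(cbind(lon = c(0, 4, 4, 0, 0),
                                           lat = c(0, 0, 4, 4, 0)))),
                     class = "range_set")
  pm <- rasterize(whole, grid)
  expect_true(all(pm[, "all"]))

  # strictly inside one cell
  ll <- cea_inverse(grid$origin[1] + c(10, 30), grid$origin[2] + c(10, 30),
                    grid$lon0, grid$lat_ts)
  inside <- structure(list(tiny = list(cbind(
    lon = ll$lon[c(1, 2, 2, 1, 1)], lat = ll$lat[c(1, 1, 2, 2, 1)]))),
    class = "range_set")
  expect_equal(sum(rasterize(inside, grid)), 1L)

  # straddling the boundary of two horizontally adjacent cells
  lls <- cea_inverse(grid$origin[1] + c(80, 120), grid$origin[2] + c(10, 30),
                     grid$lon0, grid$lat_ts)
  straddle <- structure(list(s = list(cbind(
    lon = lls$lon[c(1, 2, 2, 1, 1)], lat = lls$lat[c(1, 1, 2, 2, 1)]))),
    class = "range_set")
  expect_equal(sum(rasterize(straddle, grid)), 2L)

  # touching a boundary without overlap does not count
  llt <- cea_inverse(grid$origin[1] + c(100, 140), grid$origin[2] + c(10, 30),
                     grid$lon0, grid$lat_ts)
  touch <- structure(list(t = list(cbind(
    lon = llt$lon[c(1, 2, 2, 1, 1)], lat = llt$lat[c(1, 1, 2, 2, 1)]))),
    class = "range_set")
  pm_t <- rasterize(touch, grid)
  expect_equal(sum(pm_t), 1L)

  # a range entirely off-grid warns and leaves an all-false column
  off <- structure(c(whole, list(gone = list(cbind(lon = c(50, 51, 51, 50, 50),
                                                   lat = c(50, 50, 51, 51, 50))))),
                   class = "range_set")
  expect_warning(pm_off <- rasterize(off, grid), "gone")
  expect_false(any(pm_off[, "gone"]))
})

test_that("area and centroid occupancy rules differ as documented", {
  grid <- build_grid(c(0, 4, 0, 4), cell_km = 100, lon0 = 2, lat_ts = 0)
  # sliver overlapping two cells but containing only one centre
  ll <- cea_inverse(grid$origin[1] + c(40, 110), grid$origin[2] + c(40, 60),
                    grid$lon0, grid$lat_ts)
  rs <- structure(list(s = list(cbind(
    lon = ll$lon[c(1, 2, 2, 1, 1)], lat = ll$lat[c(1, 1, 2, 2, 1)]))),
    class = "range_set")
  expect_equal(sum(rasterize(rs, grid, rule = "area")), 2L)
  expect_equal(sum(rasterize(rs, grid, rule = "centroid")), 1L)
})

test_that("general polygons rasterize through the clipping path", {
  grid <- build_grid(c(0, 4, 0, 4), cell_km = 100, lon0 = 2, lat_ts = 0)
  # triangle spanning several cells (not an axis-aligned rectangle)
  ll <- cea_inverse(grid$origin[1] + c(20, 380, 200),
                    grid$origin[2] + c(20, 20, 380),
                    grid$lon0, grid$lat_ts)
  tri_m <- cbind(lon = ll$lon[c(1, 2, 3, 1)], lat = ll$lat[c(1, 2, 3, 1)])
  tri <- structure(list(tri = list(tri_m)), class = "range_set")
  pm <- rasterize(tri, grid)
  # the three corner cells must be hit, and a cell far outside must not
  hit_cells <- which(pm[, 1L])
  corner_ids <- c(1L, 4L, 3L * grid$nx + 3L)  # row-major ids of corners
  expect_true(all(corner_ids %in% hit_cells))
  expect_lt(length(hit_cells), nrow(pm))
})

test_that("richness is additive, monotone and double-count consistent", {
  syn <- generate_scenario(tiny_scenario(n_species = 25, seed = 4))
  grid <- build_grid(c(-75, -45, -25, 25), cell_km = 200)
  pm <- rasterize(syn$ranges, grid)
  sp <- colnames(pm)
  parts <- split(sp, rep(1:3, length.out = length(sp)))
  total <- richness(pm)
  expect_equal(total,
               richness(pm, parts[[1]]) + richness(pm, parts[[2]]) +
                 richness(pm, parts[[3]]))
  # double-counting identity
  expect_equal(sum(total), sum(colSums(pm)))
  # dropping a species never increases any cell's richness
  expect_true(all(richness(pm[, -1, drop = FALSE]) <= total))
  expect_error(richness(pm, "not_a_species"), "unknown species")
})
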
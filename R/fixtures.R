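#' Specification of the synthetic toy bay
#'
#' The toy bay is a deterministic, seed-controlled stand-in for a real
#' estuary margin: a cross-shore elevation ramp from subtidal (-3 m
#' MHHW-equivalent) in the west to upland (+2 m) in the east with additive
#' Gaussian noise on the LiDAR-error scale, a subsided diked polygon sitting
#' near -1.5 m, an urbanized polygon on the upland fringe, a subtidal
#' channel, two subregions with distinct low/high SSC and OM attributes, and
#' a 3 x 3 array of synthetic tide gauges encoding a known, gently varying
#' tidal-datum field so the NAVD88-to-MHHW round trip is verifiable against
#' truth.
#'
#' @param n_rows,n_cols Domain size in cells (>= 10 each).
#' @param cellsize Cell size in meters (default 5).
#' @param noise_sd Gaussian elevation noise, m (default 0.05).
#' @param seed Integer seed; fully determines all outputs.
#' @return A `toy_bay_spec` list.
#' @export
toy_bay_spec <- function(n_rows = 200, n_cols = 200, cellsize = 5,
                         noise_sd = 0.05, seed = 1L) {
  if (n_rows < 10 || n_cols < 10) {
    stop("toy bay domain must be at least 10 x 10 cells", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, cellsize = cellsize,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "toy_bay_spec")
}

#' Generate the synthetic toy bay
#'
#' @param spec A [toy_bay_spec()].
#' @return A list: `elev_navd` (`marsh_grid`, NAVD88), `truth_mhhw`
#'   (`marsh_grid`, the MHHW-referenced elevations the datum pipeline should
#'   recover), `gauges` (tibble of synthetic tide gauges with
#'   `mhhw_minus_mllw` and `navd_to_mllw` offsets), `subregions` (attributed
#'   polygon tibble), `veg` (class raster), `veg_corrections` (named
#'   vector), `diked`, `urban` (mask grids).
#' @export
#' @examples
#' bay <- make_toy_bay(toy_bay_spec(n_rows = 40, n_cols = 40))
#' table(classify_habitat(round_10cm(bay$truth_mhhw$values)))
make_toy_bay <- function(spec = toy_bay_spec()) {
  stopifnot(inherits(spec, "toy_bay_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cellsize
  width <- nc * cs; height <- nr * cs
  g0 <- marsh_grid(matrix(NA_real_, nr, nc), 0, 0, cs, datum = "MHHW")
  ctr <- grid_centers(g0)
  X <- matrix(rep(ctr$x, each = nr), nr, nc)
  Y <- matrix(rep(ctr$y, times = nc), nr, nc)

  # cross-shore ramp west (subtidal) -> east (upland), plus seeded noise
  truth <- -3 + 5 * X / width
  withr::with_seed(spec$seed, {
    truth <- truth + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  })

  # subtidal channel meandering north-south through the lower intertidal
  ch_x <- 0.25 * width + 0.05 * width * sin(2 * pi * Y / height)
  truth[abs(X - ch_x) < 2.5 * cs] <- -2.6

  # subsided diked polygon on the marsh plain; urban block on the upland edge
  diked_poly <- cbind(x = c(0.55, 0.75, 0.75, 0.55) * width,
                      y = c(0.10, 0.10, 0.35, 0.35) * height)
  urban_poly <- cbind(x = c(0.85, 1.00, 1.00, 0.85) * width,
                      y = c(0.55, 0.55, 0.95, 0.95) * height)
  in_diked <- matrix(point_in_polygon(as.vector(X), as.vector(Y),
                                      diked_poly[, 1], diked_poly[, 2]), nr, nc)
  truth[in_diked] <- -1.5                         # subsided, flat
  in_urban <- matrix(point_in_polygon(as.vector(X), as.vector(Y),
                                      urban_poly[, 1], urban_poly[, 2]), nr, nc)

  truth_mhhw <- marsh_grid(truth, 0, 0, cs, datum = "MHHW")

  # known, gently varying datum fields (a few cm across the domain, so an
  # all-points IDW of the gauge samples recovers them to ~1 cm)
  range_field <- function(x, y) 1.80 + 0.02 * x / width - 0.015 * y / height
  zmllw_field <- function(x, y) 0.15 + 0.01 * x / width + 0.02 * y / height
  mhhw_navd <- zmllw_field(X, Y) + range_field(X, Y)   # NAVD height of MHHW
  elev_navd <- marsh_grid(truth + mhhw_navd, 0, 0, cs, datum = "NAVD88")

  gx <- rep(c(0.1, 0.5, 0.9) * width, times = 3)
  gy <- rep(c(0.1, 0.5, 0.9) * height, each = 3)
  gauges <- tibble::tibble(
    gauge = paste0("G", seq_along(gx)), x = gx, y = gy,
    mhhw_minus_mllw = range_field(gx, gy),
    navd_to_mllw = -zmllw_field(gx, gy)
  )

  # two subregions split north/south, attributes on the tested grids
  subregions <- tibble::tibble(
    id = c(1, 2),
    name = c("north_muddy", "south_clear"),
    ssc_low = c(100, 25), ssc_high = c(300, 150),
    om_low = c(1, 1), om_high = c(3, 2),
    geometry = list(
      cbind(x = c(0, width, width, 0), y = c(height / 2, height / 2, height, height)),
      cbind(x = c(0, width, width, 0), y = c(0, 0, height / 2, height / 2))
    )
  )

  # vegetation: dense-mat class on the northern marsh plain biases the
  # NAVD88 surface upward; correction restores it
  veg_vals <- matrix(NA_real_, nr, nc)
  veg_sel <- truth > -0.5 & truth < 0.3 & Y > height / 2
  veg_vals[veg_sel] <- 2
  veg_corrections <- c(`2` = -0.30)
  elev_navd$values[veg_sel] <- elev_navd$values[veg_sel] + 0.30

  list(
    elev_navd = elev_navd,
    truth_mhhw = truth_mhhw,
    gauges = gauges,
    subregions = subregions,
    veg = marsh_grid(veg_vals, 0, 0, cs, datum = "class"),
    veg_corrections = veg_corrections,
    diked = marsh_grid(in_diked * 1, 0, 0, cs, datum = "mask"),
    urban = marsh_grid(in_urban * 1, 0, 0, cs, datum = "mask"),
    spec = spec
  )
}

#' Materialize toy-bay fixture files
#'
#' Writes the toy bay to disk in the formats the pipeline reads: ASCII grids
#' for rasters and masks, GeoJSON for subregions, CSV for gauges and the
#' vegetation correction table.
#'
#' @param spec A [toy_bay_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_toy_bay <- function(spec = toy_bay_spec(), dir = ".") {
  bay <- make_toy_bay(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_ascii_grid(bay$elev_navd, p("elevation_navd88.asc"))
  write_ascii_grid(bay$veg, p("vegetation.asc"))
  write_ascii_grid(bay$diked, p("diked_mask.asc"))
  write_ascii_grid(bay$urban, p("urban_mask.asc"))
  write_polygons_geojson(bay$subregions, p("subregions.geojson"))
  readr::write_csv(bay$gauges, p("gauges.csv"))
  readr::write_csv(tibble::tibble(class = names(bay$veg_corrections),
                                  correction_m = unname(bay$veg_corrections)),
                   p("veg_corrections.csv"))
  invisible(c(elevation = p("elevation_navd88.asc"),
              vegetation = p("vegetation.asc"),
              diked = p("diked_mask.asc"), urban = p("urban_mask.asc"),
              subregions = p("subregions.geojson"), gauges = p("gauges.csv"),
              corrections = p("veg_corrections.csv")))
}
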
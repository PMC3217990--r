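#' Lightweight georeferenced grid
#'
#' A minimal raster container: a numeric matrix (rows top-down, columns
#' west-east) with a cell size and the coordinates of the lower-left corner.
#' Cell extents are half-open, anchored at the upper-left; cell centers are
#' at `xll + (j - 0.5) * cellsize`. Values are meters (elevation) or integer
#' class codes; `NA` is nodata.
#'
#' @param values Numeric matrix.
#' @param xll,yll Map coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length in map units (m).
#' @param datum Free-text tag for what the values are referenced to
#'   (e.g. `"NAVD88"`, `"MHHW"`, `"class"`).
#' @return A `marsh_grid` object.
#' @export
marsh_grid <- function(values, xll = 0, yll = 0, cellsize = 5,
                       datum = "NAVD88") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, datum = datum),
            class = "marsh_grid")
}

#' @export
print.marsh_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<marsh_grid> %d x %d cells of %g m (%s); range [%.3g, %.3g], %d nodata\n",
    nrow(v), ncol(v), x$cellsize, x$datum,
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.marsh_grid <- function(x) dim(x$values)

# cell-center coordinates
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(x = g$xll + (seq_len(nc) - 0.5) * g$cellsize,
       y = g$yll + (nr - seq_len(nr) + 0.5) * g$cellsize)
}

#' @export
as_tibble.marsh_grid <- function(x, ...) {
  ctr <- grid_centers(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep(ctr$x, each = nr),
    y = rep(ctr$y, times = nc),
    value = as.vector(x$values)
  )
}

#' @export
autoplot.marsh_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble.marsh_grid(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)",
                  fill = object$datum) +
    ggplot2::theme_minimal()
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Inverse-distance-weighted surface from scattered points
#'
#' Second-order (power 2 by default) inverse-distance weighting using all
#' points: each cell takes \eqn{\sum w_i v_i / \sum w_i} with
#' \eqn{w_i = d_i^{-p}}; a cell whose center coincides with a point takes
#' that point's value. This is how sparse tide-gauge datum offsets are
#' spread into continuous offset surfaces.
#'
#' @param points Data frame with columns `x`, `y`, `value`.
#' @param grid_spec A `marsh_grid` (values ignored) or a list with `nrow`,
#'   `ncol`, `xll`, `yll`, `cellsize` defining the output geometry.
#' @param power IDW exponent (default 2).
#' @return A `marsh_grid` of interpolated values.
#' @export
idw_surface <- function(points, grid_spec, power = 2) {
  if (!is.data.frame(points) || nrow(points) == 0) {
    stop("`points` must be a non-empty data frame with x, y, value",
         call. = FALSE)
  }
  g <- if (inherits(grid_spec, "marsh_grid")) grid_spec else
    marsh_grid(matrix(NA_real_, grid_spec$nrow, grid_spec$ncol),
               grid_spec$xll, grid_spec$yll, grid_spec$cellsize)
  ctr <- grid_centers(g)
  cx <- rep(ctr$x, each = nrow(g$values))   # column-major over (row, col)
  cy <- rep(ctr$y, times = ncol(g$values))
  d2 <- outer(cx, points$x, `-`)^2 + outer(cy, points$y, `-`)^2
  w <- d2^(-power / 2)
  exact <- d2 < 1e-18
  vals <- as.vector((w %*% points$value) / rowSums(w))
  if (any(exact)) {
    hit <- which(exact, arr.ind = TRUE)
    vals[hit[, 1]] <- points$value[hit[, 2]]
  }
  marsh_grid(matrix(vals, nrow(g$values), ncol(g$values)),
             g$xll, g$yll, g$cellsize, datum = "idw")
}

#' Bilinear resampling of a grid
#'
#' Resamples a (typically coarse) grid to a target geometry by bilinear
#' interpolation of cell-center values, clamping outside the source's
#' center extent to the edge values. Used to bring the 100-m datum-offset
#' surfaces onto the 5-m elevation grid.
#'
#' @param grid Source `marsh_grid`.
#' @param target `marsh_grid` (values ignored) defining the output geometry.
#' @return A `marsh_grid` with the target geometry.
#' @export
resample_bilinear <- function(grid, target) {
  src <- grid$values
  sc <- grid_centers(grid)
  tc <- grid_centers(target)
  fx <- stats::approx(sc$x, seq_along(sc$x), xout = tc$x, rule = 2)$y
  # sc$y decreases with row index; interpolate on the reversed axis
  fy <- stats::approx(rev(sc$y), rev(seq_along(sc$y)), xout = tc$y,
                      rule = 2)$y
  i0 <- pmin(pmax(floor(fy), 1), nrow(src) - 1); ti <- fy - i0
  j0 <- pmin(pmax(floor(fx), 1), ncol(src) - 1); tj <- fx - j0
  out <- matrix(NA_real_, length(fy), length(fx))
  for (r in seq_along(fy)) {
    a <- src[i0[r], j0] * (1 - tj) + src[i0[r], j0 + 1] * tj
    b <- src[i0[r] + 1, j0] * (1 - tj) + src[i0[r] + 1, j0 + 1] * tj
    out[r, ] <- a * (1 - ti[r]) + b * ti[r]
  }
  marsh_grid(out, target$xll, target$yll, target$cellsize, datum = grid$datum)
}

#' Convert NAVD88 elevations to the MHHW reference
#'
#' Applies the datum arithmetic `NAVD88 elevation + MLLW offset - MHHW
#' offset = MHHW elevation` cell by cell: the MLLW offset surface converts
#' geodetic heights to heights above local MLLW, and subtracting the MHHW
#' offset (the local MHHW-MLLW separation) re-references them to MHHW.
#' Nodata propagates.
#'
#' @param elev `marsh_grid` of NAVD88 elevations (m).
#' @param mllw_offset `marsh_grid`; NAVD88-to-MLLW conversion (m).
#' @param mhhw_offset `marsh_grid`; local MHHW minus MLLW (m).
#' @return `marsh_grid` of elevations relative to MHHW.
#' @export
navd_to_mhhw <- function(elev, mllw_offset, mhhw_offset) {
  if (!same_geometry(elev, mllw_offset) || !same_geometry(elev, mhhw_offset)) {
    stop("offset grids are not co-registered with the elevation grid; ",
         "resample them first", call. = FALSE)
  }
  marsh_grid(elev$values + mllw_offset$values - mhhw_offset$values,
             elev$xll, elev$yll, elev$cellsize, datum = "MHHW")
}

#' Apply per-class vegetation elevation corrections
#'
#' LiDAR-style surfaces ride on top of dense vegetation; this subtracts (or
#' adds) a configured per-class offset. Classes present in the raster but
#' absent from the correction table are left unchanged with a warning;
#' nodata vegetation leaves the pixel unchanged.
#'
#' @param elev `marsh_grid` of elevations.
#' @param veg_classes `marsh_grid` of integer or character class codes.
#' @param corrections Named numeric vector: class code -> additive offset
#'   (m).
#' @return Corrected `marsh_grid`.
#' @export
vegetation_correction <- function(elev, veg_classes, corrections) {
  if (!same_geometry(elev, veg_classes)) {
    stop("vegetation raster is not co-registered with the elevation grid",
         call. = FALSE)
  }
  v <- elev$values
  cls <- veg_classes$values
  present <- unique(cls[!is.na(cls)])
  unmapped <- setdiff(as.character(present), names(corrections))
  if (length(unmapped) > 0) {
    warning("vegetation classes without a correction, left unchanged: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  for (nm in intersect(as.character(present), names(corrections))) {
    sel <- !is.na(cls) & as.character(cls) == nm
    v[sel] <- v[sel] + corrections[[nm]]
  }
  marsh_grid(v, elev$xll, elev$yll, elev$cellsize, datum = elev$datum)
}

#' Intertidal habitat classes
#'
#' The elevation bands (m MHHW, applied after rounding to the 10-cm grid so
#' that they tile the elevation axis): upland > 0.3; high marsh 0.2 to 0.3;
#' mid marsh -0.2 to 0.1; low marsh -0.5 to -0.3; mudflat -1.8 to -0.6;
#' subtidal below -1.8 (0 m MLLW under a 1.8-m range).
#'
#' @return Character vector of the six class labels, subtidal first; the
#'   integer codes used in class rasters are the positions in this vector.
#' @export
habitat_classes <- function() {
  c("subtidal", "mudflat", "low_marsh", "mid_marsh", "high_marsh", "upland")
}

#' Classify elevations into intertidal habitat
#'
#' @param x Numeric vector or `marsh_grid` of elevations, m MHHW.
#' @return For a numeric vector, a factor with levels [habitat_classes()];
#'   for a grid, a `marsh_grid` of integer class codes (1 = subtidal ...
#'   6 = upland).
#' @export
#' @examples
#' classify_habitat(c(0, -1, 0.5, -2))
classify_habitat <- function(x) {
  if (inherits(x, "marsh_grid")) {
    codes <- classify_habitat_codes(x$values)
    return(marsh_grid(codes, x$xll, x$yll, x$cellsize, datum = "class"))
  }
  factor(habitat_classes()[classify_habitat_codes(x)],
         levels = habitat_classes())
}

classify_habitat_codes <- function(x) {
  r <- round_10cm(x)
  out <- ifelse(is.na(r), NA_integer_,
         ifelse(r < -1.8 - 1e-9, 1L,
         ifelse(r < -0.6 + 1e-9, 2L,
         ifelse(r < -0.3 + 1e-9, 3L,
         ifelse(r < 0.1 + 1e-9, 4L,
         ifelse(r < 0.3 + 1e-9, 5L, 6L))))))
  if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
}

#' Rasterize attributed polygons onto a grid
#'
#' Cell-center containment (even-odd ray casting). Polygons are supplied as
#' a tibble with an `id` column and a `geometry` list-column of two-column
#' `x, y` matrices (closed implicitly).
#'
#' @param polygons Tibble with `id` and `geometry` columns.
#' @param grid_spec `marsh_grid` defining the output geometry.
#' @return `marsh_grid` of polygon ids (NA where no polygon contains the
#'   cell center).
#' @export
rasterize_polygons <- function(polygons, grid_spec) {
  ctr <- grid_centers(grid_spec)
  nr <- nrow(grid_spec$values); nc <- ncol(grid_spec$values)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = nc)
  out <- rep(NA_real_, nr * nc)
  for (k in seq_len(nrow(polygons))) {
    poly <- polygons$geometry[[k]]
    inside <- point_in_polygon(px, py, poly[, 1], poly[, 2])
    out[inside & is.na(out)] <- polygons$id[k]
  }
  marsh_grid(matrix(out, nr, nc), grid_spec$xll, grid_spec$yll,
             grid_spec$cellsize, datum = "id")
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Project an elevation grid under a scenario
#'
#' Per-pixel application of the response tables: each pixel's elevation is
#' snapped to the 10-cm grid, its subregion's (SSC, OM) attributes select a
#' table, and the projection at year `t` is looked up (or the out-of-bound
#' rules applied). Pixels falling in no subregion become nodata, with their
#' count attached as an attribute.
#'
#' @param elev_mhhw `marsh_grid` of starting elevations, m MHHW.
#' @param subregion_grid `marsh_grid` of subregion ids (from
#'   [rasterize_polygons()]).
#' @param attrs Tibble with `id`, `ssc_low`, `ssc_high`, `om_low`,
#'   `om_high` per subregion.
#' @param scenario List with `ssc_level` (`"low"`/`"high"`), `om_level`
#'   (`"low"`/`"high"`), and `slr` (an [slr_curve()]).
#' @param t Checkpoint year.
#' @param tables Named list of [response_table()]s keyed
#'   `"<ssc>_<om>_<slr label>"` covering every attribute combination used.
#' @return `marsh_grid` of projected elevations (m, future MHHW).
#' @export
project_grid <- function(elev_mhhw, subregion_grid, attrs, scenario, t,
                         tables) {
  if (!same_geometry(elev_mhhw, subregion_grid)) {
    stop("subregion raster is not co-registered with the elevation grid",
         call. = FALSE)
  }
  v <- elev_mhhw$values
  sub <- subregion_grid$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  n_orphan <- sum(!is.na(v) & is.na(sub))
  for (k in seq_len(nrow(attrs))) {
    a <- attrs[k, ]
    ssc <- if (scenario$ssc_level == "high") a$ssc_high else a$ssc_low
    om <- if (scenario$om_level == "high") a$om_high else a$om_low
    key <- paste(ssc, om, scenario$slr$label, sep = "_")
    tab <- tables[[key]]
    if (is.null(tab)) {
      stop("no response table for subregion ", a$id, " (needs ", key, ")",
           call. = FALSE)
    }
    sel <- which(!is.na(sub) & sub == a$id & !is.na(v))
    if (length(sel) == 0) next
    out[sel] <- interpolate_projection(round_10cm(v[sel]), tab, t)
  }
  res <- marsh_grid(out, elev_mhhw$xll, elev_mhhw$yll, elev_mhhw$cellsize,
                    datum = "MHHW")
  attr(res, "n_outside_subregions") <- n_orphan
  res
}

#' Habitat area accounting
#'
#' Counts pixels per (subregion, land status, habitat class) and converts
#' to hectares. Land status precedence is urban > diked > tidal: urbanized
#' pixels are unavailable for restoration regardless of levees.
#'
#' @param class_grid `marsh_grid` of habitat class codes (1-6).
#' @param subregion_grid `marsh_grid` of subregion ids.
#' @param diked_mask,urban_mask Logical-valued `marsh_grid`s (1/0 or
#'   TRUE/FALSE; NA treated as FALSE).
#' @return Tibble: `subregion`, `land_status`, `habitat`, `area_ha`.
#' @export
summarize_areas <- function(class_grid, subregion_grid, diked_mask,
                            urban_mask) {
  for (g in list(subregion_grid, diked_mask, urban_mask)) {
    if (!same_geometry(class_grid, g)) {
      stop("all grids must be co-registered", call. = FALSE)
    }
  }
  px_ha <- class_grid$cellsize^2 / 1e4
  diked <- !is.na(diked_mask$values) & diked_mask$values > 0
  urban <- !is.na(urban_mask$values) & urban_mask$values > 0
  status <- ifelse(urban, "urban", ifelse(diked, "diked", "tidal"))
  keep <- !is.na(class_grid$values)
  tibble::tibble(
    subregion = as.vector(subregion_grid$values)[keep],
    land_status = as.vector(status)[keep],
    habitat = habitat_classes()[as.vector(class_grid$values)[keep]]
  ) |>
    dplyr::count(.data$subregion, .data$land_status, .data$habitat) |>
    dplyr::mutate(area_ha = .data$n * px_ha, n = NULL)
}
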
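#' Read and write Esri ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by rows of
#' values, north to south. This is the raster format the package reads and
#' writes; it round-trips a [marsh_grid()] exactly at the printed precision
#' and is understood by the common GIS tools.
#'
#' @param grid A `marsh_grid`.
#' @param path File path (`.asc`).
#' @param digits Significant digits written (default 6).
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `marsh_grid`.
#' @export
write_ascii_grid <- function(grid, path, digits = 6) {
  v <- grid$values
  nodata <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
    paste("cellsize", grid$cellsize), paste("nodata_value", nodata)
  ), con)
  out <- ifelse(is.na(v), nodata, signif(v, digits))
  writeLines(apply(out, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param datum Datum tag attached to the grid read back.
#' @export
read_ascii_grid <- function(path, datum = "NAVD88") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vals[vals == hdr$nodata_value] <- NA
  marsh_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, datum = datum)
}

#' Write subregion polygons to GeoJSON
#'
#' @param polygons Tibble with `id`, attribute columns and a `geometry`
#'   list-column of `x, y` matrices.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- purrr::map(seq_len(nrow(polygons)), function(i) {
    g <- polygons$geometry[[i]]
    ring <- rbind(g, g[1, , drop = FALSE])
    props <- as.list(polygons[i, setdiff(names(polygons), "geometry")])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  purrr::map_dfr(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) unlist(p)))
    m <- m[-nrow(m), , drop = FALSE]      # drop closing vertex
    out <- tibble::as_tibble(f$properties)
    out$geometry <- list(m)
    out
  })
}
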
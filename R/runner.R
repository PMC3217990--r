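#' Scenario configuration
#'
#' Assembles and validates the configuration driving [run_scenarios()]:
#' tide settings, SLR curve parameters, the scenario factorial, checkpoint
#' years, calibration constants, the fixture seed and the output directory.
#' Unknown fields are rejected and physical values must be nonnegative.
#'
#' @param tide_range Baseline great diurnal range, m.
#' @param duration_days,step_h Tidal month synthesis settings.
#' @param slr_totals Named numeric vector of century totals, m.
#' @param ssc_levels,om_levels Scenario levels evaluated
#'   (`c("low", "high")` by default, matched against subregion attributes).
#' @param checkpoint_years Projection checkpoints (multiples of 20).
#' @param settling_velocity,dry_bulk_density Calibration constants.
#' @param seed Seed for the synthetic fixture.
#' @param outdir Output directory.
#' @param n_rows,n_cols Toy-bay domain size (used when no input files are
#'   given).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(tide_range = 1.8, duration_days = 28,
                            step_h = 0.1,
                            slr_totals = c(low = 0.52, high = 1.65),
                            ssc_levels = c("low", "high"),
                            om_levels = c("low", "high"),
                            checkpoint_years = seq(0, 100, 20),
                            settling_velocity = accretion_params()$settling_velocity,
                            dry_bulk_density = accretion_params()$dry_bulk_density,
                            seed = 1L, outdir = tempfile("marshrise-"),
                            n_rows = 120, n_cols = 120) {
  cfg <- list(tide_range = tide_range, duration_days = duration_days,
              step_h = step_h, slr_totals = slr_totals,
              ssc_levels = ssc_levels, om_levels = om_levels,
              checkpoint_years = checkpoint_years,
              settling_velocity = settling_velocity,
              dry_bulk_density = dry_bulk_density,
              seed = as.integer(seed), outdir = outdir,
              n_rows = n_rows, n_cols = n_cols)
  validate_config(cfg)
}

config_fields <- c("tide_range", "duration_days", "step_h", "slr_totals",
                   "ssc_levels", "om_levels", "checkpoint_years",
                   "settling_velocity", "dry_bulk_density", "seed", "outdir",
                   "n_rows", "n_cols")

#' Validate a scenario configuration
#'
#' @param cfg A named list (e.g. parsed from YAML with [read_config()]).
#' @return The config, classed `scenario_config`; errors name the offending
#'   field.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_fields)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(config_fields, names(cfg))
  if (length(missing) > 0) {
    stop("missing config fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("tide_range", "duration_days", "step_h", "slr_totals",
              "settling_velocity", "dry_bulk_density", "checkpoint_years")) {
    if (any(!is.finite(cfg[[f]])) || any(cfg[[f]] < 0)) {
      stop("config field `", f, "` must be nonnegative and finite",
           call. = FALSE)
    }
  }
  if (is.null(names(cfg$slr_totals)) || any(names(cfg$slr_totals) == "")) {
    stop("config field `slr_totals` must be a named vector", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' @rdname validate_config
#' @param path YAML file with configuration fields (missing fields take the
#'   [scenario_config()] defaults).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$slr_totals)) user$slr_totals <- unlist(user$slr_totals)
  base <- unclass(scenario_config())
  unknown <- setdiff(names(user), config_fields)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(user)] <- user
  validate_config(base)
}

#' Run the end-to-end scenario pipeline
#'
#' Orchestrates the full chain on the synthetic toy bay (or caller-supplied
#' inputs): tidal-month synthesis, datum surfaces from the gauges,
#' NAVD88-to-MHHW conversion with vegetation correction, response tables for
#' every (SSC, OM, SLR) attribute combination, per-pixel projection at each
#' checkpoint, habitat classification, and area accounting by subregion and
#' land status. Diked pixels follow the restoration convention that barriers
#' are removed at the epoch, so they are projected like tidal pixels but
#' reported under the `diked` land status.
#'
#' @param config A [scenario_config()].
#' @param bay Optional toy-bay list from [make_toy_bay()]; generated from
#'   the config seed otherwise.
#' @param write Write rasters, CSVs and the manifest under
#'   `config$outdir`?
#' @return Invisibly, a list with `areas` (tibble over scenario x checkpoint
#'   x stratum), `habitat_grids`, `projected_grids` (keyed
#'   `<scenario>_y<year>`), `elev_mhhw`, `tables`, and `manifest`.
#' @export
run_scenarios <- function(config = scenario_config(), bay = NULL,
                          write = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(bay)) {
    bay <- make_toy_bay(toy_bay_spec(n_rows = config$n_rows,
                                     n_cols = config$n_cols,
                                     seed = config$seed))
  }
  tide <- generate_tidal_month(target_range = config$tide_range,
                               duration_days = config$duration_days,
                               step_h = config$step_h)
  curves <- purrr::imap(config$slr_totals,
                        function(total, label) slr_curve(label, total))

  # datum surfaces: coarse IDW of the gauges, resampled to the grid
  coarse <- marsh_grid(matrix(NA_real_, max(10, config$n_rows %/% 10),
                              max(10, config$n_cols %/% 10)),
                       bay$elev_navd$xll, bay$elev_navd$yll,
                       bay$elev_navd$cellsize * 10)
  mhhw_off <- resample_bilinear(
    idw_surface(dplyr::rename(bay$gauges, value = "mhhw_minus_mllw"), coarse),
    bay$elev_navd)
  mllw_off <- resample_bilinear(
    idw_surface(dplyr::rename(bay$gauges, value = "navd_to_mllw"), coarse),
    bay$elev_navd)
  elev_corr <- vegetation_correction(bay$elev_navd, bay$veg,
                                     bay$veg_corrections)
  elev_mhhw <- navd_to_mhhw(elev_corr, mllw_off, mhhw_off)
  sub_grid <- rasterize_polygons(bay$subregions, elev_mhhw)

  # one response table per attribute combination actually used
  attrs <- bay$subregions[setdiff(names(bay$subregions), "geometry")]
  combos <- purrr::map_dfr(config$ssc_levels, function(sl) {
    purrr::map_dfr(config$om_levels, function(ol) {
      tibble::tibble(
        ssc = if (sl == "high") attrs$ssc_high else attrs$ssc_low,
        om = if (ol == "high") attrs$om_high else attrs$om_low
      )
    })
  })
  combos <- tidyr::expand_grid(dplyr::distinct(combos),
                               slr_label = names(curves))
  tables <- purrr::pmap(combos, function(ssc, om, slr_label) {
    response_table(ssc, om, curves[[slr_label]], tide,
                   settling_velocity = config$settling_velocity,
                   dry_bulk_density = config$dry_bulk_density)
  })
  names(tables) <- paste(combos$ssc, combos$om, combos$slr_label, sep = "_")

  scenarios <- tidyr::expand_grid(ssc_level = config$ssc_levels,
                                  om_level = config$om_levels,
                                  slr_label = names(curves))
  results <- list(projected = list(), habitat = list(), areas = list())
  for (i in seq_len(nrow(scenarios))) {
    sc <- as.list(scenarios[i, ])
    sc$slr <- curves[[sc$slr_label]]
    sc_key <- paste("ssc", sc$ssc_level, "om", sc$om_level, "slr",
                    sc$slr_label, sep = "-")
    for (t in config$checkpoint_years) {
      proj <- if (t == 0) elev_mhhw else
        project_grid(elev_mhhw, sub_grid, attrs, sc, t, tables)
      habitat <- classify_habitat(proj)
      key <- paste0(sc_key, "_y", t)
      results$projected[[key]] <- proj
      results$habitat[[key]] <- habitat
      results$areas[[key]] <- summarize_areas(habitat, sub_grid, bay$diked,
                                              bay$urban) |>
        dplyr::mutate(scenario = sc_key, year = t, .before = 1)
    }
  }
  areas <- dplyr::bind_rows(results$areas)

  manifest <- list(
    config = unclass(config)[setdiff(config_fields, "outdir")],
    scenarios = nrow(scenarios),
    checkpoints = config$checkpoint_years,
    n_pixels = prod(dim(elev_mhhw$values)),
    package_version = as.character(utils::packageVersion("marshrise"))
  )
  if (write) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(areas, file.path(config$outdir, "area_summaries.csv"))
    for (key in names(results$habitat)) {
      write_ascii_grid(results$habitat[[key]],
                       file.path(config$outdir, paste0("habitat_", key, ".asc")))
    }
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(areas = areas, habitat_grids = results$habitat,
                 projected_grids = results$projected,
                 elev_mhhw = elev_mhhw, subregion_grid = sub_grid,
                 tables = tables, manifest = manifest))
}
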
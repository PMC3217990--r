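#' Physical parameters of the accretion model
#'
#' Bundles the per-run physical configuration: suspended sediment
#' concentration (SSC) of the flooding water, the constant organic accretion
#' rate, and the two constants carried inside the Krone-type mass balance -
#' floc settling velocity and dry bulk density of the deposit. The default
#' settling velocity and bulk density are the values frozen by
#' [calibrate_accretion()] against the published sustainability thresholds;
#' see that function and the package vignette for how they were obtained.
#'
#' @param ssc Suspended sediment concentration, mg/L (>= 0).
#' @param om_rate Organic accretion rate, mm/yr (>= 0).
#' @param settling_velocity Floc settling velocity, m/s.
#' @param dry_bulk_density Dry bulk density of newly deposited sediment,
#'   kg/m^3.
#' @return An `accretion_params` list.
#' @export
#' @examples
#' accretion_params(ssc = 150, om_rate = 2)
accretion_params <- function(ssc = 150, om_rate = 2,
                             settling_velocity = 5e-5,
                             dry_bulk_density = 800) {
  stopifnot(ssc >= 0, om_rate >= 0, settling_velocity >= 0,
            dry_bulk_density > 0)
  structure(
    list(ssc = ssc, om_rate = om_rate,
         settling_velocity = settling_velocity,
         dry_bulk_density = dry_bulk_density),
    class = "accretion_params"
  )
}

#' @export
print.accretion_params <- function(x, ...) {
  cat(sprintf(
    "<accretion_params> SSC %g mg/L, OM %g mm/yr, w_s %.3g m/s, rho %g kg/m^3\n",
    x$ssc, x$om_rate, x$settling_velocity, x$dry_bulk_density))
  invisible(x)
}

# Core interval integrator for the per-cycle mass balance, per unit ambient
# concentration (1 kg/m^3). `level` is water level, `bed` the (fixed) bed
# elevation, both in the same datum; `dt_s` the sample interval in seconds.
#
# While the water is rising the column is replenished to the ambient
# concentration and deposits at the flux w_s * C; after local high water the
# column depletes as dC/dt = -w_s C / h(t), integrated exactly over each
# sample interval with h held at the interval mean. Thin films are floored at
# 1 mm to keep the depletion exponent finite. Returns settled mass per unit
# area (kg/m^2) per unit concentration (kg/m^3), i.e. meters.
unit_deposition <- function(level, bed, dt_s, w_s) {
  n <- length(level)
  if (n < 2) return(0)
  d <- level - bed
  d0 <- d[-n]; d1 <- d[-1]
  # wet fraction of each interval, resolving the wetting/drying crossings
  # within an interval (keeps the per-event edge error second order)
  both <- d0 > 0 & d1 > 0
  wetting <- d0 <= 0 & d1 > 0
  drying <- d0 > 0 & d1 <= 0
  frac <- ifelse(both, 1,
          ifelse(wetting, d1 / (d1 - d0),
          ifelse(drying, d0 / (d0 - d1), 0)))
  h <- ifelse(both, (d0 + d1) / 2,
       ifelse(wetting, d1 / 2,
       ifelse(drying, d0 / 2, 0)))
  wet <- frac > 0
  if (!any(wet)) return(0)
  h <- pmax(h, 1e-3)
  dt_i <- dt_s * frac
  rising <- d1 > d0

  dep_rise <- sum(w_s * dt_i[wet & rising])

  fw <- wet & !rising                  # falling, inundated intervals
  if (!any(fw)) return(dep_rise)
  a <- ifelse(fw, w_s * dt_i / h, 0)
  # exclusive cumulative exponent, reset at the start of each falling run
  cs <- cumsum(a)
  run_id <- cumsum(c(fw[1], diff(fw) == 1))  # increments at each run start
  idx <- which(fw)
  run_of <- run_id[idx]
  first_of_run <- !duplicated(run_of)
  base <- (cs[idx] - a[idx])[first_of_run]
  base_full <- base[match(run_of, run_of[first_of_run])]
  expo <- (cs[idx] - a[idx]) - base_full
  dep_fall <- sum(h[idx] * exp(-expo) * (1 - exp(-a[idx])))
  dep_rise + dep_fall
}

#' Sediment deposited over one inundation episode
#'
#' Implements the per-cycle Krone-type mass balance: while the water is
#' rising, the column is replenished at the ambient SSC and deposits at the
#' settling flux \eqn{w_s C}; after local high water the concentration
#' depletes as \eqn{dC/dt = -w_s C / h(t)}. The settled mass is converted to
#' bed-elevation gain through the dry bulk density.
#'
#' @param event A data frame with columns `time_h` and `depth_m` (water depth
#'   above the bed, >= 0 throughout) describing one inundation episode on a
#'   uniform time step.
#' @param params An [accretion_params()].
#' @return Bed elevation gain in meters.
#' @export
#' @examples
#' ev <- tibble::tibble(time_h = seq(0, 6, 0.1),
#'                      depth_m = pmax(0.5 * sin(pi * seq(0, 6, 0.1) / 6), 0))
#' deposition_per_cycle(ev, accretion_params(ssc = 200))
deposition_per_cycle <- function(event, params) {
  stopifnot(is.data.frame(event), all(c("time_h", "depth_m") %in% names(event)))
  if (any(event$depth_m < 0)) stop("depths must be >= 0", call. = FALSE)
  if (nrow(event) < 2) return(0)
  dt_s <- (event$time_h[2] - event$time_h[1]) * 3600
  mass <- unit_deposition(event$depth_m, 0, dt_s, params$settling_velocity)
  mass * (params$ssc / 1000) / params$dry_bulk_density
}

profile_cache <- new.env(parent = emptyenv())

series_key <- function(series) {
  paste(nrow(series), signif(attr(series, "step_h"), 8),
        signif(sum(series$level_m^2), 10), signif(max(series$level_m), 10),
        sep = "|")
}

#' Monthly unit-deposition profile of a tidal month
#'
#' Pre-computes, for a fixed tidal month and settling velocity, the settled
#' mass per unit area and unit concentration accumulated over the whole month
#' as a function of (effective) bed elevation. Because the per-cycle mass
#' balance is linear in the ambient concentration, a single profile serves
#' every SSC level; [simulate_elevation()] looks the profile up once per
#' simulated month, which is what makes century x scenario grids cheap.
#'
#' @param series A `tide_series` from [generate_tidal_month()].
#' @param settling_velocity Floc settling velocity, m/s.
#' @param eff_grid Bed elevations (series datum, m) at which to evaluate;
#'   default a 2-cm grid spanning well below MLLW to above the highest water.
#' @return A `deposition_profile`: function-like object mapping bed elevation
#'   to kg/m^2 deposited per month per (kg/m^3) ambient concentration.
#' @export
deposition_profile <- function(series, settling_velocity, eff_grid = NULL) {
  key <- paste(series_key(series), signif(settling_velocity, 8), sep = "|")
  if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
  if (is.null(eff_grid)) {
    eff_grid <- seq(min(series$level_m) - 4, max(series$level_m), by = 0.02)
  }
  dt_s <- attr(series, "step_h") * 3600
  vals <- vapply(eff_grid, function(b) {
    unit_deposition(series$level_m, b, dt_s, settling_velocity)
  }, numeric(1))
  f <- stats::approxfun(eff_grid, vals, yleft = vals[1], yright = 0, rule = 2)
  out <- structure(
    list(lookup = f, eff_grid = eff_grid, values = vals,
         settling_velocity = settling_velocity,
         month_days = (max(series$time_h) - min(series$time_h)) / 24,
         datums = compute_datums(series)),
    class = "deposition_profile"
  )
  profile_cache[[key]] <- out
  out
}

#' @export
print.deposition_profile <- function(x, ...) {
  cat(sprintf(
    "<deposition_profile> w_s %.3g m/s, %.0f-day month, %d elevation nodes\n",
    x$settling_velocity, x$month_days, length(x$eff_grid)))
  invisible(x)
}

#' Simulate a century of marsh surface elevation
#'
#' Iterates the repeating tidal month over the horizon. Each month the tide is
#' offset upward by the cumulative sea-level rise at the month midpoint
#' (equivalently the bed is lowered within the stationary tidal frame),
#' mineral gain is obtained from the monthly deposition profile scaled by
#' SSC and divided by dry bulk density, and organic gain accrues at the
#' constant rate. Elevations are reported relative to the contemporaneous
#' MHHW (start-of-run MHHW plus cumulative rise) at each checkpoint year.
#'
#' @param start_elevation Starting bed elevation, m relative to MHHW.
#' @param params An [accretion_params()].
#' @param slr An [slr_curve()].
#' @param tide A `tide_series` month.
#' @param horizon Simulation length in years (default 100); must be a
#'   multiple of `checkpoint_step`.
#' @param checkpoint_step Reporting interval in years (default 20).
#' @param profile Optional pre-built [deposition_profile()]; built (and
#'   cached) from `tide` and the params otherwise.
#' @return A `marsh_trajectory` tibble: `year`, `elev_mhhw_m`, `slr_m`,
#'   `total_accretion_m`.
#' @export
#' @examples
#' tide <- generate_tidal_month()
#' simulate_elevation(0, accretion_params(ssc = 250, om_rate = 2),
#'                    slr_curve("high"), tide)
simulate_elevation <- function(start_elevation, params, slr, tide,
                               horizon = 100, checkpoint_step = 20,
                               profile = NULL) {
  stopifnot(inherits(params, "accretion_params"), inherits(slr, "slr_curve"))
  if (horizon <= 0 || horizon %% checkpoint_step != 0) {
    stop("`horizon` must be a positive multiple of `checkpoint_step`",
         call. = FALSE)
  }
  if (is.null(profile)) {
    profile <- deposition_profile(tide, params$settling_velocity)
  }
  mhhw0 <- profile$datums$mhhw_m
  month_yr <- profile$month_days / 365.25
  n_months <- ceiling(horizon / month_yr)
  s_kg <- params$ssc / 1000          # mg/L -> kg/m^3
  om_per_month <- params$om_rate / 1000 * month_yr
  rho <- params$dry_bulk_density

  # inlined linear interpolation on the profile's uniform elevation grid
  # (an approxfun call per simulated month dominates run time otherwise)
  g <- profile$eff_grid
  v <- profile$values
  g0 <- g[1]
  inv <- 1 / (g[2] - g[1])
  n_nodes <- length(g)

  bed <- start_elevation + mhhw0      # series datum
  t_mid <- (seq_len(n_months) - 0.5) * month_yr
  offsets <- slr_elevation(slr, pmin(t_mid, 100))
  bed_path <- numeric(n_months + 1)
  bed_path[1] <- bed
  for (k in seq_len(n_months)) {
    u <- (bed - offsets[k] - g0) * inv
    f <- if (u <= 0) {
      v[1]
    } else if (u >= n_nodes - 1) {
      0
    } else {
      i <- floor(u)
      v[i + 1] + (u - i) * (v[i + 2] - v[i + 1])
    }
    bed <- bed + s_kg * f / rho + om_per_month
    bed_path[k + 1] <- bed
  }
  t_path <- c(0, seq_len(n_months)) * month_yr
  years <- seq(0, horizon, by = checkpoint_step)
  bed_at <- stats::approx(t_path, bed_path, xout = years)$y
  rise <- slr_elevation(slr, pmin(years, 100))
  out <- tibble::tibble(
    year = years,
    elev_mhhw_m = bed_at - mhhw0 - rise,
    slr_m = rise,
    total_accretion_m = bed_at - bed_path[1]
  )
  attr(out, "start_elevation") <- start_elevation
  attr(out, "params") <- params
  attr(out, "slr_label") <- slr$label
  class(out) <- c("marsh_trajectory", class(out))
  out
}

#' @export
#' @rdname simulate_elevation
#' @param x A `marsh_trajectory`.
#' @param ... Unused.
tidy.marsh_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  tibble::as_tibble(x) |>
    dplyr::mutate(
      start_elev_m = attr(x, "start_elevation"),
      ssc_mg_L = p$ssc, om_mm_yr = p$om_rate,
      slr_label = attr(x, "slr_label"),
      .before = 1
    )
}

#' @export
glance.marsh_trajectory <- function(x, ...) {
  tibble::tibble(
    start_elev_m = attr(x, "start_elevation"),
    final_elev_mhhw_m = x$elev_mhhw_m[nrow(x)],
    total_accretion_m = x$total_accretion_m[nrow(x)],
    total_slr_m = x$slr_m[nrow(x)]
  )
}

#' @export
autoplot.marsh_trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data$elev_mhhw_m)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Elevation relative to MHHW (m)") +
    ggplot2::theme_minimal()
}

#' Run the factorial accretion grid
#'
#' Executes one simulation per combination of SSC level, OM rate, SLR curve
#' and starting elevation, with the pairing rule that subtidal starts (below
#' the -1.8 m MHHW subtidal boundary) carry no organic accretion. The stock
#' configuration (7 SSC x 3 OM x 2 SLR x 2 marsh starts, plus 7 SSC x 2 SLR
#' subtidal runs at OM 0) yields 98 runs.
#'
#' @param tide A `tide_series` month.
#' @param ssc_levels SSC grid, mg/L.
#' @param om_rates OM rates, mm/yr (applied to vegetated-marsh starts only).
#' @param slr_curves List of [slr_curve()] objects.
#' @param start_elevations Starting elevations, m MHHW.
#' @param settling_velocity,dry_bulk_density Calibration constants; defaults
#'   from [accretion_params()].
#' @param horizon,checkpoint_step Passed to [simulate_elevation()].
#' @return A tibble with one row per run x checkpoint: `start_elev_m`,
#'   `ssc_mg_L`, `om_mm_yr`, `slr_label`, `year`, `elev_mhhw_m`,
#'   `total_accretion_m`.
#' @export
run_grid <- function(tide,
                     ssc_levels = c(25, 50, 100, 150, 200, 250, 300),
                     om_rates = c(1, 2, 3),
                     slr_curves = list(slr_curve("low"), slr_curve("high")),
                     start_elevations = c(-2.4, -0.5, 0),
                     settling_velocity = accretion_params()$settling_velocity,
                     dry_bulk_density = accretion_params()$dry_bulk_density,
                     horizon = 100, checkpoint_step = 20) {
  if (length(ssc_levels) == 0) stop("`ssc_levels` must be non-empty", call. = FALSE)
  if (length(om_rates) == 0) stop("`om_rates` must be non-empty", call. = FALSE)
  names(slr_curves) <- vapply(slr_curves, `[[`, character(1), "label")
  if (anyDuplicated(names(slr_curves))) {
    stop("duplicate SLR curve labels", call. = FALSE)
  }
  specs <- purrr::map_dfr(start_elevations, function(st) {
    om <- if (st < -1.8) 0 else om_rates
    tidyr::expand_grid(start_elev_m = st, ssc_mg_L = ssc_levels,
                       om_mm_yr = om, slr_label = names(slr_curves))
  })
  if (anyDuplicated(specs)) stop("duplicate run combinations", call. = FALSE)
  profile <- deposition_profile(tide, settling_velocity)
  purrr::pmap_dfr(specs, function(start_elev_m, ssc_mg_L, om_mm_yr, slr_label) {
    traj <- simulate_elevation(
      start_elev_m,
      accretion_params(ssc = ssc_mg_L, om_rate = om_mm_yr,
                       settling_velocity = settling_velocity,
                       dry_bulk_density = dry_bulk_density),
      slr_curves[[slr_label]], tide,
      horizon = horizon, checkpoint_step = checkpoint_step, profile = profile
    )
    tibble::tibble(start_elev_m, ssc_mg_L, om_mm_yr, slr_label,
                   year = traj$year, elev_mhhw_m = traj$elev_mhhw_m,
                   total_accretion_m = traj$total_accretion_m)
  })
}

#' Round an elevation to the 10-cm reporting grid
#'
#' Sustainability decisions and habitat classification operate on elevations
#' rounded to the nearest 10 cm; trajectories themselves stay exact.
#'
#' @param x Elevations in meters.
#' @return `x` rounded to the nearest 0.1 m.
#' @export
round_10cm <- function(x) round(x * 10) / 10
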
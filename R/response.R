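#' Build an elevation-indexed projection table
#'
#' Turns the three anchored accretion runs of one scenario (subtidal -2.4 m,
#' low marsh -0.5 m and mid marsh 0.0 m MHHW; the subtidal anchor carries no
#' organic accretion) into a lookup from any starting elevation on a 10-cm
#' grid to its projected elevation at each checkpoint year. Between anchors
#' the projection is linear. Two boundary pseudo-anchors close the table:
#' at the -4.0 m lower bound the projection equals the start (deep beds keep
#' pace with sea-level rise), and at the scenario upper bound (1.7 m MHHW for
#' the high curve, 0.6 m for the low curve) it equals the start minus the
#' cumulative rise (no accretion potential above the inundated frame), so
#' the interpolated surface blends continuously into both out-of-domain
#' rules applied by [apply_bounds()].
#'
#' @param ssc SSC of the scenario, mg/L.
#' @param om OM rate of the scenario, mm/yr (vegetated-marsh anchors only).
#' @param slr An [slr_curve()].
#' @param tide A `tide_series` month.
#' @param settling_velocity,dry_bulk_density Calibration constants.
#' @param x_grid Starting-elevation grid, m MHHW (default -3.7 to 1.7 by
#'   0.1, clipped to the scenario upper bound).
#' @param checkpoint_step Checkpoint spacing, years.
#' @return A `response_table` tibble: `t_yr`, `x_start_m`, `x_future_m`,
#'   with the anchor runs stored in attributes.
#' @export
response_table <- function(ssc, om, slr, tide,
                           settling_velocity = accretion_params()$settling_velocity,
                           dry_bulk_density = accretion_params()$dry_bulk_density,
                           x_grid = NULL, checkpoint_step = 20) {
  upper <- upper_bound_for(slr)
  if (is.null(x_grid)) x_grid <- seq(-3.7, upper, by = 0.1)
  x_grid <- round_10cm(x_grid)
  anchors <- c(-2.4, -0.5, 0)
  profile <- deposition_profile(tide, settling_velocity)
  runs <- purrr::map(anchors, function(st) {
    simulate_elevation(
      st,
      accretion_params(ssc = ssc, om_rate = if (st < -1.8) 0 else om,
                       settling_velocity = settling_velocity,
                       dry_bulk_density = dry_bulk_density),
      slr, tide, checkpoint_step = checkpoint_step, profile = profile
    )
  })
  years <- runs[[1]]$year
  tab <- purrr::map_dfr(years, function(t) {
    rise <- slr_elevation(slr, t)
    xa <- c(-4, anchors, upper)
    ya <- c(-4, vapply(runs, function(r) r$elev_mhhw_m[r$year == t], numeric(1)),
            upper - rise)
    # enforce the no-crossing ordering before interpolation; trajectories
    # from the physical model cannot cross, but the above-anchor blend can
    # dip under the 0-m anchor when accretion outruns the no-accretion rule
    ya <- cummax(ya)
    tibble::tibble(t_yr = t, x_start_m = x_grid,
                   x_future_m = stats::approx(xa, ya, xout = x_grid)$y)
  })
  attr(tab, "anchors") <- anchors
  attr(tab, "anchor_runs") <- runs
  attr(tab, "upper_bound") <- upper
  attr(tab, "scenario") <- list(ssc = ssc, om = om, slr_label = slr$label,
                                slr = slr)
  class(tab) <- c("response_table", class(tab))
  tab
}

# Upper interpolation bound: the band subject to future tidal inundation.
upper_bound_for <- function(slr) {
  if (slr$century_total >= 1) 1.7 else 0.6
}

#' Interpolate a projected elevation from a response table
#'
#' Two-point linear interpolation between the bracketing anchors of the
#' table's scenario. Starting elevations outside the table domain are
#' routed to [apply_bounds()] rather than extrapolated.
#'
#' @param x Starting elevation(s), m MHHW.
#' @param table A [response_table()].
#' @param t Checkpoint year present in the table.
#' @return Projected elevation(s) relative to the contemporaneous MHHW, m.
#' @export
interpolate_projection <- function(x, table, t) {
  stopifnot(inherits(table, "response_table"))
  sc <- attr(table, "scenario")
  upper <- attr(table, "upper_bound")
  if (!t %in% table$t_yr) {
    stop("checkpoint year ", t, " not present in the table", call. = FALSE)
  }
  runs <- attr(table, "anchor_runs")
  anchors <- attr(table, "anchors")
  rise <- slr_elevation(sc$slr, t)
  xa <- c(-4, anchors, upper)
  ya <- c(-4, vapply(runs, function(r) r$elev_mhhw_m[r$year == t], numeric(1)),
          upper - rise)
  ya <- cummax(ya)
  out <- rep(NA_real_, length(x))
  inside <- x >= -4 & x <= upper
  out[inside] <- stats::approx(xa, ya, xout = x[inside])$y
  if (any(!inside)) out[!inside] <- apply_bounds(x[!inside], t, sc$slr)
  out
}

#' Out-of-domain projection rules
#'
#' Starting elevations below the -4.0 m lower bound are assumed to keep pace
#' with sea-level rise (projection = start); elevations above the scenario
#' upper bound have no accretion potential and simply lose the cumulative
#' rise (projection = start - rise at `t`).
#'
#' @param x Starting elevation(s) outside the interpolation domain, m MHHW.
#' @param t Checkpoint year.
#' @param slr An [slr_curve()].
#' @return Projected elevation(s), m relative to future MHHW.
#' @export
apply_bounds <- function(x, t, slr) {
  upper <- upper_bound_for(slr)
  if (any(x >= -4 & x <= upper)) {
    stop("apply_bounds() received elevations inside the interpolation ",
         "domain [-4, ", upper, "]; use interpolate_projection()",
         call. = FALSE)
  }
  ifelse(x < -4, x, x - slr_elevation(slr, t))
}

#' Years of marsh sustainability
#'
#' Marsh sustainability is zero elevation loss, rounded to the nearest
#' 10 cm: the run is sustained through the last consecutive 20-yr checkpoint
#' at which its elevation relative to contemporaneous MHHW has not dropped
#' below the starting elevation after rounding.
#'
#' @param ssc SSC, mg/L.
#' @param om OM rate, mm/yr.
#' @param slr An [slr_curve()].
#' @param start Starting elevation, m MHHW (-0.5 low marsh, 0 mid marsh).
#' @param tide A `tide_series` month.
#' @param settling_velocity,dry_bulk_density Calibration constants.
#' @return Duration in years (0 when the first checkpoint already fails).
#' @export
sustainability_duration <- function(ssc, om, slr, start,
                                    tide = generate_tidal_month(),
                                    settling_velocity = accretion_params()$settling_velocity,
                                    dry_bulk_density = accretion_params()$dry_bulk_density) {
  traj <- simulate_elevation(
    start,
    accretion_params(ssc = ssc, om_rate = om,
                     settling_velocity = settling_velocity,
                     dry_bulk_density = dry_bulk_density),
    slr, tide
  )
  duration_from_trajectory(traj, start)
}

#' Minimum starting elevation reaching mid marsh
#'
#' Scans the table's 10-cm starting-elevation grid for the lowest start
#' whose projection at the horizon reaches the mid marsh floor (-0.2 m
#' MHHW), reported with the habitat class of that starting elevation. When
#' even the lowest grid elevation qualifies the result is flagged, since
#' still-lower starts outside the modelled range may also qualify.
#'
#' @param table A [response_table()].
#' @param horizon Checkpoint year in the table.
#' @param floor_elev Mid marsh floor, m MHHW (default -0.2).
#' @return One-row tibble: `min_start_m` (NA when unachievable),
#'   `start_class`, `achievable`, `at_lower_limit`.
#' @export
min_start_for_midmarsh <- function(table, horizon, floor_elev = -0.2) {
  stopifnot(inherits(table, "response_table"))
  sl <- dplyr::filter(table, .data$t_yr == horizon)
  if (nrow(sl) == 0) stop("horizon ", horizon, " not in table", call. = FALSE)
  ok <- which(sl$x_future_m >= floor_elev - 1e-9)
  if (length(ok) == 0) {
    return(tibble::tibble(min_start_m = NA_real_, start_class = NA_character_,
                          achievable = FALSE, at_lower_limit = FALSE))
  }
  x <- sl$x_start_m[min(ok)]
  tibble::tibble(
    min_start_m = x,
    start_class = as.character(classify_habitat(x)),
    achievable = TRUE,
    at_lower_limit = min(ok) == 1
  )
}

#' @export
print.response_table <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "<response_table> SSC %g mg/L, OM %g mm/yr, SLR %s (upper bound %.1f m)\n",
    sc$ssc, sc$om, sc$slr_label, attr(x, "upper_bound")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
autoplot.response_table <- function(object, ...) {
  sc <- attr(object, "scenario")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x_start_m, y = .data$x_future_m,
                               colour = factor(.data$t_yr))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Starting elevation (m MHHW)",
      y = "Projected elevation (m MHHW)", colour = "Year",
      title = sprintf("SSC %g mg/L, OM %g mm/yr, SLR %s",
                      sc$ssc, sc$om, sc$slr_label)
    ) +
    ggplot2::theme_minimal()
}

#' Sustainability grid across scenarios
#'
#' Evaluates [sustainability_duration()] over a factorial of SSC, OM, SLR
#' and starting elevations -- the tabular counterpart of a
#' sustainability-matrix figure.
#'
#' @param tide A `tide_series` month.
#' @param ssc_levels,om_rates SSC and OM grids.
#' @param slr_curves Named list of [slr_curve()]s.
#' @param starts Starting elevations, m MHHW.
#' @param ... Calibration constants forwarded to
#'   [sustainability_duration()].
#' @return Tibble with one row per combination and `duration_yr`.
#' @export
sustainability_grid <- function(tide,
                                ssc_levels = c(25, 50, 100, 150, 200, 250, 300),
                                om_rates = c(1, 2, 3),
                                slr_curves = list(low = slr_curve("low"),
                                                  high = slr_curve("high")),
                                starts = c(-0.5, 0), ...) {
  grid <- tidyr::expand_grid(ssc_mg_L = ssc_levels, om_mm_yr = om_rates,
                             slr_label = names(slr_curves),
                             start_elev_m = starts)
  grid$duration_yr <- purrr::pmap_dbl(grid, function(ssc_mg_L, om_mm_yr,
                                                     slr_label, start_elev_m) {
    sustainability_duration(ssc_mg_L, om_mm_yr, slr_curves[[slr_label]],
                            start_elev_m, tide, ...)
  })
  grid
}

#' Plot a sustainability grid
#'
#' @param grid Output of [sustainability_grid()].
#' @return A ggplot tile panel of sustained duration by SSC and OM.
#' @export
plot_sustainability_grid <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = factor(.data$ssc_mg_L),
                               y = factor(.data$om_mm_yr),
                               fill = .data$duration_yr)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$duration_yr), size = 3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$slr_label),
      cols = ggplot2::vars(.data$start_elev_m),
      labeller = ggplot2::label_both
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "SSC (mg/L)", y = "OM (mm/yr)",
                  fill = "Sustained (yr)") +
    ggplot2::theme_minimal()
}
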
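test_that("still-water settling follows the exponential depletion closed form", {
  # constant depth h, ambient concentration C0, no replenishment, duration T:
  # settled mass per area = h * C0 * (1 - exp(-w_s T / h))
  p <- accretion_params(ssc = 200, om_rate = 0)
  h <- 0.8
  T_h <- 6
  ev <- tibble::tibble(time_h = seq(0, T_h, 0.1), depth_m = h)
  got <- deposition_per_cycle(ev, p)
  C0 <- p$ssc / 1000
  want <- h * C0 * (1 - exp(-p$settling_velocity * T_h * 3600 / h)) /
    p$dry_bulk_density
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("no sediment or no water means no deposition", {
  ev <- tibble::tibble(time_h = seq(0, 6, 0.1),
                       depth_m = pmax(sin(seq(0, 6, 0.1)), 0))
  expect_equal(deposition_per_cycle(ev, accretion_params(ssc = 0)), 0)
  dry <- tibble::tibble(time_h = seq(0, 6, 0.1), depth_m = 0)
  expect_equal(deposition_per_cycle(dry, accretion_params(ssc = 300)), 0)
  neg <- tibble::tibble(time_h = c(0, 0.1), depth_m = c(0.1, -0.1))
  expect_error(deposition_per_cycle(neg, accretion_params()), ">= 0")
})

test_that("per-cycle deposition matches fine-step explicit integration within 1%", {
  p <- accretion_params(ssc = 250, om_rate = 0)
  cases <- list(
    function(t) pmax(0.9 * sin(pi * t / 6), 0),          # symmetric flood
    function(t) pmax(0.5 * sin(pi * t / 8)^2 - 0.1, 0),  # shallow, flat-topped
    function(t) pmax(1.4 * sin(pi * t / 10) - 0.3, 0)    # deep, asymmetric span
  )
  for (shape in cases) {
    ev <- tibble::tibble(time_h = seq(0, 10, 0.1),
                         depth_m = shape(seq(0, 10, 0.1)))
    got <- deposition_per_cycle(ev, p)
    # the oracle integrates the same piecewise-linear depth profile finely
    depth_fun <- stats::approxfun(ev$time_h, ev$depth_m)
    want <- oracle_deposition(depth_fun, 10, p)
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("organic-only accretion is exact arithmetic", {
  tide <- test_tide()
  p <- accretion_params(ssc = 0, om_rate = 2)
  traj <- simulate_elevation(-0.5, p, zero_slr(), tide, horizon = 60,
                             checkpoint_step = 20)
  # 2 mm/yr for 50 years = +0.10 m, interpolated between monthly steps
  at50 <- stats::approx(traj$year, traj$elev_mhhw_m, xout = 50)$y
  expect_equal(at50 - (-0.5), 0.10, tolerance = 1e-4)
  expect_equal(traj$total_accretion_m[traj$year == 60], 0.12, tolerance = 1e-4)
})

test_that("without SLR a depositing marsh rises but never beyond the highest water", {
  tide <- test_tide()
  hw <- max(tide$level_m) - compute_datums(tide)$mhhw_m
  for (ssc in c(50, 300)) {
    traj <- simulate_elevation(-1.5, accretion_params(ssc = ssc, om_rate = 0),
                               zero_slr(), tide)
    expect_true(all(diff(traj$elev_mhhw_m) >= 0))
    expect_lte(max(traj$elev_mhhw_m), hw)
  }
})

test_that("the monthly-profile simulator agrees with direct per-cycle integration", {
  # 5-year mineral-only run, bed frozen month to month in both paths
  tide <- test_tide()
  p <- accretion_params(ssc = 200, om_rate = 0)
  traj <- simulate_elevation(-0.6, p, zero_slr(), tide, horizon = 5,
                             checkpoint_step = 5)
  d <- compute_datums(tide)
  month_yr <- 28 / 365.25
  bed <- -0.6 + d$mhhw_m
  for (k in seq_len(ceiling(5 / month_yr))) {
    cycles <- inundation_cycles(tide, bed)
    gain <- 0
    for (i in seq_len(nrow(cycles))) {
      sel <- tide$time_h >= cycles$start_h[i] & tide$time_h <= cycles$end_h[i]
      ev <- tibble::tibble(time_h = tide$time_h[sel],
                           depth_m = pmax(tide$level_m[sel] - bed, 0))
      gain <- gain + deposition_per_cycle(ev, p)
    }
    bed <- bed + gain
  }
  direct <- stats::approx(c(0, ceiling(5 / month_yr) * month_yr),
                          c(-0.6, bed - d$mhhw_m), xout = 5)$y
  # the two paths resolve wetting/drying crossings differently (the events
  # above are truncated at sample boundaries, the monthly profile resolves
  # the sub-sample crossing), so agreement is to a couple of percent
  expect_lt(abs(traj$elev_mhhw_m[2] - direct), 0.025 * abs(direct + 0.6))
})

test_that("century elevation responds monotonically to SSC, OM and SLR", {
  tide <- test_tide()
  final_elev <- function(ssc, om, slr, start = -0.5) {
    tr <- simulate_elevation(start, accretion_params(ssc = ssc, om_rate = om),
                             slr, tide)
    tr$elev_mhhw_m[tr$year == 100]
  }
  high <- slr_curve("high"); low <- slr_curve("low")
  by_ssc <- vapply(c(25, 100, 200, 300), final_elev, numeric(1),
                   om = 1, slr = high)
  expect_true(all(diff(by_ssc) > 0))
  by_om <- vapply(1:3, function(om) final_elev(150, om, high), numeric(1))
  expect_true(all(diff(by_om) > 0))
  expect_gt(final_elev(150, 1, low), final_elev(150, 1, high))
})

test_that("raising OM from 1 to 3 mm/yr shifts no century elevation by more than 20 cm", {
  tide <- test_tide()
  g <- run_grid(tide, om_rates = c(1, 3),
                start_elevations = c(-0.5, 0)) |>
    dplyr::filter(.data$year == 100) |>
    tidyr::pivot_wider(id_cols = c("start_elev_m", "ssc_mg_L", "slr_label"),
                       names_from = "om_mm_yr", values_from = "elev_mhhw_m")
  delta <- g$`3` - g$`1`
  expect_true(all(delta > 0))
  expect_true(all(delta <= 0.20 + 1e-9))
})

test_that("the run grid enumerates the factorial with the subtidal OM rule", {
  tide <- test_tide()
  g <- run_grid(tide)
  runs <- dplyr::distinct(g, .data$start_elev_m, .data$ssc_mg_L,
                          .data$om_mm_yr, .data$slr_label)
  expect_equal(nrow(runs), 98)   # 7 x 3 x 2 x 2 marsh starts + 7 x 2 subtidal
  expect_true(all(runs$om_mm_yr[runs$start_elev_m == -2.4] == 0))
  expect_error(run_grid(tide, ssc_levels = numeric(0)), "non-empty")

  single <- run_grid(tide, ssc_levels = 150, om_rates = 2,
                     slr_curves = list(slr_curve("high")),
                     start_elevations = 0)
  direct <- simulate_elevation(0, accretion_params(ssc = 150, om_rate = 2),
                               slr_curve("high"), tide)
  expect_equal(single$elev_mhhw_m, direct$elev_mhhw_m)
})

test_that("a wider tidal frame changes century elevations by at most 0.2 m", {
  tide <- test_tide()
  tide28 <- generate_tidal_month(target_range = 2.8)
  high <- slr_curve("high")
  for (ssc in c(150, 300)) {
    p <- accretion_params(ssc = ssc, om_rate = 1)
    a <- simulate_elevation(0, p, high, tide)
    b <- simulate_elevation(0, p, high, tide28)
    deficit <- a$elev_mhhw_m[6] - b$elev_mhhw_m[6]
    expect_lt(abs(deficit), 0.2)
    expect_lt(abs(deficit) / a$total_accretion_m[6], 0.06)
  }
})
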
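test_that("projections reproduce anchor runs exactly and interpolate linearly", {
  tide <- test_tide()
  tab <- response_table(200, 2, slr_curve("high"), tide)
  runs <- attr(tab, "anchor_runs")
  anchors <- attr(tab, "anchors")
  for (t in c(20, 60, 100)) {
    for (i in seq_along(anchors)) {
      want <- runs[[i]]$elev_mhhw_m[runs[[i]]$year == t]
      expect_equal(interpolate_projection(anchors[i], tab, t), want,
                   tolerance = 1e-12)
    }
    # random in-bracket points against the textbook two-point formula
    y0 <- runs[[2]]$elev_mhhw_m[runs[[2]]$year == t]
    y1 <- runs[[3]]$elev_mhhw_m[runs[[3]]$year == t]
    xs <- withr::with_seed(42, stats::runif(100, -0.5, 0))
    got <- interpolate_projection(xs, tab, t)
    want <- oracle_linear(xs, -0.5, y0, 0, y1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("out-of-domain elevations follow the boundary rules", {
  high <- slr_curve("high")
  expect_equal(apply_bounds(-5, 60, high), -5)
  expect_equal(apply_bounds(2.5, 100, high), 2.5 - 1.65)
  expect_equal(apply_bounds(2.5, 0, high), 2.5)
  expect_error(apply_bounds(0.3, 40, high), "inside")

  tide <- test_tide()
  tab <- response_table(150, 1, high, tide)
  # routed, not linearly extrapolated
  expect_equal(interpolate_projection(c(-4.5, 2.0), tab, 100),
               c(-4.5, 2.0 - 1.65))
})

test_that("the projection surface is monotone in start and continuous at the bounds", {
  tide <- test_tide()
  for (lbl in c("low", "high")) {
    slr <- slr_curve(lbl)
    tab <- response_table(100, 1, slr, tide)
    for (t in c(20, 100)) {
      sl <- dplyr::filter(tab, .data$t_yr == t)
      expect_true(all(diff(sl$x_future_m) >= -1e-12))
      # across the lower bound: -4.0 maps to itself, matching the rule below
      expect_lt(abs(interpolate_projection(-4, tab, t) - (-4)), 1e-9)
      # one grid cell above the upper bound vs the above-bound rule
      ub <- attr(tab, "upper_bound")
      gap <- abs(interpolate_projection(ub, tab, t) -
                   apply_bounds(ub + 0.1, t, slr))
      expect_lt(gap, 0.1 + 1e-9)
    }
  }
})

test_that("sustainability durations reproduce the trivial cases", {
  tide <- test_tide()
  expect_equal(sustainability_duration(0, 0, slr_curve("high"), 0, tide), 0)
  # generous sediment under no SLR is sustained the full century
  expect_equal(sustainability_duration(300, 3, zero_slr(), -0.5, tide), 100)
})

test_that("minimum start for mid marsh matches zero-accretion arithmetic", {
  tide <- test_tide()
  tab <- response_table(0, 0, slr_curve("high"), tide)
  # pure subsidence by 1.65 m: the continuous crossing sits at 1.45 m ...
  expect_equal(interpolate_projection(1.45, tab, 100), -0.2,
               tolerance = 1e-9)
  # ... so the first qualifying 10-cm grid start is 1.5 m
  res <- min_start_for_midmarsh(tab, 100)
  expect_equal(res$min_start_m, 1.5)
  expect_equal(res$start_class, "upland")
  expect_false(res$at_lower_limit)

  # with very high SSC under low SLR, starts below the lowest anchor qualify
  tab300 <- response_table(300, 0, slr_curve("low"), tide)
  res300 <- min_start_for_midmarsh(tab300, 100)
  expect_true(res300$achievable)
  expect_lte(res300$min_start_m, -2.4)
})

test_that("min start responds monotonically to horizon under low SLR, high SSC", {
  tide <- test_tide()
  tab <- response_table(250, 1, slr_curve("low"), tide)
  ms <- vapply(c(20, 60, 100),
               function(h) min_start_for_midmarsh(tab, h)$min_start_m,
               numeric(1))
  expect_true(all(diff(ms) <= 0))
})

test_that("sustainability grids respond monotonically to drivers", {
  tide <- test_tide()
  g <- sustainability_grid(tide, ssc_levels = c(50, 150, 300),
                           om_rates = c(1, 3), starts = 0)
  by_ssc <- g |>
    dplyr::arrange(.data$ssc_mg_L) |>
    dplyr::group_by(.data$om_mm_yr, .data$slr_label, .data$start_elev_m) |>
    dplyr::summarise(mono = all(diff(.data$duration_yr) >= 0),
                     .groups = "drop")
  expect_true(all(by_ssc$mono))
  wide <- tidyr::pivot_wider(g, names_from = "slr_label",
                             values_from = "duration_yr")
  expect_true(all(wide$low >= wide$high))
})
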
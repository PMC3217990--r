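#' Published-threshold calibration fixture
#'
#' Encodes, as machine-checkable entries, the sustainability and restoration
#' thresholds stated in the text of the study this model reproduces: which
#' SSC levels sustain mid/low marsh for how long under each sea-level-rise
#' curve, which subtidal restorations succeed, and the tide-range sensitivity
#' bounds. [calibrate_accretion()] searches settling velocity and dry bulk
#' density against these entries. Entries marked `mandatory` are the ones the
#' calibrated pair is required to satisfy simultaneously; the remainder are
#' scored but not required.
#'
#' Note: the low-SSC sustainability caps (25-50 mg/L) are jointly
#' irreconcilable with the high-SSC thresholds under this model class --
#' deposition is linear in SSC, so no parameter pair can both out-pace the
#' low SLR curve at 300 mg/L near MHHW and stall at 25 mg/L half a meter
#' lower. The calibration therefore reports per-entry agreement rather than
#' assuming feasibility; see the package vignette.
#'
#' @return A tibble of fixture entries with list-column `cases`.
#' @export
make_threshold_fixture <- function() {
  entry <- function(id, description, mandatory, type, cases, op, value,
                    agg = "max", year = 100, target = -0.2) {
    tibble::tibble(id = id, description = description, mandatory = mandatory,
                   type = type, cases = list(cases), op = op, value = value,
                   agg = agg, year = year, target = target)
  }
  g <- tidyr::expand_grid
  dplyr::bind_rows(
    entry("mid300_century_loss",
          "no tested SSC sustains a mid marsh start for the full century under high SLR",
          TRUE, "duration",
          g(ssc = 300, om = 1:3, slr = "high", start = 0), "lt", 100),
    entry("mid300_high_80yr",
          "mid marsh at 300 mg/L holds through year 80 under high SLR",
          TRUE, "duration",
          g(ssc = 300, om = 1:3, slr = "high", start = 0), "eq", 80),
    entry("subtidal250_high_restorable",
          "subtidal start reaches mid marsh elevation by year 100 at 250 mg/L, high SLR",
          TRUE, "elev_at",
          g(ssc = 250, om = 0, slr = "high", start = -2.4), "ge", -0.2,
          agg = "min"),
    entry("subtidal150_high_unrestorable",
          "subtidal start stays below mid marsh at year 100 at 150 mg/L, high SLR",
          TRUE, "elev_at",
          g(ssc = 150, om = 0, slr = "high", start = -2.4), "lt", -0.2),
    entry("subtidal300_low_20yr",
          "subtidal start reaches mid marsh by the first 20-yr checkpoint at 300 mg/L, low SLR",
          TRUE, "reach_by",
          g(ssc = 300, om = 0, slr = "low", start = -2.4), "le", 20,
          agg = "min"),
    entry("range_deficit_20cm",
          "raising the tide range 1.8 -> 2.8 m lowers no century elevation by more than 0.2 m",
          TRUE, "range_deficit",
          g(ssc = c(150, 200, 250, 300), om = 1, slr = c("low", "high"),
            start = c(-0.5, 0)), "le", 0.2),
    entry("ssc25_40yr_cap",
          "25 mg/L sustains neither marsh start beyond 40 years under either SLR curve",
          TRUE, "duration",
          g(ssc = 25, om = 1:3, slr = c("low", "high"), start = c(-0.5, 0)),
          "le", 40),
    entry("ssc50_high_fails",
          "50 mg/L is unsustainable from the first checkpoint under high SLR",
          FALSE, "duration",
          g(ssc = 50, om = 1:3, slr = "high", start = c(-0.5, 0)), "eq", 0),
    entry("ssc150_low_mid_century",
          "mid marsh persists the full century at 150 mg/L under low SLR",
          FALSE, "duration",
          g(ssc = 150, om = 1, slr = "low", start = 0), "eq", 100),
    entry("ssc100_low_lowmarsh_century",
          "low marsh persists the full century at 100 mg/L under low SLR",
          FALSE, "duration",
          g(ssc = 100, om = 1, slr = "low", start = -0.5), "eq", 100),
    entry("ssc50_om3_low_lowmarsh",
          "low marsh persists the full century at 50 mg/L with 3 mm/yr OM under low SLR",
          FALSE, "duration",
          g(ssc = 50, om = 3, slr = "low", start = -0.5), "eq", 100),
    entry("mid250_high_shorter",
          "mid marsh at 250 mg/L under high SLR holds for some period short of 300 mg/L's",
          FALSE, "duration",
          g(ssc = 250, om = 1:3, slr = "high", start = 0), "le", 80),
    entry("mid200_high_sustained",
          "mid marsh at 200 mg/L is sustained for at least one checkpoint under high SLR",
          FALSE, "duration",
          g(ssc = 200, om = 1:3, slr = "high", start = 0), "ge", 20),
    entry("range_pct_5",
          "tide-range elevation deficit stays within 5% of total predicted accretion",
          FALSE, "range_pct",
          g(ssc = c(150, 200, 250, 300), om = 1, slr = c("low", "high"),
            start = c(-0.5, 0)), "le", 5)
  )
}

# duration of sustained (no rounded elevation loss) checkpoints, consecutive
# from year 0
duration_from_trajectory <- function(traj, start) {
  ok <- round_10cm(traj$elev_mhhw_m) >= round_10cm(start)
  bad <- which(!ok)
  if (length(bad) == 0) return(max(traj$year))
  if (bad[1] == 1) return(0)
  traj$year[bad[1] - 1]
}

first_checkpoint_reaching <- function(traj, target) {
  hit <- which(traj$year > 0 & traj$elev_mhhw_m >= target)
  if (length(hit) == 0) return(Inf)
  traj$year[hit[1]]
}

compare_op <- function(observed, op, value, tol = 1e-9) {
  switch(op,
    eq = is.finite(observed) && abs(observed - value) <= tol,
    le = observed <= value + tol,
    ge = observed >= value - tol,
    lt = observed < value - tol,
    gt = observed > value + tol,
    stop("unknown comparison op: ", op, call. = FALSE)
  )
}

# Evaluate one fixture entry for a given (w_s, rho). `ctx` carries the tidal
# months and per-settling-velocity profile cache.
eval_fixture_entry <- function(e, ws, rho, ctx) {
  cases <- e$cases[[1]]
  run <- function(ssc, om, slr, start, tide, profile) {
    simulate_elevation(start,
                       accretion_params(ssc, om, ws, rho),
                       ctx$curves[[slr]], tide, profile = profile)
  }
  pr <- ctx$profile(ws, wide = FALSE)
  vals <- purrr::pmap_dbl(cases, function(ssc, om, slr, start) {
    traj <- run(ssc, om, slr, start, ctx$tide, pr)
    switch(e$type,
      duration = duration_from_trajectory(traj, start),
      elev_at = traj$elev_mhhw_m[traj$year == e$year],
      reach_by = first_checkpoint_reaching(traj, e$target),
      range_deficit = ,
      range_pct = {
        wide <- run(ssc, om, slr, start, ctx$tide_wide, ctx$profile(ws, wide = TRUE))
        deficit <- traj$elev_mhhw_m[nrow(traj)] - wide$elev_mhhw_m[nrow(wide)]
        if (e$type == "range_deficit") deficit
        else 100 * deficit / traj$total_accretion_m[nrow(traj)]
      }
    )
  })
  observed <- if (e$agg == "max") max(vals) else min(vals)
  tibble::tibble(id = e$id, description = e$description,
                 mandatory = e$mandatory,
                 observed = observed, op = e$op, value = e$value,
                 pass = compare_op(observed, e$op, e$value))
}

#' Calibrate settling velocity and dry bulk density
#'
#' Grid search over the two constants the Krone-type mass balance carries but
#' the source study does not print. Each candidate pair is scored against
#' [make_threshold_fixture()]: mandatory entries count 100, optional entries
#' 1, ties broken toward mid-range values (geometric midpoint for settling
#' velocity, arithmetic for density). The default density range extends to
#' 1200 kg/m^3 -- the upper end for consolidating mineral-rich estuarine
#' deposits -- so the search is not clipped at the feasible ridge for the
#' printed high-SSC thresholds, which runs from roughly (5e-5 m/s, 800
#' kg/m^3) toward higher settling velocities at higher densities.
#'
#' The low-SSC sustainability caps in the fixture cannot be met jointly with
#' the high-SSC thresholds (see [make_threshold_fixture()]); with
#' `strict = FALSE` (default) the best-scoring pair is returned with its
#' per-entry agreement table, with `strict = TRUE` an error reports the
#' best-achieved agreement when any mandatory entry fails.
#'
#' @param tide A `tide_series` month at the baseline range.
#' @param fixture Fixture tibble from [make_threshold_fixture()].
#' @param ws_range Settling velocity search range, m/s.
#' @param rho_range Dry bulk density search range, kg/m^3.
#' @param n_ws,n_rho Grid sizes (log-spaced / linear).
#' @param wide_range Tide range used by the range-sensitivity entries (m).
#' @param strict Error when mandatory entries cannot all be satisfied.
#' @return A `marsh_calibration` object; see [tidy.marsh_calibration()].
#' @export
calibrate_accretion <- function(tide = generate_tidal_month(),
                                fixture = make_threshold_fixture(),
                                ws_range = c(5e-5, 1e-3),
                                rho_range = c(200, 1200),
                                n_ws = 10, n_rho = 21,
                                wide_range = 2.8,
                                strict = FALSE) {
  stopifnot(length(ws_range) == 2, length(rho_range) == 2,
            all(ws_range > 0), all(rho_range > 0), nrow(fixture) > 0)
  ws_grid <- if (n_ws == 1) sqrt(prod(ws_range)) else
    10^seq(log10(ws_range[1]), log10(ws_range[2]), length.out = n_ws)
  rho_grid <- if (n_rho == 1) mean(rho_range) else
    seq(rho_range[1], rho_range[2], length.out = n_rho)

  base_range <- compute_datums(tide)$range_m
  tide_wide <- new_tide_series(tide$time_h,
                               tide$level_m * (wide_range / base_range),
                               attr(tide, "step_h"))
  ctx <- list(
    tide = tide, tide_wide = tide_wide,
    curves = list(low = slr_curve("low"), high = slr_curve("high")),
    profile = function(ws, wide) {
      deposition_profile(if (wide) tide_wide else tide, ws)
    }
  )
  needs_wide <- any(fixture$type %in% c("range_deficit", "range_pct"))

  pairs <- tidyr::expand_grid(ws = ws_grid, rho = rho_grid)
  scored <- purrr::pmap_dfr(pairs, function(ws, rho) {
    agree <- purrr::map_dfr(seq_len(nrow(fixture)), function(i) {
      eval_fixture_entry(fixture[i, ], ws, rho, ctx)
    })
    tibble::tibble(ws = ws, rho = rho,
                   score = sum(agree$pass * ifelse(agree$mandatory, 100, 1)),
                   n_mandatory_fail = sum(agree$mandatory & !agree$pass),
                   agreement = list(agree))
  })
  # tie-break toward mid-range
  mid_ws <- sqrt(prod(ws_range)); mid_rho <- mean(rho_range)
  scored$tiebreak <- abs(log(scored$ws / mid_ws)) / abs(log(ws_range[2] / mid_ws)) +
    abs(scored$rho - mid_rho) / (diff(rho_range) / 2 + 1e-12)
  scored <- dplyr::arrange(scored, dplyr::desc(.data$score), .data$tiebreak,
                           .data$ws, .data$rho)
  best <- scored[1, ]
  agreement <- best$agreement[[1]]
  complete <- best$n_mandatory_fail == 0

  if (strict && !complete) {
    failing <- agreement$id[agreement$mandatory & !agreement$pass]
    stop("no (settling velocity, bulk density) pair satisfies all mandatory ",
         "fixture entries; best pair w_s = ", signif(best$ws, 3),
         " m/s, rho = ", best$rho, " kg/m^3 fails: ",
         paste(failing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(settling_velocity = best$ws, dry_bulk_density = best$rho,
         score = best$score, complete = complete, agreement = agreement,
         ws_grid = ws_grid, rho_grid = rho_grid),
    class = "marsh_calibration"
  )
}

#' @export
print.marsh_calibration <- function(x, ...) {
  cat(sprintf(
    "<marsh_calibration> w_s = %.3g m/s, rho = %g kg/m^3 (%s; %d/%d entries pass)\n",
    x$settling_velocity, x$dry_bulk_density,
    if (x$complete) "all mandatory entries satisfied" else
      "some mandatory entries unattainable",
    sum(x$agreement$pass), nrow(x$agreement)))
  invisible(x)
}

#' Per-entry agreement of a calibration
#'
#' @param x A `marsh_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per fixture entry: observed value, comparison,
#'   and pass/fail.
#' @export
tidy.marsh_calibration <- function(x, ...) x$agreement

#' @export
glance.marsh_calibration <- function(x, ...) {
  tibble::tibble(
    settling_velocity = x$settling_velocity,
    dry_bulk_density = x$dry_bulk_density,
    score = x$score, complete = x$complete,
    n_pass = sum(x$agreement$pass), n_entries = nrow(x$agreement)
  )
}
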
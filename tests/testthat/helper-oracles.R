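# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths: brute-force scans, explicit fine-step
# integration, and textbook formulas.

# shared fixtures, built once per test run
test_tide <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_tidal_month()
    val
  }
})

test_bay <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_toy_bay(toy_bay_spec(n_rows = 40, n_cols = 40))
    val
  }
})

# tidal datums by brute-force window scan (integer count of ~lunar-day
# windows spanning the record, matching the documented datum definition)
oracle_datums <- function(time_h, level_m, window_h = 24.84) {
  span <- max(time_h) - min(time_h)
  n_win <- max(1, round(span / window_h))
  wl <- span / n_win
  hh <- ll <- numeric(n_win)
  for (w in seq_len(n_win)) {
    sel <- time_h - min(time_h) >= (w - 1) * wl &
      (time_h - min(time_h) < w * wl | w == n_win)
    hh[w] <- max(level_m[sel])
    ll[w] <- min(level_m[sel])
  }
  list(mhhw = mean(hh), mllw = mean(ll))
}

# explicit fine-step integration of the deposition/depletion equations for a
# depth profile given as a function of time (hours)
oracle_deposition <- function(depth_fun, t_end_h, params, dt_h = 0.002) {
  tt <- seq(0, t_end_h, by = dt_h)
  h <- depth_fun(tt)
  ws <- params$settling_velocity
  C_amb <- params$ssc / 1000
  dt_s <- dt_h * 3600
  C <- C_amb
  dep <- 0
  for (i in seq_len(length(tt) - 1)) {
    hm_raw <- (h[i] + h[i + 1]) / 2
    if (hm_raw <= 0) { C <- C_amb; next }
    hm <- max(hm_raw, 1e-3)
    rising <- h[i + 1] > h[i]
    if (rising) C <- C_amb
    flux <- ws * C * dt_s
    dep <- dep + flux
    if (!rising) C <- max(C - flux / hm, 0)
  }
  dep / params$dry_bulk_density
}

# textbook two-point linear interpolation
oracle_linear <- function(x, x0, y0, x1, y1) {
  y0 + (x - x0) / (x1 - x0) * (y1 - y0)
}

# IDW by double loop
oracle_idw <- function(px, py, pts, power = 2) {
  num <- den <- 0
  for (i in seq_len(nrow(pts))) {
    d2 <- (px - pts$x[i])^2 + (py - pts$y[i])^2
    if (d2 < 1e-18) return(pts$value[i])
    w <- d2^(-power / 2)
    num <- num + w * pts$value[i]
    den <- den + w
  }
  num / den
}

zero_slr <- function() slr_curve("none", century_total = 0, initial_rate = 0)
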
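grid_spec_20 <- function() marsh_grid(matrix(NA_real_, 20, 20), 0, 0, 10)

test_that("IDW surfaces reproduce the textbook cases", {
  spec <- grid_spec_20()
  one <- tibble::tibble(x = 55, y = 72, value = 3.3)
  s1 <- idw_surface(one, spec)
  expect_true(all(abs(s1$values - 3.3) < 1e-12))

  same <- tibble::tibble(x = c(10, 150, 80), y = c(20, 90, 170),
                         value = rep(1.8, 3))
  expect_true(all(abs(idw_surface(same, spec)$values - 1.8) < 1e-12))

  expect_error(idw_surface(same[0, ], spec), "non-empty")
})

test_that("IDW matches a brute-force double loop and honors exact hits", {
  spec <- grid_spec_20()
  pts <- withr::with_seed(7, tibble::tibble(
    x = stats::runif(10, 0, 200), y = stats::runif(10, 0, 200),
    value = stats::rnorm(10)
  ))
  surf <- idw_surface(pts, spec)
  ctr <- list(x = 0 + (1:20 - 0.5) * 10, y = 0 + (20 - 1:20 + 0.5) * 10)
  for (i in c(1, 7, 20)) for (j in c(2, 11, 19)) {
    expect_equal(surf$values[i, j], oracle_idw(ctr$x[j], ctr$y[i], pts),
                 tolerance = 1e-10)
  }
  # a gauge exactly on a cell center wins that cell
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(x = ctr$x[4], y = ctr$y[9],
                                               value = 99))
  expect_equal(idw_surface(pts2, spec)$values[9, 4], 99)
})

test_that("datum conversion is elementwise arithmetic with nodata propagation", {
  elev <- marsh_grid(matrix(c(2, 1, NA, 0.5), 2, 2), 0, 0, 5)
  mllw <- marsh_grid(matrix(0.1, 2, 2), 0, 0, 5)
  mhhw <- marsh_grid(matrix(1.9, 2, 2), 0, 0, 5)
  out <- navd_to_mhhw(elev, mllw, mhhw)
  expect_equal(out$values[1, 1], 2 + 0.1 - 1.9)
  expect_true(is.na(out$values[1, 2]))
  expect_equal(out$datum, "MHHW")

  zero <- marsh_grid(matrix(0, 2, 2), 0, 0, 5)
  expect_equal(navd_to_mhhw(elev, zero, zero)$values, elev$values)

  wrong <- marsh_grid(matrix(0, 3, 2), 0, 0, 5)
  expect_error(navd_to_mhhw(elev, wrong, mhhw), "co-registered")
})

test_that("vegetation corrections apply per class and skip unmapped or nodata", {
  elev <- marsh_grid(matrix(1, 2, 3), 0, 0, 5)
  veg <- marsh_grid(matrix(c(2, 2, 7, NA, 2, NA), 2, 3), 0, 0, 5)
  expect_warning(out <- vegetation_correction(elev, veg, c(`2` = -0.3)), "7")
  expect_equal(out$values[veg$values %in% 2], rep(0.7, 3))
  expect_equal(out$values[is.na(veg$values)], rep(1, 2))
  expect_equal(out$values[which(veg$values == 7)], 1)
  # zero correction is the identity
  out0 <- suppressWarnings(vegetation_correction(elev, veg, c(`2` = 0, `7` = 0)))
  expect_equal(out0$values, elev$values)
})

test_that("habitat bands classify the printed reference elevations", {
  expect_equal(as.character(classify_habitat(0)), "mid_marsh")
  expect_equal(as.character(classify_habitat(-1)), "mudflat")
  expect_equal(as.character(classify_habitat(0.5)), "upland")
  expect_equal(as.character(classify_habitat(-2)), "subtidal")
  expect_equal(as.character(classify_habitat(-0.4)), "low_marsh")
  expect_equal(as.character(classify_habitat(0.25)), "high_marsh")
})

test_that("classification after 10-cm rounding is total over the elevation axis", {
  xs <- withr::with_seed(11, stats::runif(2000, -6, 3))
  cls <- classify_habitat(xs)
  expect_false(any(is.na(cls)))
  # band edges land where the rounded grid puts them
  expect_equal(as.character(classify_habitat(c(0.1499, 0.15001))),
               c("mid_marsh", "high_marsh"))
})

test_that("polygon rasterization assigns by cell-center containment", {
  spec <- marsh_grid(matrix(NA_real_, 10, 10), 0, 0, 10)
  polys <- tibble::tibble(
    id = c(1, 2),
    geometry = list(
      cbind(x = c(0, 50, 50, 0), y = c(0, 0, 100, 100)),
      cbind(x = c(50, 100, 100, 50), y = c(0, 0, 100, 100))
    )
  )
  ras <- rasterize_polygons(polys, spec)
  expect_true(all(ras$values[, 1:5] == 1))
  expect_true(all(ras$values[, 6:10] == 2))
})

test_that("bilinear resampling recovers a linear field exactly", {
  # source: f(x, y) = 0.004 x + 0.002 y sampled on a 10 x 8 grid of 100-m cells
  src <- outer(1:10, 1:8, function(i, j) {
    0.004 * ((j - 0.5) * 100) + 0.002 * ((10 - i + 0.5) * 100)
  })
  coarse <- marsh_grid(src, 0, 0, 100)
  fine <- marsh_grid(matrix(NA_real_, 40, 32), 100, 100, 20)
  out <- resample_bilinear(coarse, fine)
  want <- outer(1:40, 1:32, function(i, j) {
    0.004 * (100 + (j - 0.5) * 20) + 0.002 * (100 + (40 - i + 0.5) * 20)
  })
  expect_equal(out$values, want, tolerance = 1e-12)
})

test_that("per-pixel projection equals the scalar composition", {
  tide <- test_tide()
  high <- slr_curve("high")
  tab150 <- response_table(150, 1, high, tide)
  tab300 <- response_table(300, 3, high, tide)
  tables <- list("150_1_high" = tab150, "300_3_high" = tab300)
  attrs <- tibble::tibble(id = 1:2, ssc_low = c(150, 300),
                          ssc_high = c(150, 300),
                          om_low = c(1, 3), om_high = c(1, 3))
  vals <- withr::with_seed(3, matrix(stats::runif(100, -4.6, 2.2), 10, 10))
  elev <- marsh_grid(vals, 0, 0, 5, datum = "MHHW")
  sub <- marsh_grid(matrix(rep(c(1, 2), each = 50), 10, 10), 0, 0, 5)
  scenario <- list(ssc_level = "low", om_level = "low", slr = high)
  out <- project_grid(elev, sub, attrs, scenario, 60, tables)
  for (i in c(1, 4, 10)) for (j in c(2, 6, 9)) {
    tab <- if (sub$values[i, j] == 1) tab150 else tab300
    expect_equal(out$values[i, j],
                 interpolate_projection(round_10cm(vals[i, j]), tab, 60),
                 tolerance = 1e-12)
  }
  # a constant raster stays constant (the model is pixel-local)
  const <- marsh_grid(matrix(-0.3, 10, 10), 0, 0, 5)
  sub1 <- marsh_grid(matrix(1, 10, 10), 0, 0, 5)
  outc <- project_grid(const, sub1, attrs[1, ], scenario, 60, tables)
  expect_equal(length(unique(as.vector(outc$values))), 1)
  # everything below the lower bound keeps pace with SLR
  deep <- marsh_grid(matrix(-4.7, 10, 10), 0, 0, 5)
  outd <- project_grid(deep, sub1, attrs[1, ], scenario, 100, tables)
  expect_equal(outd$values, deep$values)
  # a pixel in no subregion becomes nodata and is counted
  sub_na <- sub1; sub_na$values[1, 1] <- NA
  outn <- project_grid(const, sub_na, attrs[1, ], scenario, 60, tables)
  expect_true(is.na(outn$values[1, 1]))
  expect_equal(attr(outn, "n_outside_subregions"), 1)
  # missing table for an attribute combination names the subregion
  expect_error(project_grid(const, sub1, attrs[2, ], scenario, 60,
                            tables["150_1_high"]),
               "subregion 2")
})

test_that("area accounting conserves the domain and converts pixels to hectares", {
  # 400 mid-marsh pixels at 5 m resolution are exactly one hectare
  cls <- marsh_grid(matrix(4, 20, 20), 0, 0, 5)
  sub <- marsh_grid(matrix(1, 20, 20), 0, 0, 5)
  none <- marsh_grid(matrix(0, 20, 20), 0, 0, 5)
  a <- summarize_areas(cls, sub, none, none)
  expect_equal(nrow(a), 1)
  expect_equal(a$area_ha, 1)
  expect_equal(a$land_status, "tidal")

  bay <- test_bay()
  habitat <- classify_habitat(bay$truth_mhhw)
  subg <- rasterize_polygons(bay$subregions, habitat)
  areas <- summarize_areas(habitat, subg, bay$diked, bay$urban)
  px_ha <- bay$truth_mhhw$cellsize^2 / 1e4
  expect_equal(sum(areas$area_ha),
               sum(!is.na(habitat$values)) * px_ha)
  # per-status totals equal the mask areas (urban > diked precedence)
  urban_px <- sum(bay$urban$values > 0)
  diked_px <- sum(bay$diked$values > 0 & !(bay$urban$values > 0))
  by_status <- dplyr::count(areas, .data$land_status,
                            wt = .data$area_ha, name = "ha")
  expect_equal(by_status$ha[by_status$land_status == "urban"],
               urban_px * px_ha)
  expect_equal(by_status$ha[by_status$land_status == "diked"],
               diked_px * px_ha)
  # brute-force pixel count for one stratum
  want <- sum(habitat$values == 2 & subg$values %in% 1 &
                !(bay$diked$values > 0) & !(bay$urban$values > 0),
              na.rm = TRUE) * px_ha
  got <- areas$area_ha[areas$subregion == 1 & areas$land_status == "tidal" &
                         areas$habitat == "mudflat"]
  expect_equal(got, want)
})
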
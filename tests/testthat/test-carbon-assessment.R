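test_that("carbon_map scales class densities by cell area in hectares", {
  pools <- default_pool_table()
  scheme <- lulc_scheme()
  # one forest cell of exactly 1 ha (100 m cells)
  r <- make_raster(3L, 1, scheme, cell_size_m = 100)
  cm <- carbon_map(r, pools)
  expect_equal(cm$values[1, 1], 202)

  # halving the cell edge quarters the cell area, hence the cell value
  r50 <- make_raster(3L, 1, scheme, cell_size_m = 50)
  expect_equal(carbon_map(r50, pools)$values[1, 1], 202 / 4)

  # nodata cells carry NA and are excluded from totals
  r2 <- make_raster(c(3L, -9999L, 1L, 2L), 2, scheme, cell_size_m = 100)
  cm2 <- carbon_map(r2, pools)
  expect_true(is.na(cm2$values[1, 2]))
  expect_equal(total_storage(cm2), 202 + 8 + 60)

  incomplete <- pools[pools$class_code != 3, ]
  expect_error(carbon_map(r, incomplete), "misses classes: 3")
})

test_that("cell-sum and area-table storage routes agree to 1e-9 relative", {
  pools <- default_pool_table()
  for (s in 1:6) {
    r <- random_raster(12, 17, 7, seed = s)
    r$scheme <- lulc_scheme()
    r$grid[seq_len(s * 3)] <- r$nodata
    a <- total_storage(carbon_map(r, pools))
    b <- storage_from_areas(area_table(r), pools)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("uniform rasters give the obvious totals", {
  pools <- default_pool_table()
  r <- make_raster(rep(3L, 10), 2, lulc_scheme(), cell_size_m = 100)
  expect_equal(total_storage(carbon_map(r, pools)), 2020)
  zero <- carbon_map(r, pools)
  zero$values[] <- NA_real_
  expect_equal(total_storage(zero), 0)
})

test_that("published areas and pools reproduce the published storage", {
  pools <- default_pool_table()
  ref <- reference_ledger()
  ats <- calabria_area_tables(ref$year)
  stored <- vapply(ats, storage_from_areas, numeric(1), pools = pools)
  expect_equal(unname(stored), ref$stored_Mg, tolerance = 1e-4)
})

test_that("sequestration is the signed storage difference", {
  expect_equal(sequestration(5, 5), 0)
  expect_equal(sequestration(2, 7), -sequestration(7, 2))
  ref <- reference_ledger()
  s <- sequestration(ref$stored_Mg[3], ref$stored_Mg[4])  # 2012 -> 2018
  expect_equal(s, 206432.00, tolerance = 1e-5)
})

test_that("CO2 equivalence is exactly 44/12", {
  expect_equal(co2_equivalent(12), 44)
  expect_equal(co2_equivalent(0), 0)
  expect_equal(co2_equivalent(206432.00), 756917.33, tolerance = 1e-7)
  # published CO2 entry deviates only by upstream rounding
  expect_equal(co2_equivalent(206432.00), 756919.47, tolerance = 1e-4)
})

test_that("valuation matches the geometric-series oracle", {
  # oracle: explicit sum of the discount series
  oracle <- function(V, s, p, q, r, c) {
    g <- (1 + r / 100) * (1 + c / 100)
    V * s / (q - p) * sum(vapply(0:(q - p - 1), function(t) g^-t, 1))
  }
  vp <- valuation_params(V = 200, r = 3, c = 0, p = 2018, q = 2024)
  expect_equal(valuation(vp, 1), oracle(200, 1, 2018, 2024, 3, 0))
  expect_equal(valuation(vp, 1), 200 / 6 * 5.579708, tolerance = 1e-6)
  expect_equal(round(valuation(vp, 1), 2), 185.99)

  # undiscounted limit and the single-year case
  vp0 <- valuation_params(V = 200, r = 0, c = 0, p = 0, q = 6)
  expect_equal(valuation(vp0, 3), 200 * 3)
  vp1 <- valuation_params(V = 200, r = 7, c = 2, p = 0, q = 1)
  expect_equal(valuation(vp1, 5), 200 * 5)

  # monotone decreasing in the discount rate for s > 0
  vals <- vapply(c(0, 1, 3, 10), function(rr)
    valuation(valuation_params(V = 200, r = rr, c = 0, p = 0, q = 6), 1),
    numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(valuation_params(V = 200, p = 2024, q = 2024), "exceed")
})

test_that("stored_value converts to million EUR at the carbon price", {
  expect_equal(round(stored_value(167359466.90, 200), 2), 33471.89)
  expect_equal(round(stored_value(164202650.36, 200), 2), 32840.53)
  expect_equal(stored_value(0), 0)
})

test_that("the ledger telescopes and its columns are mutually consistent", {
  pools <- default_pool_table()
  ats <- calabria_area_tables()
  led <- build_ledger(ats, pools)
  expect_equal(nrow(led), 5L)
  expect_equal(sum(led$variation_MgC[-1]),
               led$stored_Mg[5] - led$stored_Mg[1], tolerance = 1e-9)
  expect_equal(led$co2_eq_Mg[-1], led$variation_MgC[-1] * 44 / 12)
  expect_equal(led$stored_value_MEUR, led$stored_Mg * 200 / 1e6)
  # discounting shrinks the magnitude of each period value
  expect_true(all(abs(led$variation_value_MEUR[-1]) <=
                    abs(led$variation_value_undiscounted_MEUR[-1]) + 1e-12))

  # a repeated area table yields zero variation
  led0 <- build_ledger(list(ats[[1]], {
    a <- ats[[1]]; attr(a, "year") <- 2006; a
  }), pools)
  expect_equal(led0$variation_MgC[2], 0)

  expect_error(build_ledger(ats[c(2, 1)], pools), "increasing")
})
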
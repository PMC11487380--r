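test_that("confusion_matrix puts identical maps on the diagonal", {
  r <- random_raster(6, 6, 3, seed = 2)
  cm <- confusion_matrix(r, r)
  expect_equal(sum(unclass(cm)) - sum(diag(unclass(cm))), 0L)
  expect_equal(sum(unclass(cm)), 36L)

  r2 <- r
  r2$grid[1, 1] <- if (r$grid[1, 1] == 1L) 2L else 1L
  cm2 <- confusion_matrix(r2, r)
  expect_equal(sum(unclass(cm2)) - sum(diag(unclass(cm2))), 1L)
})

test_that("components follow the closed forms on constructed maps", {
  # perfect agreement with uniform marginals over 8 classes:
  # chance = 1/8, all remaining agreement at grid-cell level
  scheme8 <- class_scheme(1:8)
  r8 <- make_raster(rep(1:8, each = 2), 4, scheme8)
  ac <- agreement_components(confusion_matrix(r8, r8), J_chance = 8)
  expect_equal(ac[["chance"]], 0.125)
  expect_equal(ac[["quantity"]], 0)
  expect_equal(ac[["gridcell"]], 0.875)
  expect_equal(ac[["dis_gridcell"]], 0)
  expect_equal(ac[["dis_quantity"]], 0)

  # shared marginals but maximally misallocated two-class maps:
  # no agreement, all disagreement at grid-cell level
  scheme <- two_class_scheme()
  sim <- make_raster(c(1L, 1L, 2L, 2L), 2, scheme)
  ref <- make_raster(c(2L, 2L, 1L, 1L), 2, scheme)
  ac2 <- agreement_components(confusion_matrix(sim, ref), J_chance = 2)
  expect_equal(ac2[["chance"]], 0)
  expect_equal(ac2[["gridcell"]], 0)
  expect_equal(ac2[["dis_gridcell"]], 1)
  expect_equal(ac2[["dis_quantity"]], 0)
})

test_that("components are non-negative and sum to 1 on random rasters", {
  for (s in 1:12) {
    nr <- sample(3:20, 1)
    nc <- sample(3:20, 1)
    sim <- random_raster(nr, nc, 4, seed = s)
    ref <- random_raster(nr, nc, 4, seed = s + 500)
    ac <- agreement_components(confusion_matrix(sim, ref), J_chance = 5)
    expect_true(all(ac >= 0))
    expect_equal(sum(ac), 1, tolerance = 1e-9)
  }
})

test_that("kappas equal a brute-force confusion-matrix oracle", {
  set.seed(31)
  for (s in 1:10) {
    nr <- sample(5:20, 1)
    nc <- sample(5:20, 1)
    sim <- random_raster(nr, nc, 4, seed = s + 40)
    # correlated reference: copy sim, perturb some cells
    ref <- sim
    flip <- sample(nr * nc, round(0.3 * nr * nc))
    ref$grid[flip] <- sample(4L, length(flip), replace = TRUE)
    cm <- confusion_matrix(sim, ref)
    ks <- kappa_set(agreement_components(cm, J_chance = 5))
    oracle <- kappa_oracle(unclass(cm), J_chance = 5)
    expect_equal(ks$Kstd, oracle$Kstd, tolerance = 1e-12)
    expect_equal(ks$Kno, oracle$Kno, tolerance = 1e-12)
    expect_equal(ks$Kloc, oracle$Kloc, tolerance = 1e-12)
  }
})

test_that("identical maps give kappa 1; Kloc >= Kstd when quantity differs", {
  r <- random_raster(10, 10, 3, seed = 77)
  ks <- kappa_set(agreement_components(confusion_matrix(r, r), J_chance = 4))
  expect_equal(ks$Kno, 1)
  expect_equal(ks$Kstd, 1)
  expect_equal(ks$Kloc, 1)
  expect_equal(ks$Klocstrata, ks$Kloc)

  for (s in 1:6) {
    sim <- random_raster(8, 8, 3, seed = s + 10)
    # correlated reference so observed agreement exceeds expectation
    # (with agreement below chance both kappas are negative and the
    # ordering reverses)
    ref <- sim
    set.seed(s + 700)
    flip <- sample(64, 20)
    ref$grid[flip] <- sample(3L, 20, replace = TRUE)
    ac <- agreement_components(confusion_matrix(sim, ref), J_chance = 4)
    ks <- kappa_set(ac)
    ex <- attr(ac, "exact")
    if (ex[["Pm"]] < 1 && ex[["M"]] > ex[["Nm"]]) {
      expect_gte(ks$Kloc, ks$Kstd)
    }
  }
})

test_that("degenerate denominators give NA rather than a number", {
  # one-class maps: N(m) = 1 and P(m) = N(m)
  scheme <- two_class_scheme()
  r <- make_raster(rep(1L, 9), 3, scheme)
  ac <- agreement_components(confusion_matrix(r, r), J_chance = 2)
  ks <- kappa_set(ac)
  expect_true(is.na(ks$Kstd))
  expect_true(is.na(ks$Kloc))
  expect_false(is.na(ks$Kno))
})

test_that("bundled case-study components reproduce the published kappas", {
  ks12 <- kappa_set(calabria_agreement_components(2012))
  expect_equal(ks12$Kstd, 0.9656, tolerance = 1e-3)
  expect_equal(ks12$Kno, 0.9773, tolerance = 1e-3)
  expect_equal(ks12$Kloc, 0.9755, tolerance = 1e-3)
  expect_equal(ks12$Klocstrata, ks12$Kloc)

  ks18 <- kappa_set(calabria_agreement_components(2018))
  expect_equal(ks18$Kstd, 0.9814, tolerance = 1e-3)
  expect_equal(ks18$Kno, 0.9877, tolerance = 1e-3)
  expect_equal(ks18$Kloc, 0.9854, tolerance = 1e-3)

  # the 2012 components sum to 1 exactly as printed
  ac12 <- calabria_agreement_components(2012)
  expect_equal(sum(ac12), 1, tolerance = 1e-9)
})

test_that("validation reports round-trip the component labels", {
  ac <- calabria_agreement_components(2012)
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(ac, path)
  rep <- read.csv(path, stringsAsFactors = FALSE)
  expect_true("Agreement due to chance" %in% rep$statistic)
  expect_true(all(c("Kstd", "Kno", "Kloc", "Klocstrata") %in% rep$statistic))
  expect_equal(nrow(rep), 11L)
})
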
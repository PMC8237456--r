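test_that("scalar EQD2 reproduces the stereotactic worked example", {
  expect_equal(eqd2_scalar(50, 4, 3), 155)
  expect_equal(eqd2_scalar(50, 4, 3) / 50, 3.1)
  expect_equal(eqd2_scalar(0, 4, 3), 0)
  # 2 Gy fractions are their own EQD2, for any alpha/beta
  for (ab in c(2, 3, 10))
    for (n in c(1, 15, 30))
      expect_equal(eqd2_scalar(2 * n, n, ab), 2 * n, tolerance = 1e-12)
  expect_error(eqd2_scalar(50, 4, 0), "alpha/beta")
  expect_error(eqd2_scalar(-1, 4, 3), ">= 0")
})

test_that("EQD2 is strictly increasing in total and fraction dose", {
  D <- seq(0.5, 80, by = 0.5)
  for (ab in c(2, 3, 10)) {
    e <- eqd2_scalar(D, 4, ab)
    expect_true(all(diff(e) > 0))
    # fixed total dose, fewer fractions (larger d) -> larger EQD2
    expect_gt(eqd2_scalar(50, 4, ab), eqd2_scalar(50, 10, ab))
  }
})

test_that("EQD2 inversion is the exact round trip of the scalar formula", {
  expect_equal(invert_eqd2(155, 4, 3), 12.5, tolerance = 1e-12)
  expect_equal(invert_eqd2(0, 4, 3), 0)
  for (ab in c(2, 3, 10)) {
    d <- seq(0.25, 30, by = 0.25)
    E <- eqd2_scalar(d * 4, 4, ab)
    d_back <- invert_eqd2(E, 4, ab)
    expect_lt(max(abs(d_back - d) / d), 1e-9)
    expect_equal(invert_eqd2(2 * 12, 12, ab), 2, tolerance = 1e-12)
  }
  expect_error(invert_eqd2(-1, 4, 3), ">= 0")
})

test_that("boost prescription adjustment matches its grid-search oracle", {
  nominal <- fractionation_scheme(4, 12.5, "SBRT")
  cfrt <- fractionation_scheme(30, 2, "CFRT")
  # nothing to subtract -> the nominal scheme
  adj0 <- adjust_boost_prescription(nominal, 0, cfrt, 10)
  expect_equal(adj0$fraction_dose, 12.5)
  expect_equal(adj0$n_fractions, 4L)
  # 60 Gy at 2 Gy/f is its own EQD2: the delivered boost EQD2 is E_rx - 60
  for (ab in c(3, 10)) {
    adj <- adjust_boost_prescription(nominal, 60, cfrt, ab)
    E_rx <- eqd2_scalar(50, 4, ab)
    expect_equal(eqd2_scalar(adj$total_dose, 4, ab), E_rx - 60,
                 tolerance = 1e-9)
  }
  # two-stage fine grid search as an independent oracle (1 uGy resolution)
  adj <- adjust_boost_prescription(nominal, 12, cfrt, 10)
  E_target <- eqd2_scalar(50, 4, 10) - eqd2_scalar(12, 30, 10)
  coarse <- seq(0, 15, by = 1e-4)
  d0 <- coarse[which.min(abs(eqd2_scalar(coarse * 4, 4, 10) - E_target))]
  fine <- seq(d0 - 1e-4, d0 + 1e-4, by = 1e-6)
  d_star <- fine[which.min(abs(eqd2_scalar(fine * 4, 4, 10) - E_target))]
  expect_equal(adj$fraction_dose, d_star, tolerance = 1e-6)
  # proportional mode scales the nominal fraction dose by the EQD2 ratio
  prop <- adjust_boost_prescription(nominal, 12, cfrt, 10, mode = "proportional")
  E_rx <- eqd2_scalar(50, 4, 10)
  expect_equal(prop$fraction_dose, 12.5 * E_target / E_rx, tolerance = 1e-12)
  # fully pre-covered prescription -> zero-dose scheme with a warning
  expect_warning(z <- adjust_boost_prescription(nominal, 200, cfrt, 10),
                 "zero-dose")
  expect_equal(z$fraction_dose, 0)
})

test_that("voxel-wise EQD2 resolves alpha/beta by structure priority", {
  dims <- c(8, 6, 6); sp <- c(4, 4, 4)
  lung_m <- array(FALSE, dims); lung_m[, , ] <- TRUE
  pt_m <- array(FALSE, dims); pt_m[3:4, 3:4, 3:4] <- TRUE
  st <- structure_set(list(
    PTV_PT = structure_mask("PTV_PT", pt_m, sp),
    lung_total = structure_mask("lung_total", lung_m, sp)))
  abm <- alpha_beta_map()
  dose <- volume_grid(array(50, dims), sp)
  e <- eqd2_grid(dose, 4, abm, st)
  # lung voxel: the worked example; target voxel: alpha/beta 10 wins
  expect_equal(e$values[1, 1, 1], 155)
  expect_equal(e$values[3, 3, 3], eqd2_scalar(50, 4, 10))
  # 2 Gy per fraction everywhere: conversion is the identity
  d2 <- volume_grid(array(60, dims), sp)
  expect_equal(eqd2_grid(d2, 30, abm, st)$values, d2$values,
               tolerance = 1e-12)
  # spot-check random voxels against the scalar operation
  set.seed(5)
  dr <- volume_grid(array(runif(prod(dims), 0, 70), dims), sp)
  er <- eqd2_grid(dr, 4, abm, st)
  for (k in 1:20) {
    idx <- cbind(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    ab <- if (pt_m[idx]) 10 else 3
    expect_equal(er$values[idx], eqd2_scalar(dr$values[idx], 4, ab),
                 tolerance = 1e-12)
  }
  # voxels outside all structures with no default are an error
  abm_nodefault <- alpha_beta_map(default = NA)
  st_partial <- structure_set(list(PTV_PT = structure_mask("PTV_PT", pt_m, sp)))
  expect_error(eqd2_grid(dose, 4, abm_nodefault, st_partial), "default")
})

test_that("hybrid summation is linear and EQD2-inflates only large fractions", {
  dims <- c(8, 6, 6); sp <- c(4, 4, 4)
  lung_m <- array(TRUE, dims)
  st <- structure_set(list(lung_total = structure_mask("lung_total", lung_m, sp)))
  abm <- alpha_beta_map()
  boost_scheme <- fractionation_scheme(4, 12.5, "SBRT")
  cfrt <- volume_grid(array(10, dims), sp)
  zero <- volume_grid(array(0, dims), sp)
  expect_equal(sum_hybrid(cfrt, zero, boost_scheme, domain = "physical")$values,
               cfrt$values)
  expect_equal(sum_hybrid(cfrt, zero, boost_scheme, abm, st, "EQD2")$values,
               cfrt$values)
  # lung voxel receiving 10 Gy CFRT + 50 Gy boost in 4 fractions
  boost <- volume_grid(array(50, dims), sp)
  e <- sum_hybrid(cfrt, boost, boost_scheme, abm, st, "EQD2")
  expect_equal(e$values[1, 1, 1], 165)
  p <- sum_hybrid(cfrt, boost, boost_scheme, domain = "physical")
  expect_true(all(e$values >= p$values))
  # linearity in the CFRT component within a domain
  cfrt2 <- volume_grid(array(25, dims), sp)
  e2 <- sum_hybrid(cfrt2, boost, boost_scheme, abm, st, "EQD2")
  expect_equal(e2$values - e$values, cfrt2$values - cfrt$values,
               tolerance = 1e-12)
  mismatched <- volume_grid(array(1, dims + 1), sp)
  expect_error(sum_hybrid(cfrt, mismatched, boost_scheme, domain = "physical"),
               "lattice")
})
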
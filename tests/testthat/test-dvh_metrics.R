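uniform_case <- function(value, dims = c(6, 6, 6), sp = c(2, 2, 2)) {
  list(dose = volume_grid(array(value, dims), sp),
       mask = structure_mask("s", array(TRUE, dims), sp))
}

test_that("DVH and Vx/Dx agree with direct voxel counting", {
  u <- uniform_case(10)
  curve <- dvh(u$dose, u$mask)
  expect_equal(curve$volume_pct[curve$dose <= 10], rep(100, sum(curve$dose <= 10)))
  expect_equal(curve$volume_pct[length(curve$volume_pct)], 0)
  expect_true(all(diff(curve$volume_pct) <= 0))

  # half the mask at 10 Gy, half at 20 Gy
  dims <- c(6, 6, 6)
  vals <- array(10, dims); vals[1:3, , ] <- 20
  half <- volume_grid(vals, c(2, 2, 2))
  mask <- structure_mask("s", array(TRUE, dims), c(2, 2, 2))
  expect_equal(v_at_dose(half, mask, 15), 50)

  # random grid: V_x equals the voxel count at every probe level
  set.seed(3)
  rnd <- volume_grid(array(runif(prod(dims), 0, 60), dims), c(2, 2, 2))
  v <- rnd$values[mask$mask]
  for (x in c(5, 20, 33.3, 59))
    expect_equal(v_at_dose(rnd, mask, x), mean(v >= x) * 100)
  expect_equal(v_at_dose(uniform_case(21)$dose, mask, 20), 100)
  expect_equal(v_at_dose(uniform_case(19)$dose, mask, 20), 0)
})

test_that("Dx follows the sorted-voxel inverse CDF", {
  u <- uniform_case(10)
  expect_equal(d_at_volume(u$dose, u$mask, 5), 10)
  expect_equal(d_at_volume(u$dose, u$mask, 95), 10)
  dims <- c(10, 10, 10)
  ramp <- volume_grid(array(seq(0, 100, length.out = 1000), dims), c(2, 2, 2))
  mask <- structure_mask("s", array(TRUE, dims), c(2, 2, 2))
  sorted <- sort(ramp$values[mask$mask], decreasing = TRUE)
  for (p in c(5, 30, 50, 95, 100))
    expect_equal(d_at_volume(ramp, mask, p), sorted[ceiling(p / 100 * 1000)])
  expect_equal(d_at_volume(ramp, mask, 50), 50, tolerance = 0.2)
  expect_gte(d_at_volume(ramp, mask, 5), d_at_volume(ramp, mask, 95))
  expect_error(d_at_volume(ramp, mask, 0), "0, 100")
})

test_that("conformity and homogeneity indices match their formulas", {
  dims <- c(10, 10, 10); sp <- c(2, 2, 2)
  tgt <- array(FALSE, dims); tgt[3:6, 3:6, 3:6] <- TRUE
  target <- structure_mask("t", tgt, sp)
  # dose >= L exactly on the target
  d1 <- volume_grid(array(0, dims), sp); d1$values[tgt] <- 60
  expect_equal(conformity_index(d1, target, 60), 1)
  # dose covers the target plus an equal external volume -> 0.5
  ext <- array(FALSE, dims); ext[3:6, 3:6, 7:10] <- TRUE
  d2 <- volume_grid(array(0, dims), sp); d2$values[tgt | ext] <- 60
  expect_equal(conformity_index(d2, target, 60), 0.5)
  # dose covers half the target only -> 0.5
  halft <- array(FALSE, dims); halft[3:4, 3:6, 3:6] <- TRUE
  d3 <- volume_grid(array(0, dims), sp); d3$values[halft] <- 60
  expect_equal(conformity_index(d3, target, 60), 0.5)
  expect_warning(ci0 <- conformity_index(volume_grid(array(0, dims), sp),
                                         target, 60), "CI set to 0")
  expect_equal(ci0, 0)

  u <- volume_grid(array(30, dims), sp)
  full <- structure_mask("s", array(TRUE, dims), sp)
  expect_equal(homogeneity_index(u, full), 1)
  ramp <- volume_grid(array(seq(50, 100, length.out = 1000), dims), sp)
  sorted <- sort(ramp$values[full$mask], decreasing = TRUE)
  expect_equal(homogeneity_index(ramp, full),
               sorted[ceiling(0.05 * 1000)] / sorted[ceiling(0.95 * 1000)])
  expect_gte(homogeneity_index(ramp, full), 1)
})

test_that("plan parameters reduce correctly in degenerate plans", {
  # CFRT delivers exactly 60 Gy on the nodal target, boost contributes 0
  st <- small_phantom_case()$structures
  ln <- st$structures$PTV_LN
  dims <- dim(ln$mask)
  cfrt_vals <- array(0, dims); cfrt_vals[ln$mask] <- 60
  cfrt <- volume_grid(cfrt_vals, ln$spacing)
  zero <- volume_grid(array(0, dims), ln$spacing)
  hyb <- suppressWarnings(hybrid_plan_dose(
    cfrt, zero, fractionation_scheme(30, 2, "CFRT"),
    fractionation_scheme(4, 12.5, "SBRT"), alpha_beta_map(), st))
  pp <- suppressWarnings(plan_parameters(hyb, st, "physical"))
  expect_equal(pp$ptv_ln_ci60, 1)

  # a plan delivered at 2 Gy/fraction everywhere: physical and EQD2
  # parameter vectors coincide
  cfrt_u <- volume_grid(array(40, dims), ln$spacing)
  boost_u <- volume_grid(array(8, dims), ln$spacing)  # 2 Gy x 4
  hyb2 <- hybrid_plan_dose(cfrt_u, boost_u, fractionation_scheme(20, 2, "CFRT"),
                           fractionation_scheme(4, 2, "SIB_boost"),
                           alpha_beta_map(), st)
  pp_p <- suppressWarnings(plan_parameters(hyb2, st, "physical"))
  pp_e <- suppressWarnings(plan_parameters(hyb2, st, "EQD2"))
  shared <- setdiff(names(pp_p), c("domain", "ptv_pt_ci140"))
  expect_equal(unlist(pp_p[shared]), unlist(pp_e[shared]), tolerance = 1e-12)
})

test_that("phantom plan parameters match sorted-voxel recomputation", {
  case <- small_phantom_case()
  st <- case$structures
  pp <- suppressWarnings(plan_parameters(case$hybrid, st, "EQD2"))
  dose <- case$hybrid$summed_eqd2
  for (nm in c("heart", "esophagus", "lung_total")) {
    v <- dose$values[st$structures[[nm]]$mask]
    sorted <- sort(v, decreasing = TRUE)
    oracle <- list(
      d5 = sorted[ceiling(0.05 * length(v))],
      mean = mean(v), max = max(v),
      v20 = mean(v >= 20) * 100, v50 = mean(v >= 50) * 100)
    if (nm == "heart") {
      expect_equal(pp$heart_d5, oracle$d5)
      expect_equal(pp$heart_mean, oracle$mean)
      expect_equal(pp$heart_dmax, oracle$max)
    } else if (nm == "esophagus") {
      expect_equal(pp$eso_dmax, oracle$max)
      expect_equal(pp$eso_v50, oracle$v50)
    } else {
      expect_equal(pp$lung_total_v20, oracle$v20)
      expect_equal(pp$lung_total_mld, oracle$mean)
    }
    expect_lte(oracle$mean, oracle$max)
  }
  # CI formula recomputed from raw voxel sets
  ln <- st$structures$PTV_LN
  vv <- voxel_volume_cc(dose)
  tv <- sum(ln$mask) * vv
  v_ri <- sum(dose$values >= 60) * vv
  v_rx <- sum(ln$mask & dose$values >= 60) * vv
  expect_equal(pp$ptv_ln_ci60, v_rx^2 / (tv * v_ri))
  expect_gt(pp$ptv_ln_ci60, 0)
  expect_lte(pp$ptv_ln_ci60, 1)
})
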
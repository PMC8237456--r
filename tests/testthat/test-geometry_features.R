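test_that("structure volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  s <- structure_mask("s", m, c(1, 1, 1))
  expect_equal(structure_volume(s), 1.0)
  expect_equal(structure_volume(s), structure_volume(s))
  sph <- sphere_mask(20, 1)
  expect_equal(structure_volume(sph), 4 / 3 * pi * 20^3 / 1000,
               tolerance = 0.05)
})

test_that("minimum surface distance matches forced and analytic cases", {
  a <- array(FALSE, c(15, 3, 3)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(15, 3, 3)); b[12, 2, 2] <- TRUE
  A <- structure_mask("A", a, c(4, 4, 4))
  B <- structure_mask("B", b, c(4, 4, 4))
  expect_equal(min_surface_distance(A, B), 4.0)
  expect_equal(min_surface_distance(A, A), 0)
  # spheres with radii 10 + 20 mm, centres 70 mm apart -> 4 cm gap
  sp <- 2
  n <- 60
  grid_pts <- (seq_len(n) - 1) * sp
  mk <- function(ctr, r) {
    g <- expand.grid(z = grid_pts, y = grid_pts, x = grid_pts)
    structure_mask("s", array((g$z - ctr[1])^2 + (g$y - ctr[2])^2 +
                                (g$x - ctr[3])^2 <= r^2, c(n, n, n)),
                   rep(sp, 3))
  }
  s1 <- mk(c(24, 60, 60), 10)
  s2 <- mk(c(94, 60, 60), 20)
  expect_equal(min_surface_distance(s1, s2), 4.0,
               tolerance = sqrt(3) * sp / 40)
})

test_that("minimum surface distance equals brute force and is symmetric", {
  for (seed in 1:4) {
    A <- random_blob(c(14, 12, 10), c(2, 2.5, 3), 5, seed, "A")
    B <- random_blob(c(14, 12, 10), c(2, 2.5, 3), 5, seed + 100, "B")
    expect_equal(min_surface_distance(A, B), brute_min_dist(A, B) / 10,
                 tolerance = 1e-9)
    expect_equal(min_surface_distance(A, B), min_surface_distance(B, A))
    intersects <- any(A$mask & B$mask)
    expect_identical(min_surface_distance(A, B) == 0, intersects)
  }
  A <- random_blob(c(8, 8, 8), c(1, 1, 1), 4, 1)
  B <- random_blob(c(9, 8, 8), c(1, 1, 1), 4, 2)
  expect_error(min_surface_distance(A, B), "lattice")
})

test_that("signed cranio-caudal overlap thickness follows slab extents", {
  sp <- c(5, 5, 5)
  mk <- function(zidx) {
    m <- array(FALSE, c(30, 4, 4)); m[zidx, , ] <- TRUE
    structure_mask("s", m, sp)
  }
  a <- mk(3:8)       # 6 slices of 5 mm -> 3.0 cm extent
  expect_equal(overlap_slices_thickness(a, a), 3.0)
  # A's outer top face at 47.5 mm, B's bottom face at 92.5 mm -> -4.5 cm
  a2 <- mk(1:10)
  b2 <- mk(20:30)
  expect_equal(overlap_slices_thickness(a2, b2), -4.5)
  # A strictly inside B's span -> A's own extent
  inner <- mk(12:15)
  outer <- mk(5:25)
  expect_equal(overlap_slices_thickness(inner, outer), 4 * 0.5)
  # never exceeds either structure's z-extent; negative iff spans disjoint
  for (seed in 1:5) {
    set.seed(seed)
    za <- sort(sample(30, 2)); zb <- sort(sample(30, 2))
    A <- mk(za[1]:za[2]); B <- mk(zb[1]:zb[2])
    th <- overlap_slices_thickness(A, B)
    expect_lte(th, min(diff(za) + 1, diff(zb) + 1) * 0.5)
    disjoint <- za[2] < zb[1] || zb[2] < za[1]
    expect_identical(th < 0, disjoint)
  }
})

test_that("overlap volume ratios follow set algebra", {
  sp <- c(2, 2, 2)
  cube <- function(z, y, x) {
    m <- array(FALSE, c(12, 12, 12)); m[z, y, x] <- TRUE
    structure_mask("c", m, sp)
  }
  a <- cube(1:4, 1:4, 1:4)
  b <- cube(8:11, 8:11, 8:11)
  expect_equal(overlap_volume_ratio(a, b, "A"), 0)
  inner <- cube(2:3, 2:3, 2:3)
  expect_equal(overlap_volume_ratio(inner, a, "A"), 1)
  # equal cubes sharing half their extent
  c1 <- cube(1:4, 1:4, 1:4)
  c2 <- cube(3:6, 1:4, 1:4)
  expect_equal(overlap_volume_ratio(c1, c2, "A"), 0.5)
  # |A n B| identity between the two denominators
  expect_equal(overlap_volume_ratio(c1, c2, "A") * structure_volume(c1),
               overlap_volume_ratio(c1, c2, "B") * structure_volume(c2))
})

test_that("neck-corrected nodal volume subtracts tagged components", {
  dims <- c(20, 8, 8); sp <- c(2, 2, 2)
  m <- array(FALSE, dims)
  m[1:10, 2:6, 2:6] <- TRUE    # mediastinal component
  m[15:18, 3:5, 3:5] <- TRUE   # neck component
  lab <- array(0L, dims); lab[1:10, 2:6, 2:6] <- 1L; lab[15:18, 3:5, 3:5] <- 2L
  ln <- structure_mask("PTV_LN", m, sp, component_labels = lab,
                       component_tags = c("2" = "neck_node"))
  full <- structure_volume(ln)
  neck <- 4 * 3 * 3 * prod(sp) / 1000
  expect_equal(corrected_ln_volume(ln), full - neck)
  # untagged mask: corrected equals full volume
  ln0 <- structure_mask("PTV_LN", m, sp)
  expect_equal(corrected_ln_volume(ln0), structure_volume(ln0))
  # everything tagged neck: corrected volume collapses to zero
  all_neck <- structure_mask("PTV_LN", m, sp, component_labels = lab,
                             component_tags = c("1" = "neck_node",
                                                "2" = "neck_node"))
  expect_equal(corrected_ln_volume(all_neck), 0)
})

test_that("feature extraction is deterministic and flags degenerate anatomy", {
  st <- small_phantom_case()$structures
  f1 <- extract_features(st)
  f2 <- extract_features(st)
  expect_identical(f1, f2)
  expect_true(all(vapply(f1, is.finite, logical(1))))
  expect_lte(f1$corr_vol_ratio_ln_total_lung, f1$vol_ratio_ln_total_lung)
  expect_lte(f1$corr_vol_ratio_ln_ipsi_lung, f1$vol_ratio_ln_ipsi_lung)
  # heart placed clear of the nodal target -> overlap ratio exactly 0
  st0 <- make_phantom(phantom_spec(shape = c(72, 46, 60),
                                   spacing = c(4.5, 4.5, 4.5),
                                   heart_ln_overlap_cc = 0))
  expect_equal(extract_features(st0)$overlap_ratio_heart_ln_to_ln, 0)
})
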
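# Synthetic thoracic phantom: two lung ellipsoids, a heart ellipsoid, an
# esophageal tube, a spinal-cord cylinder, a spherical primary-tumour PTV
# inside the ipsilateral lung and an ellipsoidal nodal PTV in the
# mediastinum (optionally with a separate neck-node component cranial to
# the lung apices).  Placement of the primary target is driven by two
# controllable geometry features: the minimum 3D surface gap to the nodal
# target and the signed cranio-caudal overlap thickness.  Analytic
# two-component dose distributions (prescription plateau with
# distance-driven sigmoid falloff) stand in for planned dose.

#' Specify a synthetic thoracic phantom
#'
#' Default target sizes are the cohort central values this generator
#' emulates (primary PTV 30.7 cc, nodal PTV 199.5 cc, 4.0 cm gap, 1.9 cm
#' cranio-caudal overlap); the realizable ranges are primary 10.9-100.1 cc,
#' nodal 24.8-452.3 cc, gap 1.2-7.1 cm, overlap -4.5-6.1 cm.
#'
#' @param shape lattice dimensions (z, y, x).
#' @param spacing voxel size in mm (z, y, x).
#' @param pt_volume_cc primary-tumour PTV volume (sphere).
#' @param ln_volume_cc nodal PTV volume (2:1:1 prolate ellipsoid, long axis
#'   cranio-caudal); excludes any neck component.
#' @param pt_ln_gap_cm requested minimum 3D surface distance between the
#'   two targets.
#' @param pt_ln_overlap_cm requested signed cranio-caudal overlap
#'   thickness; negative values place the primary tumour cranial to the
#'   nodal target with an axial gap.  Must not exceed the smaller of the
#'   two z-extents.
#' @param heart_ln_overlap_cc requested heart / nodal-PTV overlap volume
#'   (cc); the heart's anterior offset is solved so the realized overlap
#'   matches it.  The default gives an overlap ratio to the nodal target of
#'   about 0.07 (the cohort median); 0 places the heart clear of the nodal
#'   target.
#' @param neck_node_cc volume of an optional neck-node component of the
#'   nodal PTV (0 = none), placed cranial to the lung apices.
#' @param laterality which lung hosts the primary tumour.
#' @param jitter_mm s.d. of the seeded random jitter applied to organ
#'   centres (anatomy variation across a cohort); 0 = fully deterministic
#'   geometry.
#' @param seed integer seed driving the jitter.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(110, 70, 90), spacing = c(3, 3, 3),
                         pt_volume_cc = 30.7, ln_volume_cc = 199.5,
                         pt_ln_gap_cm = 4.0, pt_ln_overlap_cm = 1.9,
                         heart_ln_overlap_cc = 14, neck_node_cc = 0,
                         laterality = c("right", "left"),
                         jitter_mm = 0, seed = 1L) {
  laterality <- match.arg(laterality)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (pt_volume_cc <= 0 || ln_volume_cc <= 0) stop("target volumes must be positive")
  if (heart_ln_overlap_cc < 0) stop("heart_ln_overlap_cc must be >= 0")
  r_pt <- (3 * pt_volume_cc * 1000 / (4 * pi))^(1 / 3)
  if (r_pt < max(spacing))
    stop("primary target radius below voxel spacing: unrealizable on lattice")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 pt_volume_cc = pt_volume_cc, ln_volume_cc = ln_volume_cc,
                 pt_ln_gap_cm = pt_ln_gap_cm,
                 pt_ln_overlap_cm = pt_ln_overlap_cm,
                 heart_ln_overlap_cc = heart_ln_overlap_cc,
                 neck_node_cc = neck_node_cc, laterality = laterality,
                 jitter_mm = jitter_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance from point p (relative to centre) to the surface of an
# axis-aligned ellipsoid with semi-axes `semi`; negative inside.
point_ellipsoid_distance <- function(p, semi) {
  q <- sum((p / semi)^2)
  if (q <= 1) return(-(1 - sqrt(q)) * min(semi))  # approximate depth, unused
  # nearest surface point: x_i = semi_i^2 p_i / (semi_i^2 + t), t > 0
  f <- function(t) sum(semi^2 * p^2 / (semi^2 + t)^2) - 1
  t <- stats::uniroot(f, c(0, max(semi) * sqrt(sum(p^2)) + 1),
                      tol = 1e-10)$root
  x <- semi^2 * p / (semi^2 + t)
  sqrt(sum((p - x)^2))
}

# voxel-centre coordinate arrays for a lattice
coord_arrays <- function(shape, spacing, origin = c(0, 0, 0)) {
  z <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  x <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(z = array(rep(z, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
       x = array(rep(x, each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(co, centre, semi) {
  ((co$z - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$x - centre[3]) / semi[3])^2 <= 1
}

# z-aligned tube of radius r between z limits
tube_mask <- function(co, yx_centre, r, zlim) {
  (co$y - yx_centre[1])^2 + (co$x - yx_centre[2])^2 <= r^2 &
    co$z >= zlim[1] & co$z <= zlim[2]
}

#' Generate a phantom structure set
#'
#' Realizes a [phantom_spec()] on its lattice.  The primary target is
#' placed so that the realized minimum surface gap and signed cranio-caudal
#' overlap with the nodal target match the requested values to within
#' voxelization error (about one voxel diagonal); realized target volumes
#' match requested volumes within voxelization error.  The ipsilateral
#' lung mask includes the primary target (tumour delineated within lung).
#'
#' @param spec a [phantom_spec()].
#' @return A [structure_set()] with the seven required structures; the
#'   nodal PTV carries component labels (component 2 tagged `"neck_node"`
#'   when a neck component was requested).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing
  extent <- (sh - 1) * sp
  co <- coord_arrays(sh, sp)
  rng <- local_rng(spec$seed)
  jit <- function(n = 3) if (spec$jitter_mm > 0)
    rng$rnorm(n, 0, spec$jitter_mm) else rep(0, n)

  cx <- extent[3] / 2; cy <- extent[2] / 2
  lung_z_c <- 0.46 * extent[1]
  lung_semi <- c(0.29 * extent[1], 0.31 * extent[2], 0.195 * extent[3])
  side <- if (spec$laterality == "right") 1 else -1
  lung_r_c <- c(lung_z_c, cy - 0.015 * extent[2], cx + 0.23 * extent[3]) + jit()
  lung_l_c <- c(lung_z_c, cy - 0.015 * extent[2], cx - 0.23 * extent[3]) + jit()
  eso_yx <- c(cy + 0.15 * extent[2], cx + 0.017 * extent[3]) + jit(2)
  cord_yx <- c(cy + 0.30 * extent[2], cx) + jit(2)

  lung_r <- ellipsoid_mask(co, lung_r_c, lung_semi)
  lung_l <- ellipsoid_mask(co, lung_l_c, lung_semi)
  eso <- tube_mask(co, eso_yx, 6, c(0.12, 0.80) * extent[1])
  cord <- tube_mask(co, cord_yx, 6, c(0, 0.97) * extent[1])

  # nodal PTV: prolate ellipsoid (2:1:1) in the mediastinum
  s_ln <- (3 * spec$ln_volume_cc * 1000 / (8 * pi))^(1 / 3)
  ln_semi <- c(2 * s_ln, s_ln, s_ln)
  ln_c <- c(0.49 * extent[1], cy + 0.025 * extent[2], cx) + jit()
  ln_main <- ellipsoid_mask(co, ln_c, ln_semi)

  # heart: mid-caudal ellipsoid whose anterior offset from the nodal PTV is
  # solved so the realized heart/LN overlap matches the requested volume
  heart_semi <- c(0.155 * extent[1], 0.22 * extent[2], 0.17 * extent[3])
  heart_zx <- c(0.40 * extent[1], cx - 0.06 * extent[3]) + jit(2)
  vox_cc <- prod(sp) / 1000
  heart_at <- function(dy)
    ellipsoid_mask(co, c(heart_zx[1], ln_c[2] - dy, heart_zx[2]), heart_semi)
  overlap_at <- function(dy) sum(heart_at(dy) & ln_main) * vox_cc
  dy_max <- ln_semi[2] + heart_semi[2] + 5 * sp[2]
  if (spec$heart_ln_overlap_cc == 0) {
    dy <- dy_max
  } else {
    if (overlap_at(0) < spec$heart_ln_overlap_cc)
      stop("requested heart/LN overlap volume unrealizable for this anatomy")
    lo <- 0; hi <- dy_max
    for (iter in 1:25) {
      mid <- (lo + hi) / 2
      if (overlap_at(mid) >= spec$heart_ln_overlap_cc) lo <- mid else hi <- mid
    }
    dy <- lo
  }
  heart <- heart_at(dy)
  heart_c <- c(heart_zx[1], ln_c[2] - dy, heart_zx[2])

  # primary PTV: sphere placed from the requested gap/overlap
  r_pt <- (3 * spec$pt_volume_cc * 1000 / (4 * pi))^(1 / 3)
  overlap <- spec$pt_ln_overlap_cm * 10
  if (overlap > min(2 * r_pt, 2 * ln_semi[1]) + 1e-9)
    stop("requested cranio-caudal overlap exceeds a target z-extent: unrealizable")
  dz <- ln_semi[1] + r_pt - overlap
  gap <- spec$pt_ln_gap_cm * 10
  fgap <- function(dx) point_ellipsoid_distance(c(dz, 0, dx), ln_semi) - r_pt - gap
  hi <- ln_semi[3] + r_pt + gap + 10
  if (fgap(hi) < 0) hi <- hi + gap + 50
  dx <- if (fgap(0) >= 0) 0 else stats::uniroot(fgap, c(0, hi), tol = 1e-8)$root
  pt_c <- ln_c + c(dz, 0, side * dx)
  if (pt_c[1] + r_pt > extent[1] || pt_c[3] + r_pt > extent[3] ||
      pt_c[3] - r_pt < 0)
    stop("primary target placement falls outside the lattice: unrealizable")
  pt <- ellipsoid_mask(co, pt_c, rep(r_pt, 3))

  ln_mask <- ln_main
  comp <- array(0L, sh); comp[ln_main] <- 1L
  tags <- NULL
  if (spec$neck_node_cc > 0) {
    r_nn <- (3 * spec$neck_node_cc * 1000 / (4 * pi))^(1 / 3)
    apex <- max(lung_r_c[1] + lung_semi[1], lung_l_c[1] + lung_semi[1])
    nn_c <- c(apex + r_nn + 2 * sp[1], cy, cx + 0.05 * extent[3])
    if (nn_c[1] + r_nn > extent[1])
      stop("neck node does not fit above the lung apices: unrealizable")
    nn <- ellipsoid_mask(co, nn_c, rep(r_nn, 3))
    if (any(nn & ln_mask)) stop("neck node merged with mediastinal component")
    ln_mask <- ln_mask | nn
    comp[nn] <- 2L
    tags <- c("2" = "neck_node")
  }

  lung_ipsi_m <- (if (side == 1) lung_r else lung_l) & !heart | pt
  lung_contra <- (if (side == 1) lung_l else lung_r) & !heart
  st <- list(
    PTV_PT = structure_mask("PTV_PT", pt, sp),
    PTV_LN = structure_mask("PTV_LN", ln_mask, sp, component_labels = comp,
                            component_tags = tags),
    lung_total = structure_mask("lung_total", lung_ipsi_m | lung_contra, sp),
    lung_ipsi = structure_mask("lung_ipsi", lung_ipsi_m, sp),
    heart = structure_mask("heart", heart, sp),
    esophagus = structure_mask("esophagus", eso, sp),
    spinal_cord = structure_mask("spinal_cord", cord, sp))
  realized <- sum(pt) * prod(sp) / 1000
  if (abs(realized - spec$pt_volume_cc) > 0.1 * spec$pt_volume_cc)
    stop(sprintf("realized primary volume %.1f cc deviates > 10%% from %.1f cc; refine the lattice",
                 realized, spec$pt_volume_cc))
  structure_set(st, spec$laterality)
}

# deterministic RNG stream that leaves the global seed untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else rm(list = ".Random.seed", envir = globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = with_state(stats::runif), rnorm = with_state(stats::rnorm),
       sample_int = with_state(sample.int))
}

#' Specify the analytic dose model of a hybrid regime
#'
#' Two regimes: `"C&S"` delivers 2 Gy x 30 to the nodal PTV (CFRT) plus a
#' 12.5 Gy x 4 stereotactic boost to the primary PTV; `"C&SIB"` delivers
#' 2 Gy x 26 (CFRT) plus a sequential 4-fraction plan combining 2 Gy x 4 to
#' the nodal PTV with 12.5 Gy x 4 to the primary PTV.  Each component is a
#' prescription plateau inside its target with a sigmoid falloff in signed
#' surface distance; the stereotactic falloff reaches its 50% isodose
#' within 6 mm of the target surface by default, the CFRT penumbra is
#' broader.  A small distance-decaying scatter background is added.
#'
#' @param regime `"C&S"` or `"C&SIB"`.
#' @param sbrt_d50_mm distance (mm) from the primary-target surface at
#'   which the boost falls to 50% of prescription (<= 6 by default).
#' @param cfrt_d50_mm the CFRT equivalent for the nodal component.
#' @param sbrt_margin_mm,cfrt_margin_mm distance (mm) out to which the
#'   prescription isodose spills beyond the target surface.
#' @param hotspot fractional in-target dose heterogeneity of the boost
#'   plateau (0 = flat).
#' @param cfrt_hotspot the CFRT equivalent.
#' @param background_frac scatter floor as a fraction of prescription.
#' @param adjust_boost apply the unintended-dose prescription adjustment
#'   (the CFRT D99 of the primary target, EQD2-converted, is deducted from
#'   the boost prescription before conversion back to fraction dose).
#' @param ab_tumor tumour alpha/beta (Gy) used by the adjustment.
#' @return An object of class `dose_model_spec`.
#' @export
dose_model_spec <- function(regime = c("C&S", "C&SIB"), sbrt_d50_mm = 5,
                            cfrt_d50_mm = 12, sbrt_margin_mm = 1,
                            cfrt_margin_mm = 4, hotspot = 0.10,
                            cfrt_hotspot = 0.03, background_frac = 0.04,
                            adjust_boost = TRUE, ab_tumor = 10) {
  regime <- match.arg(regime)
  if (sbrt_d50_mm <= 0 || sbrt_d50_mm > 6)
    stop("stereotactic 50% falloff must be in (0, 6] mm")
  if (cfrt_d50_mm <= 0) stop("cfrt_d50_mm must be positive")
  schemes <- if (regime == "C&S") {
    list(cfrt = fractionation_scheme(30, 2, "CFRT"),
         boost_pt = fractionation_scheme(4, 12.5, "SBRT"))
  } else {
    list(cfrt = fractionation_scheme(26, 2, "CFRT"),
         boost_pt = fractionation_scheme(4, 12.5, "SIB_boost"),
         boost_ln = fractionation_scheme(4, 2, "SIB_boost"))
  }
  structure(list(regime = regime, schemes = schemes,
                 sbrt_d50_mm = sbrt_d50_mm, cfrt_d50_mm = cfrt_d50_mm,
                 sbrt_margin_mm = sbrt_margin_mm,
                 cfrt_margin_mm = cfrt_margin_mm,
                 hotspot = hotspot, cfrt_hotspot = cfrt_hotspot,
                 background_frac = background_frac,
                 adjust_boost = adjust_boost, ab_tumor = ab_tumor),
            class = "dose_model_spec")
}

# plateau + sigmoid falloff component: prescription inside the target
# (with optional centre-weighted hotspot), a thin shell still at
# prescription out to margin_mm (the isodose spill a real plan shows), 50%
# of prescription at d50_mm, plus an exponentially decaying scatter floor.
dose_component <- function(target, rx, d50_mm, hotspot, background_frac,
                           margin_mm = 0, hot_scale_mm = 15, bg_scale_mm = 80) {
  if (d50_mm <= margin_mm) stop("d50_mm must exceed margin_mm")
  sd <- signed_surface_distance(target)
  k <- log(3) / (d50_mm - margin_mm)
  f <- ifelse(sd <= 0,
              1 + hotspot * (1 - exp(sd / hot_scale_mm)),
              pmin(1, 2 / (1 + exp(k * (sd - margin_mm)))))
  bg <- background_frac * exp(-pmax(sd, 0) / bg_scale_mm)
  volume_grid(rx * pmax(f, bg), target$spacing, target$origin)
}

#' Generate the per-component dose grids of a hybrid plan
#'
#' @param structures a [structure_set()] from [make_phantom()] (or any set
#'   with the required targets).
#' @param dose_spec a [dose_model_spec()].
#' @return A list with `cfrt` and `boost` [volume_grid()]s (physical dose),
#'   the corresponding schemes (`cfrt_scheme`, `boost_scheme`), and
#'   `boost_scheme_nominal` when the prescription adjustment was applied.
#' @export
make_dose <- function(structures, dose_spec) {
  stopifnot(inherits(dose_spec, "dose_model_spec"))
  check_required(structures, c("PTV_PT", "PTV_LN"))
  pt <- get_structure(structures, "PTV_PT")
  ln <- get_structure(structures, "PTV_LN")
  sch <- dose_spec$schemes
  cfrt <- dose_component(ln, sch$cfrt$total_dose, dose_spec$cfrt_d50_mm,
                         dose_spec$cfrt_hotspot, dose_spec$background_frac,
                         dose_spec$cfrt_margin_mm)
  boost_scheme <- sch$boost_pt
  nominal <- NULL
  if (dose_spec$adjust_boost) {
    d99 <- d_at_volume(cfrt, pt, 99)
    nominal <- boost_scheme
    boost_scheme <- adjust_boost_prescription(nominal, d99, sch$cfrt,
                                              dose_spec$ab_tumor)
  }
  boost <- dose_component(pt, boost_scheme$total_dose, dose_spec$sbrt_d50_mm,
                          dose_spec$hotspot, dose_spec$background_frac,
                          dose_spec$sbrt_margin_mm)
  if (dose_spec$regime == "C&SIB") {
    ln_comp <- dose_component(ln, sch$boost_ln$total_dose,
                              dose_spec$cfrt_d50_mm, dose_spec$cfrt_hotspot,
                              dose_spec$background_frac,
                              dose_spec$cfrt_margin_mm)
    boost <- volume_grid(pmax(boost$values, ln_comp$values),
                         boost$spacing, boost$origin)
  }
  list(cfrt = cfrt, boost = boost, cfrt_scheme = sch$cfrt,
       boost_scheme = boost_scheme, boost_scheme_nominal = nominal)
}
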
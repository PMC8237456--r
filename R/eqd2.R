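# Linear-quadratic EQD2 machinery: scalar and voxel-wise conversion, its
# inverse, the boost prescription-adjustment rule, and hybrid-plan dose
# summation.  EQD2 = D (d + a/b) / (2 + a/b) with d the dose per fraction;
# 2 Gy fractions are their own EQD2, so the CFRT component always enters
# the sum uncorrected.

#' Define a fractionation scheme
#'
#' @param n_fractions number of fractions (>= 1).
#' @param fraction_dose nominal dose per fraction in Gy (>= 0; 0 only for
#'   the degenerate "nothing left to deliver" scheme).
#' @param label one of `"CFRT"`, `"SBRT"`, `"SIB_boost"`.
#' @return An object of class `fractionation_scheme` with fields
#'   `n_fractions`, `fraction_dose` and `total_dose`.
#' @export
fractionation_scheme <- function(n_fractions, fraction_dose,
                                 label = c("CFRT", "SBRT", "SIB_boost")) {
  label <- match.arg(label)
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("n_fractions must be a positive integer")
  if (fraction_dose < 0 || !is.finite(fraction_dose))
    stop("fraction_dose must be finite and >= 0")
  structure(list(n_fractions = as.integer(n_fractions),
                 fraction_dose = fraction_dose,
                 total_dose = n_fractions * fraction_dose,
                 label = label),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<%s> %g Gy x %df = %g Gy\n", x$label, x$fraction_dose,
              x$n_fractions, x$total_dose))
  invisible(x)
}

#' Per-structure alpha/beta assignment
#'
#' Maps structure names to linear-quadratic alpha/beta values (Gy) with a
#' priority order resolving voxels inside several structures, plus a
#' default for unassigned voxels.  Defaults: targets 10 Gy, lung 3 Gy,
#' heart 3 Gy, esophagus 10 Gy, spinal cord 2 Gy; targets outrank organs
#' at risk, which outrank lung.  All values are configurable — only the
#' lung value is anchored in the radiobiology literature this package
#' follows; the rest are conventional.
#'
#' @param values named numeric vector of alpha/beta in Gy.
#' @param priority character vector, highest priority first; must cover
#'   all names in `values`.
#' @param default alpha/beta for voxels in no listed structure (Gy), or
#'   `NA` to make such voxels an error in [eqd2_grid()].
#' @return An object of class `alpha_beta_map`.
#' @export
alpha_beta_map <- function(values = c(PTV_PT = 10, PTV_LN = 10,
                                      spinal_cord = 2, esophagus = 10,
                                      heart = 3, lung_ipsi = 3,
                                      lung_total = 3),
                           priority = c("PTV_PT", "PTV_LN", "spinal_cord",
                                        "esophagus", "heart", "lung_ipsi",
                                        "lung_total"),
                           default = 3) {
  if (any(values <= 0) || any(!is.finite(values)))
    stop("all alpha/beta values must be positive and finite")
  if (!setequal(priority, names(values)))
    stop("priority must cover exactly the structures in values")
  if (!is.na(default) && default <= 0) stop("default alpha/beta must be positive")
  structure(list(values = values, priority = priority, default = default),
            class = "alpha_beta_map")
}

#' Scalar EQD2 conversion
#'
#' `EQD2 = D (d + alpha/beta) / (2 + alpha/beta)` with `d = D / n`.
#' Vectorized over `D`.
#'
#' @param D total physical dose in Gy (>= 0).
#' @param n_fractions number of fractions delivering `D`.
#' @param alpha_beta tissue alpha/beta in Gy (> 0).
#' @return EQD2 in Gy.
#' @export
eqd2_scalar <- function(D, n_fractions, alpha_beta) {
  if (alpha_beta <= 0 || !is.finite(alpha_beta))
    stop("alpha/beta must be positive and finite")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (any(D < 0)) stop("dose must be >= 0")
  D * (D / n_fractions + alpha_beta) / (2 + alpha_beta)
}

#' Invert EQD2 to a fraction dose
#'
#' Returns the fraction dose `d` such that `n` fractions of `d` give the
#' target EQD2: the positive root of `n d (d + alpha/beta) =
#' E (2 + alpha/beta)`.  Round trip with [eqd2_scalar()] is exact to
#' floating point.
#'
#' @param E target EQD2 in Gy (>= 0); vectorized.
#' @param n_fractions number of fractions.
#' @param alpha_beta tissue alpha/beta in Gy.
#' @return Fraction dose in Gy.
#' @export
invert_eqd2 <- function(E, n_fractions, alpha_beta) {
  if (any(E < 0)) stop("target EQD2 must be >= 0")
  if (alpha_beta <= 0 || !is.finite(alpha_beta))
    stop("alpha/beta must be positive and finite")
  (-alpha_beta + sqrt(alpha_beta^2 +
                        4 * E * (2 + alpha_beta) / n_fractions)) / 2
}

#' Voxel-wise EQD2 conversion of a dose grid
#'
#' Converts every voxel with [eqd2_scalar()], using the per-voxel fraction
#' dose `dose / n_fractions` and the alpha/beta resolved by structure
#' priority: a voxel takes the alpha/beta of the highest-priority structure
#' containing it, else the map default.
#'
#' @param dose a [volume_grid()] of physical dose in Gy.
#' @param n_fractions fractions over which the grid dose is delivered.
#' @param ab_map an [alpha_beta_map()].
#' @param structures a [structure_set()] on the dose lattice.
#' @return A [volume_grid()] of EQD2 in Gy.
#' @export
eqd2_grid <- function(dose, n_fractions, ab_map, structures) {
  stopifnot(inherits(dose, "volume_grid"), inherits(ab_map, "alpha_beta_map"))
  for (s in structures$structures)
    if (!same_lattice(dose, s)) stop("dose and structures must share a lattice")
  ab <- array(NA_real_, dim(dose$values))
  # apply lowest priority first so higher priorities overwrite
  for (nm in rev(ab_map$priority)) {
    s <- structures$structures[[nm]]
    if (!is.null(s)) ab[s$mask] <- ab_map$values[[nm]]
  }
  unassigned <- is.na(ab)
  if (any(unassigned)) {
    if (is.na(ab_map$default))
      stop("voxels outside all structures and no default alpha/beta set")
    ab[unassigned] <- ab_map$default
  }
  D <- dose$values
  volume_grid(D * (D / n_fractions + ab) / (2 + ab), dose$spacing, dose$origin)
}

#' Adjust a boost prescription for unintended CFRT dose
#'
#' The boost target already receives unintended dose (its D99) from the
#' CFRT component.  That dose, converted to EQD2, is subtracted from the
#' EQD2-corrected boost prescription, and the remaining EQD2 is converted
#' back to an actual fraction dose.  Two conversion modes:
#' `"eqd2_inversion"` (default) solves the LQ quadratic exactly so the
#' delivered boost EQD2 equals the remaining EQD2 by construction;
#' `"proportional"` scales the nominal fraction dose by the EQD2 ratio
#' `E_remaining / E_rx`.
#'
#' @param nominal nominal boost [fractionation_scheme()] (e.g. 12.5 Gy x 4).
#' @param cfrt_D99_PT unintended CFRT dose to the boost target in Gy.
#' @param cfrt_scheme the CFRT [fractionation_scheme()] delivering it.
#' @param ab_tumor tumour alpha/beta in Gy.
#' @param mode `"eqd2_inversion"` or `"proportional"`.
#' @return The adjusted [fractionation_scheme()] (same fraction number).
#'   If nothing remains to deliver, a zero-dose scheme with a warning.
#' @export
adjust_boost_prescription <- function(nominal, cfrt_D99_PT, cfrt_scheme,
                                      ab_tumor = 10,
                                      mode = c("eqd2_inversion", "proportional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nominal, "fractionation_scheme"),
            inherits(cfrt_scheme, "fractionation_scheme"))
  if (cfrt_D99_PT < 0) stop("cfrt_D99_PT must be >= 0")
  E_rx <- eqd2_scalar(nominal$total_dose, nominal$n_fractions, ab_tumor)
  E_unintended <- eqd2_scalar(cfrt_D99_PT, cfrt_scheme$n_fractions, ab_tumor)
  E_remaining <- max(E_rx - E_unintended, 0)
  if (E_remaining == 0) {
    warning("unintended CFRT dose covers the whole boost prescription; ",
            "returning a zero-dose scheme")
    return(fractionation_scheme(nominal$n_fractions, 0, nominal$label))
  }
  d_adj <- switch(mode,
    eqd2_inversion = invert_eqd2(E_remaining, nominal$n_fractions, ab_tumor),
    proportional = nominal$fraction_dose * E_remaining / E_rx)
  fractionation_scheme(nominal$n_fractions, d_adj, nominal$label)
}

#' Sum the CFRT and boost components of a hybrid plan
#'
#' Physical domain: plain voxel-wise sum.  EQD2 domain: the boost grid is
#' EQD2-converted voxel-wise over its fraction number and added to the
#' *physical* CFRT grid — at 2 Gy per fraction the CFRT component is its
#' own EQD2, so it is never converted.
#'
#' @param cfrt,boost [volume_grid()] components on one lattice (resample
#'   first with [resample_to()] if needed).
#' @param boost_scheme the boost [fractionation_scheme()] (fraction number
#'   drives the voxel-wise conversion).
#' @param ab_map an [alpha_beta_map()] (EQD2 domain only).
#' @param structures a [structure_set()] (EQD2 domain only).
#' @param domain `"physical"` or `"EQD2"`.
#' @return A [volume_grid()] of summed dose in Gy.
#' @export
sum_hybrid <- function(cfrt, boost, boost_scheme, ab_map = NULL,
                       structures = NULL, domain = c("physical", "EQD2")) {
  domain <- match.arg(domain)
  if (!same_lattice(cfrt, boost))
    stop("lattice mismatch between CFRT and boost grids; resample first")
  if (domain == "physical")
    return(volume_grid(cfrt$values + boost$values, cfrt$spacing, cfrt$origin))
  if (is.null(ab_map) || is.null(structures))
    stop("EQD2 summation needs ab_map and structures")
  boost_e <- eqd2_grid(boost, boost_scheme$n_fractions, ab_map, structures)
  volume_grid(cfrt$values + boost_e$values, cfrt$spacing, cfrt$origin)
}

#' Assemble a hybrid plan's physical and EQD2 dose
#'
#' Resamples the boost onto the CFRT lattice (trilinear) and computes both
#' summed grids.
#'
#' @param cfrt,boost physical-dose [volume_grid()]s for the two components.
#' @param cfrt_scheme,boost_scheme [fractionation_scheme()]s.
#' @param ab_map an [alpha_beta_map()].
#' @param structures a [structure_set()] on the CFRT lattice.
#' @return An object of class `hybrid_plan_dose` with components `cfrt`,
#'   `boost`, `summed_physical`, `summed_eqd2` and the schemes.
#' @export
hybrid_plan_dose <- function(cfrt, boost, cfrt_scheme, boost_scheme,
                             ab_map, structures) {
  boost <- resample_to(boost, cfrt, mode = "trilinear")
  structure(list(
    cfrt = cfrt, boost = boost,
    cfrt_scheme = cfrt_scheme, boost_scheme = boost_scheme,
    summed_physical = sum_hybrid(cfrt, boost, boost_scheme,
                                 domain = "physical"),
    summed_eqd2 = sum_hybrid(cfrt, boost, boost_scheme, ab_map, structures,
                             domain = "EQD2")),
    class = "hybrid_plan_dose")
}
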
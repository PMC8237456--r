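# Cumulative DVH and the plan-parameter set used to score hybrid plans:
# conformity index CI = V_RX^2 / (TV * V_RI), homogeneity index HI =
# D5 / D95, Vx (% volume at >= x Gy), Dx (minimum dose to the hottest x%),
# mean and maximum doses.  Dx uses the sorted-voxel empirical inverse CDF
# ("higher" side), so every metric is exactly checkable by voxel counting.

mask_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "structure_mask"))
  if (!same_lattice(dose, mask)) stop("dose and mask must share a lattice")
  if (!any(mask$mask)) stop(sprintf("structure '%s' is empty", mask$name))
  dose$values[mask$mask]
}

#' Cumulative dose-volume histogram
#'
#' @param dose a [volume_grid()].
#' @param mask a [structure_mask()] on the same lattice.
#' @param bin_width DVH bin width in Gy.
#' @return An object of class `dvh_curve`: `dose` (bin edges, Gy) and
#'   `volume_pct` (cumulative % of the structure receiving at least that
#'   dose), starting at 100% and reaching 0% past the maximum dose.
#' @export
dvh <- function(dose, mask, bin_width = 0.05) {
  v <- mask_doses(dose, mask)
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  vol <- vapply(edges, function(x) mean(v >= x) * 100, numeric(1))
  structure(list(dose = edges, volume_pct = vol, structure = mask$name,
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d bins of %g Gy, D up to %g Gy\n",
              x$structure, length(x$dose), x$bin_width, max(x$dose)))
  invisible(x)
}

#' Vx: percent volume receiving at least a dose
#' @inheritParams dvh
#' @param x dose threshold in Gy.
#' @return Percent of the structure volume with dose `>= x`.
#' @export
v_at_dose <- function(dose, mask, x) {
  v <- mask_doses(dose, mask)
  mean(v >= x) * 100
}

#' Dx: minimum dose to the hottest p% of a structure
#'
#' Empirical inverse cumulative DVH at voxel granularity: voxel doses are
#' sorted in decreasing order and the `ceiling(p/100 * n)`-th value is
#' returned, i.e. the smallest dose still inside the hottest p%.
#'
#' @inheritParams dvh
#' @param p volume percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
d_at_volume <- function(dose, mask, p) {
  if (p <= 0 || p > 100) stop("p must be in (0, 100]")
  v <- sort(mask_doses(dose, mask), decreasing = TRUE)
  v[ceiling(p / 100 * length(v))]
}

#' Conformity index at a dose level
#'
#' `CI = V_RX^2 / (TV * V_RI)` with `TV` the target volume, `V_RX` the
#' target volume covered by at least level `L`, and `V_RI` the total volume
#' anywhere receiving at least `L`.  CI is 1 only when the reference
#' isodose coincides exactly with the target.
#'
#' @param dose a [volume_grid()].
#' @param target a [structure_mask()].
#' @param level isodose level `L` in Gy.
#' @return CI in `[0, 1]`; 0 (with a warning) if no voxel reaches `L`.
#' @export
conformity_index <- function(dose, target, level) {
  if (!same_lattice(dose, target)) stop("dose and target must share a lattice")
  if (!any(target$mask)) stop("empty target")
  vv <- voxel_volume_cc(dose)
  tv <- sum(target$mask) * vv
  v_ri <- sum(dose$values >= level) * vv
  if (v_ri == 0) {
    warning(sprintf("no voxel reaches %g Gy; CI set to 0", level))
    return(0)
  }
  v_rx <- sum(target$mask & dose$values >= level) * vv
  v_rx^2 / (tv * v_ri)
}

#' Homogeneity index D5/D95
#' @inheritParams conformity_index
#' @return HI (>= 1 for any dose distribution).
#' @export
homogeneity_index <- function(dose, target) {
  d95 <- d_at_volume(dose, target, 95)
  if (d95 <= 0) stop("D95 is zero; HI undefined")
  d_at_volume(dose, target, 5) / d95
}

#' Plan-parameter names
#' @return Character vector of the parameter columns produced by
#'   [plan_parameters()].
#' @export
plan_parameter_names <- function() {
  c("ptv_ln_ci60", "ptv_ptln_ci60", "ptv_pt_ci140", "hi_ptv_ln",
    "lung_total_v20", "lung_total_mld", "lung_ipsi_v20", "lung_ipsi_mld",
    "cord_dmax", "heart_d5", "heart_d30", "heart_dmax", "heart_mean",
    "eso_dmax", "eso_v50")
}

#' Compute the plan-parameter vector for one hybrid plan
#'
#' Target coverage: nodal-target CI at 60 Gy and the CI of the union target
#' (primary + nodal, overlap voxels counted once) at 60 Gy, plus — in the
#' EQD2 domain only — the primary-target CI at 140 Gy and the nodal-target
#' homogeneity index.  Organs at risk: total and ipsilateral lung V20 (%)
#' and mean dose, spinal cord maximum, heart D5/D30/maximum/mean, esophagus
#' maximum and V50 (%).  Maximum dose is the maximum voxel value.
#'
#' @param hybrid a [hybrid_plan_dose()].
#' @param structures a [structure_set()] with the required structures.
#' @param domain `"physical"` or `"EQD2"` — selects the summed grid.
#' @param ci_ln_level,ci_union_level,ci_pt_level CI isodose levels in Gy.
#' @param lung_v_level,eso_v_level Vx thresholds in Gy.
#' @return A one-row `data.frame` with the columns of
#'   [plan_parameter_names()] plus a `domain` tag; `ptv_pt_ci140` is `NA`
#'   in the physical domain.
#' @export
plan_parameters <- function(hybrid, structures, domain = c("physical", "EQD2"),
                            ci_ln_level = 60, ci_union_level = 60,
                            ci_pt_level = 140, lung_v_level = 20,
                            eso_v_level = 50) {
  domain <- match.arg(domain)
  stopifnot(inherits(hybrid, "hybrid_plan_dose"))
  check_required(structures)
  dose <- if (domain == "physical") hybrid$summed_physical else hybrid$summed_eqd2
  pt <- get_structure(structures, "PTV_PT")
  ln <- get_structure(structures, "PTV_LN")
  union_mask <- structure_mask("PTV_PT+LN", pt$mask | ln$mask,
                               pt$spacing, pt$origin)
  lung_t <- get_structure(structures, "lung_total")
  lung_i <- get_structure(structures, "lung_ipsi")
  heart <- get_structure(structures, "heart")
  eso <- get_structure(structures, "esophagus")
  cord <- get_structure(structures, "spinal_cord")

  data.frame(
    domain = domain,
    ptv_ln_ci60 = conformity_index(dose, ln, ci_ln_level),
    ptv_ptln_ci60 = conformity_index(dose, union_mask, ci_union_level),
    ptv_pt_ci140 = if (domain == "EQD2")
      conformity_index(dose, pt, ci_pt_level) else NA_real_,
    hi_ptv_ln = homogeneity_index(dose, ln),
    lung_total_v20 = v_at_dose(dose, lung_t, lung_v_level),
    lung_total_mld = mean(mask_doses(dose, lung_t)),
    lung_ipsi_v20 = v_at_dose(dose, lung_i, lung_v_level),
    lung_ipsi_mld = mean(mask_doses(dose, lung_i)),
    cord_dmax = max(mask_doses(dose, cord)),
    heart_d5 = d_at_volume(dose, heart, 5),
    heart_d30 = d_at_volume(dose, heart, 30),
    heart_dmax = max(mask_doses(dose, heart)),
    heart_mean = mean(mask_doses(dose, heart)),
    eso_dmax = max(mask_doses(dose, eso)),
    eso_v50 = v_at_dose(dose, eso, eso_v_level)
  )
}
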
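# Anatomical geometry features: volumes (cc), volume ratios, minimum 3D
# surface distances (cm), and signed cranio-caudal overlap thickness (cm)
# between target and organ structures.  Distances are computed in physical
# mm between voxel centres, then reported in cm.

#' Structure volume in cc
#' @param mask a [structure_mask()].
#' @return Volume in cc (voxel count x voxel volume).
#' @export
structure_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  n <- sum(mask$mask)
  if (n == 0) stop(sprintf("structure '%s' is empty", mask$name))
  n * voxel_volume_cc(mask)
}

#' Minimum 3D surface distance between two structures (cm)
#'
#' Minimum Euclidean distance in physical space between any voxel centre of
#' `A` and any voxel centre of `B`; 0 if the masks intersect.  Implemented
#' as the exact distance transform of `B` sampled at the voxels of `A`.
#'
#' @param A,B [structure_mask()] objects on a shared lattice.
#' @return Distance in cm.
#' @export
min_surface_distance <- function(A, B) {
  if (!same_lattice(A, B)) stop("lattice mismatch between structures")
  dB <- distance_to_mask(B)
  min(dB[A$mask]) / 10
}

#' Signed cranio-caudal overlap thickness (cm)
#'
#' The shared extent of the two structures' occupied cranio-caudal slabs,
#' measured between outer slice faces:
#' `min(z_sup(A), z_sup(B)) - max(z_inf(A), z_inf(B))`.  Negative when the
#' axial spans are disjoint (a cranio-caudal gap), as for a primary tumour
#' entirely above or below the nodal target.
#'
#' @param A,B [structure_mask()] objects on a shared lattice.
#' @return Signed thickness in cm.
#' @export
overlap_slices_thickness <- function(A, B) {
  if (!same_lattice(A, B)) stop("lattice mismatch between structures")
  zspan <- function(m) {
    occ <- which(apply(m$mask, 1, any))
    zc <- axis_coords(m, 1)[range(occ)]
    c(inf = zc[1] - m$spacing[1] / 2, sup = zc[2] + m$spacing[1] / 2)
  }
  a <- zspan(A); b <- zspan(B)
  (min(a["sup"], b["sup"]) - max(a["inf"], b["inf"])) / 10
}

#' Overlap volume ratio of two structures
#'
#' `volume(A intersect B) / volume(denominator)` where the denominator is
#' structure `A` or `B`.
#'
#' @param A,B [structure_mask()] objects on a shared lattice.
#' @param denominator `"A"` or `"B"`.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_volume_ratio <- function(A, B, denominator = c("B", "A")) {
  denominator <- match.arg(denominator)
  if (!same_lattice(A, B)) stop("lattice mismatch between structures")
  den <- if (denominator == "A") A else B
  nden <- sum(den$mask)
  if (nden == 0) stop("empty denominator structure")
  sum(A$mask & B$mask) / nden
}

#' Nodal target volume with neck components excluded (cc)
#'
#' Total volume of the mask minus the volume of connected components tagged
#' `"neck_node"`.  With no tagged components the full volume is returned.
#'
#' @param LN a [structure_mask()] with component labels/tags.
#' @return Volume in cc.
#' @export
corrected_ln_volume <- function(LN) {
  stopifnot(inherits(LN, "structure_mask"))
  vox <- sum(LN$mask)
  tags <- LN$component_tags
  if (!is.null(tags)) {
    neck_ids <- as.integer(names(tags)[tags == "neck_node"])
    if (length(neck_ids))
      vox <- vox - sum(LN$component_labels %in% neck_ids)
  }
  vox * voxel_volume_cc(LN)
}

# mask of LN with neck components removed (NULL if that empties it)
ln_without_neck <- function(LN) {
  tags <- LN$component_tags
  m <- LN$mask
  if (!is.null(tags)) {
    neck_ids <- as.integer(names(tags)[tags == "neck_node"])
    if (length(neck_ids)) m <- m & !(LN$component_labels %in% neck_ids)
  }
  if (!any(m)) return(NULL)
  structure_mask(paste0(LN$name, "_corrected"), m, LN$spacing, LN$origin)
}

#' Geometry feature names
#'
#' The canonical per-patient anatomy feature vector: target volumes (cc),
#' the neck-corrected nodal volume, minimum surface distances (cm), signed
#' cranio-caudal overlap thickness (cm), target-to-lung volume ratios, and
#' overlap-structure volume ratios for heart and esophagus.
#'
#' @return Character vector of feature names as produced by
#'   [extract_features()].
#' @export
geometry_feature_names <- function() {
  c("vol_pt", "vol_ln", "vol_ln_corrected",
    "min_dist_pt_ln", "overlap_thickness_pt_ln",
    "vol_ratio_ln_total_lung", "corr_vol_ratio_ln_total_lung",
    "vol_ratio_ln_ipsi_lung", "corr_vol_ratio_ln_ipsi_lung",
    "vol_ratio_pt_total_lung", "vol_ratio_pt_ipsi_lung",
    "min_dist_pt_eso", "overlap_ratio_eso_ln_to_eso",
    "min_dist_pt_heart", "overlap_ratio_heart_ln_to_heart",
    "overlap_ratio_heart_ln_to_ln")
}

#' Extract the anatomy feature vector from a structure set
#'
#' Computes the full geometry feature vector (see
#' [geometry_feature_names()]) from the seven required structures.
#' Volumes in cc, distances in cm, ratios dimensionless.  Corrected ratios
#' exclude neck-node components of the nodal target.
#'
#' @param structures a [structure_set()] containing the required structures.
#' @return A one-row `data.frame` of features.
#' @export
extract_features <- function(structures) {
  check_required(structures)
  with_name <- function(feature, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature '%s': %s", feature, conditionMessage(e)), call. = FALSE))
  }
  pt <- get_structure(structures, "PTV_PT")
  ln <- get_structure(structures, "PTV_LN")
  lung_t <- get_structure(structures, "lung_total")
  lung_i <- get_structure(structures, "lung_ipsi")
  heart <- get_structure(structures, "heart")
  eso <- get_structure(structures, "esophagus")

  vol_pt <- structure_volume(pt)
  vol_ln <- structure_volume(ln)
  vol_ln_corr <- with_name("vol_ln_corrected", corrected_ln_volume(ln))
  if (vol_ln_corr <= 0)
    stop("feature 'vol_ln_corrected': all nodal components tagged neck_node")
  vol_lung_t <- structure_volume(lung_t)
  vol_lung_i <- structure_volume(lung_i)

  data.frame(
    vol_pt = vol_pt,
    vol_ln = vol_ln,
    vol_ln_corrected = vol_ln_corr,
    min_dist_pt_ln = with_name("min_dist_pt_ln", min_surface_distance(pt, ln)),
    overlap_thickness_pt_ln =
      with_name("overlap_thickness_pt_ln", overlap_slices_thickness(pt, ln)),
    vol_ratio_ln_total_lung = vol_ln / vol_lung_t,
    corr_vol_ratio_ln_total_lung = vol_ln_corr / vol_lung_t,
    vol_ratio_ln_ipsi_lung = vol_ln / vol_lung_i,
    corr_vol_ratio_ln_ipsi_lung = vol_ln_corr / vol_lung_i,
    vol_ratio_pt_total_lung = vol_pt / vol_lung_t,
    vol_ratio_pt_ipsi_lung = vol_pt / vol_lung_i,
    min_dist_pt_eso = with_name("min_dist_pt_eso", min_surface_distance(pt, eso)),
    overlap_ratio_eso_ln_to_eso =
      with_name("overlap_ratio_eso_ln_to_eso",
                overlap_volume_ratio(eso, ln, denominator = "A")),
    min_dist_pt_heart =
      with_name("min_dist_pt_heart", min_surface_distance(pt, heart)),
    overlap_ratio_heart_ln_to_heart =
      with_name("overlap_ratio_heart_ln_to_heart",
                overlap_volume_ratio(heart, ln, denominator = "A")),
    overlap_ratio_heart_ln_to_ln =
      with_name("overlap_ratio_heart_ln_to_ln",
                overlap_volume_ratio(heart, ln, denominator = "B"))
  )
}
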
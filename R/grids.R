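# Volumetric data model shared by every stage: dose grids and structure
# masks live on a common axis-aligned lattice.  Axis order is fixed as
# (z, y, x) with z the cranio-caudal direction; spacing and origin are in
# mm and refer to voxel centres (voxel [1,1,1] sits at `origin`).

#' Create a 3D dose/scalar grid
#'
#' A `volume_grid` carries a 3D scalar array (dose in Gy) together with its
#' lattice geometry.  Axis order is fixed: the first array dimension is the
#' cranio-caudal (z) axis, then y (anterior-posterior), then x (lateral).
#' `spacing` and `origin` are in mm; `origin` is the physical coordinate of
#' the centre of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array, finite, non-negative for dose.
#' @param spacing numeric length-3, voxel size in mm per (z, y, x) axis.
#' @param origin numeric length-3, mm coordinate of the first voxel centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d (z,y,x), spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_dim <- function(grid) dim(grid$values)

#' Voxel volume of a lattice in cc
#' @param grid a `volume_grid` or `structure_mask`.
#' @return Voxel volume in cc (1 cc = 1000 mm^3).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$values %||% a$mask), dim(b$values %||% b$mask)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# physical coordinates (mm) of voxel centres along one axis
axis_coords <- function(grid, axis) {
  n <- dim(grid$values %||% grid$mask)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Create a named binary structure mask
#'
#' Masks live on the same lattice convention as [volume_grid()].  Connected
#' components can be labelled (e.g. to tag a neck-node component of a nodal
#' target separately from the mediastinal component); label 0 is background.
#'
#' @param name structure label, e.g. `"PTV_LN"`.
#' @param mask 3D logical array.
#' @param spacing,origin lattice geometry in mm, as for [volume_grid()].
#' @param component_labels optional integer array of the same shape with
#'   0 outside `mask`; if `NULL` the mask is treated as one component.
#' @param component_tags named character vector mapping component id
#'   (as character) to a tag such as `"neck_node"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, spacing, origin = c(0, 0, 0),
                           component_labels = NULL, component_tags = NULL) {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (any(is.na(mask))) stop("mask must not contain NA")
  if (!any(mask)) stop(sprintf("structure '%s' is empty", name))
  if (is.null(component_labels)) {
    component_labels <- array(0L, dim(mask))
    component_labels[mask] <- 1L
  } else {
    component_labels <- as.array(component_labels)
    storage.mode(component_labels) <- "integer"
    if (!identical(dim(component_labels), dim(mask)))
      stop("component_labels shape must match mask")
    if (any(component_labels[!mask] != 0L) || any(component_labels[mask] == 0L))
      stop("component_labels must be nonzero exactly on the mask")
  }
  structure(list(name = name, mask = mask,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 component_labels = component_labels,
                 component_tags = component_tags),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.2f cc, %d component(s)\n",
              x$name, sum(x$mask), structure_volume(x),
              max(x$component_labels)))
  invisible(x)
}

#' Bundle structure masks that share one lattice
#'
#' The hybrid-plan analysis requires masks named `PTV_PT`, `PTV_LN`,
#' `lung_total`, `lung_ipsi`, `heart`, `esophagus` and `spinal_cord`;
#' partial sets are allowed for lower-level operations.
#'
#' @param structures named list of [structure_mask()] objects on one lattice.
#' @param laterality `"right"` or `"left"`: which lung is ipsilateral to the
#'   primary tumour.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (length(structures) == 0) stop("empty structure set")
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be a named list")
  ref <- structures[[1]]
  for (s in structures) {
    if (!inherits(s, "structure_mask")) stop("all elements must be structure_mask")
    if (!same_lattice(ref, s)) stop("all masks must share one lattice")
  }
  structure(list(structures = structures, laterality = laterality,
                 spacing = ref$spacing, origin = ref$origin),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures (%s), ipsilateral lung: %s\n",
              length(x$structures), paste(names(x$structures), collapse = ", "),
              x$laterality))
  invisible(x)
}

REQUIRED_STRUCTURES <- c("PTV_PT", "PTV_LN", "lung_total", "lung_ipsi",
                         "heart", "esophagus", "spinal_cord")

get_structure <- function(set, name) {
  s <- set$structures[[name]]
  if (is.null(s)) stop(sprintf("missing required structure '%s'", name))
  s
}

check_required <- function(set, required = REQUIRED_STRUCTURES) {
  missing <- setdiff(required, names(set$structures))
  if (length(missing))
    stop(sprintf("missing required structure(s): %s",
                 paste(missing, collapse = ", ")))
  invisible(set)
}

# ---- NIfTI I/O -------------------------------------------------------------
# Internal (z,y,x) arrays are stored on disk in conventional NIfTI (x,y,z)
# order; lattice geometry goes through the sform affine.

grid_to_nifti <- function(values, spacing, origin) {
  arr <- aperm(values, c(3, 2, 1))
  aff <- rbind(cbind(diag(rev(spacing)), rev(origin)), c(0, 0, 0, 1))
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

nifti_geometry <- function(img) {
  aff <- RNifti::xform(img)
  sp_xyz <- sqrt(colSums(aff[1:3, 1:3]^2))
  list(spacing = rev(sp_xyz), origin = rev(aff[1:3, 4]))
}

#' Write a dose grid to NIfTI
#' @param grid a [volume_grid()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_dose <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  RNifti::writeNifti(grid_to_nifti(grid$values, grid$spacing, grid$origin), path)
  invisible(path)
}

#' Read a dose grid
#'
#' @param path NIfTI file with dose in Gy.
#' @param source_format `"nifti"`.  DICOM RT-DOSE input is not available in
#'   this build; convert to NIfTI upstream.
#' @return A [volume_grid()].
#' @export
read_dose <- function(path, source_format = c("nifti", "dicom")) {
  source_format <- match.arg(source_format)
  if (source_format == "dicom")
    stop("DICOM RT-DOSE reading is not supported in this build; ",
         "convert to NIfTI (e.g. with plastimatch or pydicom) first")
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  vals <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  if (min(vals) < 0) stop("negative dose values: not a dose volume?")
  volume_grid(vals, geo$spacing, geo$origin)
}

#' Write a label volume for a structure set
#'
#' Labels are assigned in the order of `set$structures` (1, 2, ...); a JSON
#' sidecar (`<path>.json`) records the label-to-name mapping and laterality.
#' Overlapping masks are written with the later structure overwriting the
#' earlier one, so prefer this format for disjoint or priority-ordered sets.
#'
#' @param set a [structure_set()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(set, path) {
  stopifnot(inherits(set, "structure_set"))
  lab <- array(0L, dim(set$structures[[1]]$mask))
  for (i in seq_along(set$structures)) lab[set$structures[[i]]$mask] <- i
  RNifti::writeNifti(grid_to_nifti(lab, set$spacing, set$origin), path)
  sidecar <- list(labels = as.list(stats::setNames(seq_along(set$structures),
                                                   names(set$structures))),
                  laterality = set$laterality)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read structure masks from a label volume
#'
#' @param path NIfTI label volume.  Label-to-name mapping is taken from
#'   `mapping` or, if `NULL`, from the JSON sidecar written by
#'   [write_structures()].
#' @param source_format `"nifti"` (label volume + mapping) or `"dicom"`
#'   (not available in this build).
#' @param mapping named integer vector, names = structure names,
#'   values = labels.
#' @param laterality overrides the sidecar laterality.
#' @param required character vector of structure names that must be present
#'   (default: the names in the mapping).
#' @return A [structure_set()].
#' @export
read_structures <- function(path, source_format = c("nifti", "dicom"),
                            mapping = NULL, laterality = NULL,
                            required = NULL) {
  source_format <- match.arg(source_format)
  if (source_format == "dicom")
    stop("DICOM RT-STRUCT reading is not supported in this build; ",
         "rasterize contours with rasterize_contours() or convert to NIfTI")
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(mapping)) {
    sidecar_path <- paste0(path, ".json")
    if (!file.exists(sidecar_path))
      stop("no mapping given and no JSON sidecar found")
    sidecar <- jsonlite::read_json(sidecar_path)
    mapping <- unlist(sidecar$labels)
    if (is.null(laterality)) laterality <- sidecar$laterality
  }
  if (is.null(laterality)) laterality <- "right"
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  lab <- aperm(array(as.integer(img), dim(img)), c(3, 2, 1))
  structures <- list()
  for (nm in names(mapping)) {
    m <- lab == mapping[[nm]]
    if (!any(m)) stop(sprintf("missing required structure '%s' (label %d empty)",
                              nm, mapping[[nm]]))
    structures[[nm]] <- structure_mask(nm, m, geo$spacing, geo$origin)
  }
  set <- structure_set(structures, laterality)
  if (!is.null(required)) check_required(set, required)
  set
}

# ---- contour rasterization -------------------------------------------------

# even-odd point-in-polygon test, vectorized over query points
point_in_polygon <- function(px, py, poly_x, poly_y) {
  inside <- rep(FALSE, length(px))
  n <- length(poly_x)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a reference lattice
#'
#' Converts planning-system style axial contours (closed polygons on z
#' planes, the geometry carried by DICOM RT-STRUCT) into a binary mask on
#' the lattice of `reference`.  A voxel is inside if its centre falls inside
#' an odd number of polygon edges on the nearest contour plane (even-odd
#' rule); contour planes are matched to slices within half a slice spacing.
#'
#' @param name structure name.
#' @param contours list of contours, each `list(z = <mm>, xy = <n x 2 matrix
#'   of (x, y) mm vertices>)`.
#' @param reference a [volume_grid()] or [structure_mask()] defining the
#'   output lattice.
#' @return A [structure_mask()].
#' @export
rasterize_contours <- function(name, contours, reference) {
  dims <- dim(reference$values %||% reference$mask)
  zc <- axis_coords(reference, 1)
  yc <- axis_coords(reference, 2)
  xc <- axis_coords(reference, 3)
  py <- rep(yc, times = length(xc))
  px <- rep(xc, each = length(yc))
  mask <- array(FALSE, dims)
  dz <- reference$spacing[1]
  for (ct in contours) {
    iz <- which(abs(zc - ct$z) <= dz / 2 + 1e-9)
    if (!length(iz)) next
    iz <- iz[which.min(abs(zc[iz] - ct$z))]
    inside <- point_in_polygon(px, py, ct$xy[, 1], ct$xy[, 2])
    plane <- matrix(inside, nrow = length(yc))
    mask[iz, , ] <- mask[iz, , ] | plane
  }
  if (!any(mask)) stop(sprintf("contours of '%s' rasterized to an empty mask", name))
  structure_mask(name, mask, reference$spacing, reference$origin)
}

# ---- resampling ------------------------------------------------------------

#' Resample a grid onto a reference lattice
#'
#' Trilinear interpolation for dose (preserves smooth fields exactly when
#' affine in space), nearest neighbour for masks (preserves binarity).
#' Target voxels whose centres fall outside the source extent get 0.
#'
#' @param grid a [volume_grid()] to resample.
#' @param reference a [volume_grid()] (or mask) whose lattice defines the
#'   output.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A [volume_grid()] on the reference lattice.
#' @export
resample_to <- function(grid, reference, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "volume_grid"))
  if (any(reference$spacing <= 0) || any(!is.finite(reference$spacing)))
    stop("degenerate reference spacing")
  if (same_lattice(grid, reference)) return(grid)
  src_dim <- dim(grid$values)
  ref_dim <- dim(reference$values %||% reference$mask)
  # fractional source index (1-based) of each reference voxel centre, per axis
  fi <- lapply(1:3, function(a)
    (reference$origin[a] + (seq_len(ref_dim[a]) - 1) * reference$spacing[a] -
       grid$origin[a]) / grid$spacing[a] + 1)
  F1 <- array(rep(fi[[1]], times = ref_dim[2] * ref_dim[3]), ref_dim)
  F2 <- array(rep(rep(fi[[2]], each = ref_dim[1]), times = ref_dim[3]), ref_dim)
  F3 <- array(rep(fi[[3]], each = ref_dim[1] * ref_dim[2]), ref_dim)
  out <- array(0, ref_dim)
  if (mode == "nearest") {
    r1 <- round(F1); r2 <- round(F2); r3 <- round(F3)
    ok <- r1 >= 1 & r1 <= src_dim[1] & r2 >= 1 & r2 <= src_dim[2] &
      r3 >= 1 & r3 <= src_dim[3]
    idx <- (r3[ok] - 1) * src_dim[1] * src_dim[2] + (r2[ok] - 1) * src_dim[1] + r1[ok]
    out[ok] <- grid$values[idx]
  } else {
    ok <- F1 >= 1 & F1 <= src_dim[1] & F2 >= 1 & F2 <= src_dim[2] &
      F3 >= 1 & F3 <= src_dim[3]
    f1 <- F1[ok]; f2 <- F2[ok]; f3 <- F3[ok]
    i1 <- pmin(floor(f1), src_dim[1] - 1); i1 <- pmax(i1, 1)
    i2 <- pmin(floor(f2), src_dim[2] - 1); i2 <- pmax(i2, 1)
    i3 <- pmin(floor(f3), src_dim[3] - 1); i3 <- pmax(i3, 1)
    w1 <- f1 - i1; w2 <- f2 - i2; w3 <- f3 - i3
    n12 <- src_dim[1] * src_dim[2]
    at <- function(a, b, c) grid$values[(c - 1) * n12 + (b - 1) * src_dim[1] + a]
    val <- (1 - w1) * (1 - w2) * (1 - w3) * at(i1, i2, i3) +
      w1 * (1 - w2) * (1 - w3) * at(i1 + 1, i2, i3) +
      (1 - w1) * w2 * (1 - w3) * at(i1, i2 + 1, i3) +
      (1 - w1) * (1 - w2) * w3 * at(i1, i2, i3 + 1) +
      w1 * w2 * (1 - w3) * at(i1 + 1, i2 + 1, i3) +
      w1 * (1 - w2) * w3 * at(i1 + 1, i2, i3 + 1) +
      (1 - w1) * w2 * w3 * at(i1, i2 + 1, i3 + 1) +
      w1 * w2 * w3 * at(i1 + 1, i2 + 1, i3 + 1)
    out[ok] <- val
  }
  volume_grid(out, reference$spacing, reference$origin)
}

# ---- distance transforms ---------------------------------------------------

#' Euclidean distance to a mask (mm)
#'
#' Exact anisotropic 3D Euclidean distance from every voxel centre to the
#' nearest voxel centre of `mask` (0 on the mask itself).
#'
#' @param mask a [structure_mask()] or logical array.
#' @param spacing required when `mask` is a bare array.
#' @return 3D numeric array of distances in mm (`Inf` if the mask is empty).
#' @export
distance_to_mask <- function(mask, spacing = NULL) {
  if (inherits(mask, "structure_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("spacing required for a bare array")
  d2 <- .edt3d_sq(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
  d2[d2 >= 1e14] <- Inf
  array(sqrt(d2), dim(mask))
}

#' Signed distance to a mask surface (mm)
#'
#' Negative inside the mask, positive outside, computed as distance to the
#' mask minus distance to its complement (voxel-centre metric, so the
#' magnitude at the boundary is one voxel rather than zero).
#'
#' @inheritParams distance_to_mask
#' @return 3D numeric array in mm.
#' @export
signed_surface_distance <- function(mask, spacing = NULL) {
  if (inherits(mask, "structure_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  distance_to_mask(mask, spacing) - distance_to_mask(!mask, spacing)
}

# ---- connected components --------------------------------------------------

# 6-connectivity connected-component labelling by frontier dilation.
label_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  remaining <- mask
  next_lab <- 0L
  shift_or <- function(frontier) {
    out <- array(FALSE, dims)
    n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
    out[-1, , ] <- out[-1, , ] | frontier[-n1, , ]
    out[-n1, , ] <- out[-n1, , ] | frontier[-1, , ]
    out[, -1, ] <- out[, -1, ] | frontier[, -n2, ]
    out[, -n2, ] <- out[, -n2, ] | frontier[, -1, ]
    out[, , -1] <- out[, , -1] | frontier[, , -n3]
    out[, , -n3] <- out[, , -n3] | frontier[, , -1]
    out
  }
  while (any(remaining)) {
    next_lab <- next_lab + 1L
    seed <- which(remaining)[1]
    comp <- array(FALSE, dims)
    comp[seed] <- TRUE
    frontier <- comp
    repeat {
      grown <- shift_or(frontier) & remaining & !comp
      if (!any(grown)) break
      comp <- comp | grown
      frontier <- grown
    }
    lab[comp] <- next_lab
    remaining <- remaining & !comp
  }
  lab
}
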
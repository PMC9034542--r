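#' Read a CT volume from NIfTI
#'
#' Geometry (spacing, origin) is taken from the NIfTI header; if the file
#' stores integers with a scale slope/intercept, RNifti applies them, so
#' voxel values arrive in HU. The internal axis order is the NIfTI order
#' (x, y, z) with z axial.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [ct_volume()].
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  geom <- nifti_geometry(img)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = geom$spacing, origin = geom$origin)
}

#' Write a CT volume (or any scalar volume) to NIfTI
#'
#' @param volume a [ct_volume()] or [dose_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  sp <- volume$spacing
  or <- volume$origin
  # xform: scaling by spacing, translation to first-voxel center
  m <- rbind(cbind(diag(sp), or), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_geometry <- function(img) {
  x <- RNifti::xform(img)
  # spacing from the column norms; origin from the translation column.
  sp <- sqrt(colSums(x[1:3, 1:3]^2))
  if (any(sp <= 0)) sp <- RNifti::pixdim(img)[1:3]
  list(spacing = as.numeric(sp), origin = as.numeric(x[1:3, 4]))
}

#' Read a dose grid
#'
#' @param path NIfTI file of absorbed dose.
#' @param scale dose-grid scaling applied on read (stored value × `scale` =
#'   Gy); formats that store scaled integers (e.g. scaling 0.001 with stored
#'   40000 meaning 40 Gy) are handled by passing their scaling factor.
#' @return a [dose_grid()].
#' @export
read_dose <- function(path, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  geom <- nifti_geometry(img)
  vox <- array(as.numeric(img) * scale, dim = dim(img))
  if (any(vox < 0)) stop("negative dose encountered on read")
  dose_grid(vox, spacing = geom$spacing, origin = geom$origin)
}

#' Write a dose grid to NIfTI
#' @param dose a [dose_grid()].
#' @param path output path.
#' @export
write_dose <- function(dose, path) write_ct(dose, path)

#' Read a set of structure masks
#'
#' Two sources are supported: per-structure binary mask volumes (NIfTI, one
#' file per structure, named by the list names), or planar contour tables
#' (data frames with columns `slice`, `x`, `y`, `ring`) rasterized onto the
#' reference grid with the voxel-center even-odd rule (see
#' [rasterize_polygons()]). Mask volumes whose grid differs from the
#' reference are resampled nearest-neighbor; masks already on the reference
#' grid are returned untouched.
#'
#' @param x named list: paths to NIfTI mask files, or contour data frames.
#' @param reference a [ct_volume()] defining the target grid.
#' @param name_map optional named character vector translating input labels
#'   to canonical structure names.
#' @return named list of [structure_mask()] objects.
#' @export
read_structures <- function(x, reference, name_map = NULL) {
  stopifnot(inherits(reference, "ct_volume"))
  out <- list()
  for (nm in names(x)) {
    canon <- if (!is.null(name_map) && nm %in% names(name_map))
      unname(name_map[[nm]]) else nm
    item <- x[[nm]]
    if (is.character(item)) {
      v <- read_ct(item)
      m <- mask_onto_grid(v, reference)
    } else if (is.data.frame(item)) {
      m <- rasterize_polygons(item, reference)$mask
    } else {
      stop("unsupported structure source for '", nm, "'")
    }
    out[[canon]] <- structure_mask(canon, m, reference$spacing,
                                   reference$origin)
  }
  out
}

# Nearest-neighbor resample of a mask volume onto the reference grid;
# identity when grids already match.
mask_onto_grid <- function(maskvol, reference) {
  if (same_grid(maskvol, reference)) return(maskvol$voxels > 0.5)
  cc <- voxel_centers(reference)
  src <- grid_of(maskvol)
  ix <- round((cc$x - src$origin[1]) / src$spacing[1]) + 1
  iy <- round((cc$y - src$origin[2]) / src$spacing[2]) + 1
  iz <- round((cc$z - src$origin[3]) / src$spacing[3]) + 1
  inx <- ix >= 1 & ix <= src$dim[1]
  iny <- iy >= 1 & iy <= src$dim[2]
  inz <- iz >= 1 & iz <= src$dim[3]
  d <- dim(reference$voxels)
  out <- array(FALSE, d)
  ix <- pmin(pmax(ix, 1), src$dim[1])
  iy <- pmin(pmax(iy, 1), src$dim[2])
  iz <- pmin(pmax(iz, 1), src$dim[3])
  vals <- maskvol$voxels[cbind(rep(ix, times = d[2] * d[3]),
                               rep(rep(iy, each = d[1]), times = d[3]),
                               rep(iz, each = d[1] * d[2]))] > 0.5
  inside <- rep(inx, times = d[2] * d[3]) &
    rep(rep(iny, each = d[1]), times = d[3]) &
    rep(inz, each = d[1] * d[2])
  out[inside & vals] <- TRUE
  out
}

#' Write structure masks as NIfTI volumes
#'
#' @param structures named list of [structure_mask()].
#' @param dir output directory; one `<name>.nii.gz` per structure.
#' @export
write_structures <- function(structures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in structures) {
    v <- ct_volume(array(as.numeric(s$mask), dim = dim(s$mask)),
                   s$spacing, s$origin)
    write_ct(v, file.path(dir, paste0(s$name, ".nii.gz")))
  }
  invisible(dir)
}

#' Embed a patch volume into a base volume
#'
#' Replaces the half-open box `[roi_origin, roi_origin + dim(patch))` of
#' `base` with `patch`; every voxel outside the box is bit-identical to
#' `base`. Used to restore a generated ROI into the surrounding NCT.
#'
#' @param base,patch [ct_volume()] objects.
#' @param roi_origin integer voxel triple (1-based) of the patch's first
#'   voxel inside `base`.
#' @return a [ct_volume()] with the geometry of `base`.
#' @export
embed_roi <- function(base, patch, roi_origin) {
  stopifnot(inherits(base, "ct_volume"), inherits(patch, "ct_volume"))
  roi_origin <- as.integer(roi_origin)
  pd <- dim(patch$voxels)
  bd <- dim(base$voxels)
  if (any(roi_origin < 1L) || any(roi_origin + pd - 1L > bd))
    stop("patch overruns base extent")
  out <- base$voxels
  out[roi_origin[1]:(roi_origin[1] + pd[1] - 1L),
      roi_origin[2]:(roi_origin[2] + pd[2] - 1L),
      roi_origin[3]:(roi_origin[3] + pd[3] - 1L)] <- patch$voxels
  ct_volume(out, base$spacing, base$origin)
}
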
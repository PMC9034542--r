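#' 3D CT volume with grid geometry
#'
#' The package's canonical image container: a 3D numeric array of Hounsfield
#' units together with its grid geometry. Axis order is fixed to (x, y, z)
#' with z the axial (slice) axis; voxel indices are 1-based in R but the
#' world position of voxel (1,1,1) is `origin` (voxel centers).
#'
#' @param voxels 3D numeric array of intensities (HU for CT, Gy for dose).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel's
#'   center.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers")
  if (any(!is.finite(voxels))) stop("`voxels` must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

grid_of <- function(v) list(dim = dim(v$voxels), spacing = v$spacing,
                            origin = v$origin)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centers along each axis
#'
#' @param volume a [ct_volume()] (or `dose_grid`).
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @keywords internal
voxel_centers <- function(volume) {
  d <- dim(volume$voxels)
  list(x = volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1],
       y = volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2],
       z = volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3])
}

#' Co-registered non-contrast / contrast-enhanced pair
#'
#' Both members must share one grid exactly: pairs enter the pipeline already
#' registered (deformable registration is an upstream step outside this
#' package).
#'
#' @param nct,cect [ct_volume()] objects on an identical grid.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(nct, cect) {
  stopifnot(inherits(nct, "ct_volume"), inherits(cect, "ct_volume"))
  if (!same_grid(nct, cect))
    stop("NCT and CECT must share shape, spacing and origin (pre-registered)")
  structure(list(nct = nct, cect = cect), class = "paired_sample")
}

#' Named binary structure mask on a reference grid
#'
#' @param name structure label (one of the canonical cardiac names or any
#'   label).
#' @param mask 3D logical array matching the reference grid.
#' @param spacing,origin grid geometry, usually taken from the reference CT.
#' @return An object of class `structure_mask`. Empty masks are allowed and
#'   flagged via `attr(x, "empty")`.
#' @export
structure_mask <- function(name, mask, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  obj <- structure(list(name = as.character(name), mask = mask,
                        spacing = as.numeric(spacing),
                        origin = as.numeric(origin)),
                   class = "structure_mask")
  attr(obj, "empty") <- !any(mask)
  obj
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels true (%.2f cc)%s\n",
              x$name, sum(x$mask),
              sum(x$mask) * prod(x$spacing) / 1000,
              if (isTRUE(attr(x, "empty"))) " [empty]" else ""))
  invisible(x)
}

#' 3D absorbed-dose grid in Gy
#'
#' @param voxels 3D numeric array of dose (Gy, non-negative).
#' @param spacing,origin grid geometry in mm.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (any(!is.finite(voxels))) stop("dose must be finite")
  if (any(voxels < 0)) stop("dose must be non-negative")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, max %.3g Gy, mean %.3g Gy\n",
              d[1], d[2], d[3], max(x$voxels), mean(x$voxels)))
  invisible(x)
}

#' Apply a stored-value rescale (slope/intercept)
#'
#' CT formats store integers that map to HU through
#' `HU = slope * stored + intercept` (e.g. slope 1, intercept -1024).
#' Readers of such formats apply this before constructing a [ct_volume()].
#'
#' @param stored numeric array of stored values.
#' @param slope,intercept rescale parameters.
#' @return numeric array of HU.
#' @export
apply_rescale <- function(stored, slope = 1, intercept = 0) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("rescale slope/intercept must be finite")
  slope * stored + intercept
}
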
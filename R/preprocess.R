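#' Preprocessing configuration
#'
#' Defaults follow the clinical pipeline: resampling to 0.9 x 0.9 x 1.0 mm,
#' a heart-centred ROI of 384 x 384 x 150 voxels, a fixed contrast window of
#' [-150, 500] HU, 352 x 352 random training crops, and a model intensity
#' range of [-1, 1].
#'
#' @param target_spacing mm triple for resampling.
#' @param roi_size voxel triple of the heart ROI crop.
#' @param window HU pair (low, high) for the contrast window.
#' @param train_crop in-plane random-crop size used during training only.
#' @param normalized_range intensity pair the window maps onto.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(0.9, 0.9, 1.0),
                              roi_size = c(384L, 384L, 150L),
                              window = c(-150, 500),
                              train_crop = 352L,
                              normalized_range = c(-1, 1)) {
  if (window[1] >= window[2]) stop("window low must be < high")
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  if (train_crop > min(roi_size[1:2]))
    stop("train_crop must not exceed the in-plane ROI size")
  structure(list(target_spacing = as.numeric(target_spacing),
                 roi_size = as.integer(roi_size),
                 window = as.numeric(window),
                 train_crop = as.integer(train_crop),
                 normalized_range = as.numeric(normalized_range)),
            class = "preprocess_config")
}

#' Trilinear resampling to a target spacing
#'
#' Output shape is `round(extent / target_spacing)`; the origin stays at the
#' first-voxel center. Values are trilinearly interpolated; constants are
#' preserved exactly, and sampling beyond the last voxel center clamps to
#' the edge.
#'
#' @param volume a [ct_volume()] or [dose_grid()].
#' @param target_spacing mm triple (> 0).
#' @return resampled volume of the same class.
#' @export
resample_volume <- function(volume, target_spacing) {
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  d <- dim(volume$voxels)
  extent <- d * volume$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  if (identical(nd, d) && all(abs(target_spacing - volume$spacing) < 1e-12))
    return(volume)
  # continuous source indices (0-based) of the new voxel centers
  gi <- lapply(1:3, function(a) {
    (seq_len(nd[a]) - 1) * target_spacing[a] / volume$spacing[a]
  })
  vals <- trilinear_sample(volume$voxels, gi[[1]], gi[[2]], gi[[3]])
  out <- array(vals, dim = nd)
  if (inherits(volume, "dose_grid"))
    dose_grid(pmax(out, 0), target_spacing, volume$origin)
  else ct_volume(out, target_spacing, volume$origin)
}

# Sample `vox` at the grid outer product of continuous 0-based indices
# (gx, gy, gz), trilinear with edge clamping. Returns array
# length(gx) x length(gy) x length(gz).
trilinear_sample <- function(vox, gx, gy, gz) {
  d <- dim(vox)
  clamp <- function(g, n) pmin(pmax(g, 0), n - 1)
  gx <- clamp(gx, d[1]); gy <- clamp(gy, d[2]); gz <- clamp(gz, d[3])
  x0 <- pmin(floor(gx), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(gy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(gz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(gx))
  if (d[2] == 1) y0 <- rep(0, length(gy))
  if (d[3] == 1) z0 <- rep(0, length(gz))
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  nd <- c(length(gx), length(gy), length(gz))

  FX <- array(fx, nd); FY <- array(rep(fy, each = nd[1]), nd)
  FZ <- array(rep(fz, each = nd[1] * nd[2]), nd)
  gather <- function(dx, dy, dz) {
    ix <- pmin(x0 + dx, d[1] - 1) + 1
    iy <- pmin(y0 + dy, d[2] - 1) + 1
    iz <- pmin(z0 + dz, d[3] - 1) + 1
    array(vox[cbind(rep(ix, times = nd[2] * nd[3]),
                    rep(rep(iy, each = nd[1]), times = nd[3]),
                    rep(iz, each = nd[1] * nd[2]))], nd)
  }
  v000 <- gather(0, 0, 0); v100 <- gather(1, 0, 0)
  v010 <- gather(0, 1, 0); v110 <- gather(1, 1, 0)
  v001 <- gather(0, 0, 1); v101 <- gather(1, 0, 1)
  v011 <- gather(0, 1, 1); v111 <- gather(1, 1, 1)
  (v000 * (1 - FX) + v100 * FX) * (1 - FY) * (1 - FZ) +
    (v010 * (1 - FX) + v110 * FX) * FY * (1 - FZ) +
    (v001 * (1 - FX) + v101 * FX) * (1 - FY) * FZ +
    (v011 * (1 - FX) + v111 * FX) * FY * FZ
}

#' Crop a box around a center voxel, padding with the window floor
#'
#' The requested box is half-open of the given size, centred at `center`
#' (1-based voxel indices); parts hanging outside the source are padded with
#' `pad_value` (default the contrast-window lower bound, -150 HU). The
#' origin is updated so voxel positions remain correct.
#'
#' @param volume a [ct_volume()].
#' @param center integer voxel triple.
#' @param size integer voxel triple of the output box.
#' @param pad_value fill value for out-of-volume voxels.
#' @return cropped [ct_volume()] with attribute `roi_origin` (the 1-based
#'   index of the box's first voxel inside the source grid, possibly <= 0).
#' @export
crop_roi <- function(volume, center, size, pad_value = -150) {
  center <- as.integer(round(center)); size <- as.integer(size)
  d <- dim(volume$voxels)
  start <- center - size %/% 2L
  out <- array(pad_value, size)
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + size - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1L
    dst_hi <- src_hi - start + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      volume$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                    src_lo[3]:src_hi[3]]
  }
  v <- ct_volume(out, volume$spacing,
                 volume$origin + (start - 1L) * volume$spacing)
  attr(v, "roi_origin") <- start
  v
}

#' Window and normalize HU to the model range
#'
#' Clips to the contrast window and maps it affinely onto the normalized
#' model range; the mapping is monotone and exactly invertible on the
#' clipped range (see [denormalize_hu()]).
#'
#' @param x a [ct_volume()] or plain numeric array of HU.
#' @param config a [preprocess_config()].
#' @return object of the same kind, on the normalized scale.
#' @export
window_normalize <- function(x, config = preprocess_config()) {
  w <- config$window; r <- config$normalized_range
  f <- function(v) {
    v <- pmin(pmax(v, w[1]), w[2])
    (v - w[1]) / (w[2] - w[1]) * (r[2] - r[1]) + r[1]
  }
  if (inherits(x, "ct_volume")) {
    out <- x; out$voxels <- array(f(x$voxels), dim = dim(x$voxels)); out
  } else {
    y <- f(x); if (!is.null(dim(x))) dim(y) <- dim(x); y
  }
}

#' Invert [window_normalize()] back to clipped HU
#' @param x normalized volume or array.
#' @param config the [preprocess_config()] used for normalization.
#' @export
denormalize_hu <- function(x, config = preprocess_config()) {
  w <- config$window; r <- config$normalized_range
  f <- function(v) (v - r[1]) / (r[2] - r[1]) * (w[2] - w[1]) + w[1]
  if (inherits(x, "ct_volume")) {
    out <- x; out$voxels <- array(f(x$voxels), dim = dim(x$voxels)); out
  } else {
    y <- f(x); if (!is.null(dim(x))) dim(y) <- dim(x); y
  }
}

#' Paired random crop of two slices
#'
#' Draws one offset uniformly over the valid positions and applies it to
#' both slices, preserving the pairing. Uses R's global RNG (seed upstream
#' for determinism).
#'
#' @param nct_slice,cect_slice matrices of identical shape.
#' @param crop integer crop size (square).
#' @return list `nct`, `cect` (cropped), `offset` (0-based).
#' @export
random_crop_pair <- function(nct_slice, cect_slice, crop) {
  if (!identical(dim(nct_slice), dim(cect_slice)))
    stop("paired slices must share shape")
  d <- dim(nct_slice); crop <- as.integer(crop)
  if (any(crop > d)) stop("crop larger than slice")
  ox <- if (d[1] == crop) 0L else sample.int(d[1] - crop + 1L, 1L) - 1L
  oy <- if (d[2] == crop) 0L else sample.int(d[2] - crop + 1L, 1L) - 1L
  list(nct = nct_slice[(ox + 1):(ox + crop), (oy + 1):(oy + crop)],
       cect = cect_slice[(ox + 1):(ox + crop), (oy + 1):(oy + crop)],
       offset = c(ox, oy))
}

#' Symmetrically pad a slice to a multiple of a stride
#'
#' The encoder halves resolution at each of its transitions, so inference
#' inputs must have sides divisible by 2^n_transitions; slices that do not
#' are padded with `pad_value` and cropped back after generation.
#'
#' @param slice matrix.
#' @param multiple required divisor of both sides.
#' @param pad_value fill value (normalized-scale floor, default -1).
#' @return list `slice` (padded), `trim` (function restoring the original
#'   shape from a generated slice).
#' @export
pad_to_multiple <- function(slice, multiple, pad_value = -1) {
  d <- dim(slice)
  nd <- as.integer(ceiling(d / multiple) * multiple)
  if (identical(nd, d))
    return(list(slice = slice, trim = function(s) s))
  lo <- (nd - d) %/% 2L
  out <- matrix(pad_value, nd[1], nd[2])
  out[(lo[1] + 1):(lo[1] + d[1]), (lo[2] + 1):(lo[2] + d[2])] <- slice
  list(slice = out,
       trim = function(s) s[(lo[1] + 1):(lo[1] + d[1]),
                            (lo[2] + 1):(lo[2] + d[2]), drop = FALSE])
}

#' Centroid of a structure mask, as voxel indices
#' @param mask a [structure_mask()] or logical array.
#' @return integer voxel triple (1-based), or `NULL` for an empty mask.
#' @export
mask_centroid <- function(mask) {
  m <- if (inherits(mask, "structure_mask")) mask$mask else mask
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  as.integer(round(colMeans(idx)))
}
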
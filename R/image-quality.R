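#' Image-quality metric configuration
#'
#' Metrics are computed on the clipped-HU scale by default, with `max_val`
#' (the maximum possible pixel value entering PSNR) equal to the contrast
#' window width, 650. SSIM uses an 11x11 Gaussian window (sigma 1.5) and
#' stabilizers c1 = (k1 L)^2, c2 = (k2 L)^2 with k1 = 0.01, k2 = 0.03 and
#' L = `max_val`, the reference defaults of the original SSIM formulation.
#' These scale choices are recorded in every report so results stay
#' interpretable.
#'
#' @param max_val maximum possible pixel value (PSNR's MAX and SSIM's L).
#' @param window HU clipping window applied when `evaluation_scale =
#'   "clipped_hu"`.
#' @param ssim_window odd window size for SSIM local statistics.
#' @param ssim_sigma Gaussian sigma of the SSIM window.
#' @param k1,k2 SSIM stabilizer coefficients.
#' @param evaluation_scale `"clipped_hu"` (clip to `window` before
#'   computing) or `"normalized"` (use values as given).
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(max_val = 650, window = c(-150, 500),
                          ssim_window = 11L, ssim_sigma = 1.5,
                          k1 = 0.01, k2 = 0.03,
                          evaluation_scale = c("clipped_hu", "normalized")) {
  if (max_val <= 0) stop("`max_val` must be positive")
  if (ssim_window %% 2L == 0L) stop("`ssim_window` must be odd")
  structure(list(max_val = max_val, window = as.numeric(window),
                 ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma, k1 = k1, k2 = k2,
                 evaluation_scale = match.arg(evaluation_scale)),
            class = "metric_config")
}

metric_clip <- function(x, config) {
  if (config$evaluation_scale == "clipped_hu")
    pmin(pmax(x, config$window[1]), config$window[2])
  else x
}

#' Mean absolute error between two images
#' @param x,y numeric arrays of identical shape.
#' @return `mean(|y - x|)`.
#' @export
mae <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must share shape")
  mean(abs(y - x))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(max_val^2 / MSE)`. Identical images have zero MSE; the result
#' is then `Inf`, reported as a sentinel and excluded (with a count) from
#' cohort means rather than clamped.
#'
#' @param x,y numeric arrays of identical shape.
#' @param config a [metric_config()] supplying `max_val`.
#' @export
psnr <- function(x, y, config = metric_config()) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must share shape")
  mse <- mean((y - x)^2)
  if (mse == 0) return(Inf)
  10 * log10(config$max_val^2 / mse)
}

gaussian_kernel_1d <- function(size, sigma) {
  r <- (size - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable valid-mode filtering of a matrix with a 1D kernel.
filter_valid <- function(img, k) {
  n <- length(k)
  d <- dim(img)
  out <- matrix(0, d[1] - n + 1, d[2])
  for (i in seq_len(n))
    out <- out + k[i] * img[i:(d[1] - n + i), , drop = FALSE]
  out2 <- matrix(0, nrow(out), d[2] - n + 1)
  for (i in seq_len(n))
    out2 <- out2 + k[i] * out[, i:(d[2] - n + i), drop = FALSE]
  out2
}

#' Structural similarity index (mean SSIM)
#'
#' Local Gaussian-window means, variances and covariance combined as
#' `((2 mu_x mu_y + c1)(2 sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`,
#' averaged over all (valid) window positions. Result lies in \[-1, 1\].
#'
#' @param x,y numeric matrices of identical shape, at least the window
#'   size in each dimension.
#' @param config a [metric_config()].
#' @export
ssim <- function(x, y, config = metric_config()) {
  if (!identical(dim(x), dim(y))) stop("images must share shape")
  x <- metric_clip(x, config); y <- metric_clip(y, config)
  n <- config$ssim_window
  if (any(dim(x) < n)) stop("image smaller than the SSIM window")
  k <- gaussian_kernel_1d(n, config$ssim_sigma)
  mx <- filter_valid(x, k); my <- filter_valid(y, k)
  sxx <- filter_valid(x * x, k) - mx^2
  syy <- filter_valid(y * y, k) - my^2
  sxy <- filter_valid(x * y, k) - mx * my
  L <- config$max_val
  c1 <- (config$k1 * L)^2
  c2 <- (config$k2 * L)^2
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' Slice-wise cohort evaluation of SCECT against CECT
#'
#' Computes per-slice MAE, PSNR and SSIM for the two comparison arms —
#' SCECT vs CECT and NCT vs CECT — on the clipped-HU scale, aggregates
#' mean and SD per arm, and runs a two-sample t-test per metric between
#' the arms (unpaired, equal variance by default; Welch via
#' `welch = TRUE`). Infinite PSNR values (identical slices) are excluded
#' from the mean/SD and t-test with a reported count.
#'
#' @param triplets list of samples, each `list(nct, scect, cect)` of
#'   [ct_volume()]s (or 3D arrays) on one grid.
#' @param config a [metric_config()].
#' @param slices optional list (per triplet) of axial slice indices to
#'   evaluate; default all slices.
#' @param welch use the Welch t-test variant.
#' @return An object of class `cohort_metrics`: `per_slice` (data frame),
#'   `summary` (mean/SD per arm and metric), `tests` (t-test p-values),
#'   `psnr_inf_excluded`, `config`.
#' @export
evaluate_cohort <- function(triplets, config = metric_config(),
                            slices = NULL, welch = FALSE) {
  if (length(triplets) < 1L) stop("empty cohort")
  vox <- function(v) if (inherits(v, "ct_volume")) v$voxels else v
  nz <- vapply(seq_along(triplets), function(i) {
    if (is.null(slices)) dim(vox(triplets[[i]]$cect))[3]
    else length(slices[[i]])
  }, integer(1))
  ntot <- sum(nz)
  per_slice <- data.frame(sample = integer(ntot), slice = integer(ntot),
                          mae_scect = numeric(ntot), mae_nct = numeric(ntot),
                          psnr_scect = numeric(ntot),
                          psnr_nct = numeric(ntot),
                          ssim_scect = numeric(ntot),
                          ssim_nct = numeric(ntot))
  at <- 0L
  cfg0 <- config; cfg0$evaluation_scale <- "normalized"  # already clipped
  for (i in seq_along(triplets)) {
    tr <- triplets[[i]]
    nct <- metric_clip(vox(tr$nct), config)
    scect <- metric_clip(vox(tr$scect), config)
    cect <- metric_clip(vox(tr$cect), config)
    zs <- if (is.null(slices)) seq_len(dim(cect)[3]) else slices[[i]]
    for (z in zs) {
      a <- nct[, , z]; s <- scect[, , z]; cc <- cect[, , z]
      at <- at + 1L
      per_slice$sample[at] <- i
      per_slice$slice[at] <- z
      per_slice$mae_scect[at] <- mae(s, cc)
      per_slice$mae_nct[at] <- mae(a, cc)
      per_slice$psnr_scect[at] <- psnr(s, cc, cfg0)
      per_slice$psnr_nct[at] <- psnr(a, cc, cfg0)
      per_slice$ssim_scect[at] <- ssim(s, cc, cfg0)
      per_slice$ssim_nct[at] <- ssim(a, cc, cfg0)
    }
  }
  if (nrow(per_slice) < 2L) stop("need at least two evaluated slices")

  arms <- c(scect = "scect", nct = "nct")
  metrics <- c("mae", "psnr", "ssim")
  summ <- expand.grid(metric = metrics, arm = names(arms),
                      stringsAsFactors = FALSE)
  summ$mean <- NA_real_; summ$sd <- NA_real_; summ$n <- NA_integer_
  tests <- data.frame(metric = metrics, p_value = NA_real_)
  n_inf <- 0L
  for (m in metrics) {
    va <- per_slice[[paste0(m, "_scect")]]
    vb <- per_slice[[paste0(m, "_nct")]]
    if (m == "psnr") {
      n_inf <- sum(!is.finite(va)) + sum(!is.finite(vb))
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    }
    summ[summ$metric == m & summ$arm == "scect",
         c("mean", "sd", "n")] <- list(mean(va), stats::sd(va), length(va))
    summ[summ$metric == m & summ$arm == "nct",
         c("mean", "sd", "n")] <- list(mean(vb), stats::sd(vb), length(vb))
    tests$p_value[tests$metric == m] <-
      if (length(va) > 1 && length(vb) > 1 &&
          (stats::sd(va) > 0 || stats::sd(vb) > 0))
        stats::t.test(va, vb, var.equal = !welch)$p.value
      else NA_real_
  }
  structure(list(per_slice = per_slice, summary = summ, tests = tests,
                 psnr_inf_excluded = n_inf, config = config),
            class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf("Cohort image-quality evaluation (%d slices; scale: %s, MAX = %g)\n",
              nrow(x$per_slice), x$config$evaluation_scale,
              x$config$max_val))
  for (m in c("mae", "psnr", "ssim")) {
    a <- x$summary[x$summary$metric == m & x$summary$arm == "scect", ]
    b <- x$summary[x$summary$metric == m & x$summary$arm == "nct", ]
    p <- x$tests$p_value[x$tests$metric == m]
    cat(sprintf("  %-5s SCECT-CECT %8.4f +/- %.4f | NCT-CECT %8.4f +/- %.4f | p = %s\n",
                toupper(m), a$mean, a$sd, b$mean, b$sd,
                format.pval(p, digits = 3)))
  }
  if (x$psnr_inf_excluded > 0)
    cat(sprintf("  (%d infinite PSNR value(s) excluded)\n",
                x$psnr_inf_excluded))
  invisible(x)
}
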
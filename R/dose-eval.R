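#' Resample a dose grid onto a reference CT grid
#'
#' Trilinear interpolation at the reference voxel centers (world
#' coordinates). Voxels outside the dose grid's extent receive 0 Gy; if
#' any fall outside, a warning reports the coverage fraction. Zero spatial
#' overlap is an error.
#'
#' @param dose a [dose_grid()].
#' @param reference a [ct_volume()].
#' @return a [dose_grid()] on the reference grid.
#' @export
resample_dose_to_grid <- function(dose, reference) {
  stopifnot(inherits(dose, "dose_grid"), inherits(reference, "ct_volume"))
  if (same_grid(dose, reference)) {
    return(dose_grid(dose$voxels, reference$spacing, reference$origin))
  }
  cc <- voxel_centers(reference)
  gd <- dim(dose$voxels)
  gx <- (cc$x - dose$origin[1]) / dose$spacing[1]
  gy <- (cc$y - dose$origin[2]) / dose$spacing[2]
  gz <- (cc$z - dose$origin[3]) / dose$spacing[3]
  inx <- gx >= 0 & gx <= gd[1] - 1
  iny <- gy >= 0 & gy <= gd[2] - 1
  inz <- gz >= 0 & gz <= gd[3] - 1
  if (!any(inx) || !any(iny) || !any(inz))
    stop("dose grid and reference volume do not overlap (registration error)")
  vals <- trilinear_sample(dose$voxels, gx, gy, gz)
  d <- dim(reference$voxels)
  inside <- array(rep(inx, times = d[2] * d[3]) &
                    rep(rep(iny, each = d[1]), times = d[3]) &
                    rep(inz, each = d[1] * d[2]), d)
  vals[!inside] <- 0
  cov <- mean(inside)
  if (cov < 1)
    warning(sprintf("dose grid covers %.1f%% of the reference; outside set to 0 Gy",
                    100 * cov))
  dose_grid(array(pmax(vals, 0), d), reference$spacing, reference$origin)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Unweighted voxel counting (all voxels carry equal volume): the curve
#' gives the fraction of the structure's volume receiving at least each
#' dose level, evaluated on uniform bin edges. Starts at 1.0 at 0 Gy, is
#' monotone non-increasing, and reaches 0 beyond the maximum dose.
#'
#' @param mask a non-empty [structure_mask()] on the dose grid.
#' @param dose a [dose_grid()] sharing the mask's grid.
#' @param bin_width bin width in Gy (default 0.01).
#' @return An object of class `dvh_curve`: `dose` (Gy edges), `volume`
#'   (cumulative fraction), `structure`, `volume_cc`, `bin_width`.
#' @export
compute_dvh <- function(mask, dose, bin_width = 0.01) {
  stopifnot(inherits(mask, "structure_mask"), inherits(dose, "dose_grid"))
  if (!identical(dim(mask$mask), dim(dose$voxels)))
    stop("mask and dose must share a grid")
  dv <- dose$voxels[mask$mask]
  if (!length(dv)) stop("empty mask: DVH undefined")
  edges <- seq(0, (floor(max(dv) / bin_width) + 1) * bin_width,
               by = bin_width)
  # fraction receiving >= edge (inclusive threshold, small tolerance)
  sorted <- sort(dv)
  frac <- (length(dv) - findInterval(edges - 1e-9, sorted)) / length(dv)
  structure(list(dose = edges, volume = pmin(frac, 1),
                 structure = mask$name,
                 volume_cc = length(dv) * prod(mask$spacing) / 1000,
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %.2f cc, D_max within [%.3g, %.3g] Gy, %d bins\n",
              x$structure, x$volume_cc, max(x$dose[x$volume > 0]),
              max(x$dose), length(x$dose)))
  invisible(x)
}

#' Dose-volume metrics of a structure
#'
#' `d_max` is the maximum voxel dose (not a D0.03cc variant), `d_mean` the
#' arithmetic mean voxel dose, and `V_t` the percentage of voxels with
#' dose >= t (inclusive threshold), for each requested threshold.
#'
#' @param x numeric vector of structure voxel doses, or a `dvh_curve`.
#' @param thresholds thresholds in Gy (default 5, 10, 20, 30, 40).
#' @return An object of class `dose_metrics`: `d_max`, `d_mean` (Gy) and
#'   `v_at` (named percentage vector).
#' @export
dose_metrics <- function(x, thresholds = c(5, 10, 20, 30, 40)) {
  if (inherits(x, "dvh_curve")) {
    diffvol <- -diff(c(x$volume, 0))
    # bins represented at their midpoint: |d_mean - voxel mean| <= bw/2
    d_mean <- sum((x$dose + x$bin_width / 2) * diffvol)
    d_max <- max(x$dose[x$volume > 0])
    v_at <- vapply(thresholds, function(t) {
      i <- which(x$dose >= t - 1e-12)[1]
      if (is.na(i)) 0 else 100 * x$volume[i]
    }, numeric(1))
  } else {
    x <- as.numeric(x)
    if (!length(x)) stop("empty dose input")
    d_max <- max(x)
    d_mean <- mean(x)
    v_at <- vapply(thresholds, function(t) 100 * mean(x >= t), numeric(1))
  }
  names(v_at) <- sprintf("V%gGy", thresholds)
  structure(list(d_max = d_max, d_mean = d_mean, v_at = v_at,
                 thresholds = thresholds),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("D_max %.3f Gy, D_mean %.3f Gy | %s\n", x$d_max, x$d_mean,
              paste(sprintf("%s %.1f%%", names(x$v_at), x$v_at),
                    collapse = ", ")))
  invisible(x)
}

metrics_row <- function(m) {
  c(d_max = m$d_max, d_mean = m$d_mean, m$v_at)
}

#' Dosimetric comparison of two structure-set cohorts under one dose
#'
#' For each patient the same dose field is applied to both structure sets
#' (plan transfer; no re-optimization) and the absolute per-structure
#' differences |metric(A) - metric(B)| are computed for Dmax, Dmean and
#' each V threshold; the cohort mean and SD of those absolute differences
#' are reported per structure, together with a per-metric two-sample
#' t-test between the two cohorts' raw metric values.
#'
#' @param cohort_a,cohort_b for a single patient, named lists of
#'   [structure_mask()]s; for a cohort, lists of such per-patient lists.
#' @param doses a [dose_grid()] (single patient) or list of them, already
#'   resampled onto the structure grid (see [resample_dose_to_grid()]).
#' @param thresholds V-thresholds in Gy.
#' @return An object of class `dosimetry_comparison`: `differences`
#'   (per patient/structure/metric), `summary` (mean/SD of absolute
#'   differences), `tests`, `missing` (structures absent on one side).
#' @export
compare_dosimetry <- function(cohort_a, cohort_b, doses,
                              thresholds = c(5, 10, 20, 30, 40)) {
  single <- inherits(doses, "dose_grid")
  if (single) {
    cohort_a <- list(cohort_a); cohort_b <- list(cohort_b)
    doses <- list(doses)
  }
  stopifnot(length(cohort_a) == length(cohort_b),
            length(cohort_a) == length(doses))
  diffs <- list(); raw_a <- list(); raw_b <- list(); missing <- character(0)
  for (p in seq_along(doses)) {
    A <- cohort_a[[p]]; B <- cohort_b[[p]]; dz <- doses[[p]]
    common <- intersect(names(A), names(B))
    missing <- union(missing, union(setdiff(names(A), common),
                                    setdiff(names(B), common)))
    for (nm in common) {
      if (!any(A[[nm]]$mask) || !any(B[[nm]]$mask)) {
        missing <- union(missing, nm); next
      }
      ma <- metrics_row(dose_metrics(dz$voxels[A[[nm]]$mask], thresholds))
      mb <- metrics_row(dose_metrics(dz$voxels[B[[nm]]$mask], thresholds))
      diffs[[length(diffs) + 1L]] <-
        data.frame(patient = p, structure = nm, metric = names(ma),
                   value_a = unname(ma), value_b = unname(mb),
                   abs_diff = unname(abs(ma - mb)))
    }
  }
  if (!length(diffs)) stop("no comparable structures")
  dd <- do.call(rbind, diffs)
  summ <- stats::aggregate(abs_diff ~ structure + metric, dd,
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(structure = summ$structure, metric = summ$metric,
                     mean = summ$abs_diff[, "mean"],
                     sd = summ$abs_diff[, "sd"])
  tests <- do.call(rbind, lapply(unique(dd$metric), function(m) {
    va <- dd$value_a[dd$metric == m]; vb <- dd$value_b[dd$metric == m]
    p <- if (length(va) > 1 && (stats::sd(va) > 0 || stats::sd(vb) > 0))
      stats::t.test(va, vb, var.equal = TRUE)$p.value else NA_real_
    data.frame(metric = m, p_value = p)
  }))
  structure(list(differences = dd, summary = summ, tests = tests,
                 missing = missing, thresholds = thresholds),
            class = "dosimetry_comparison")
}

#' @export
print.dosimetry_comparison <- function(x, ...) {
  cat("Absolute dosimetric differences (same transferred dose, both sets)\n")
  wide <- stats::reshape(x$summary, idvar = "structure",
                         timevar = "metric", direction = "wide")
  print(wide, row.names = FALSE, digits = 3)
  if (length(x$missing))
    cat("  structures flagged missing:",
        paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Pointwise average of DVH curves
#'
#' @param curves list of `dvh_curve`s with one bin width; shorter curves
#'   are extended with zero volume to the longest dose axis.
#' @return a `dvh_curve` of the pointwise mean cumulative fractions.
#' @export
average_dvh <- function(curves) {
  stopifnot(length(curves) >= 1L)
  bw <- unique(vapply(curves, `[[`, numeric(1), "bin_width"))
  if (length(bw) != 1L) stop("curves must share one bin width")
  nmax <- max(vapply(curves, function(cv) length(cv$dose), integer(1)))
  edges <- seq(0, by = bw, length.out = nmax)
  vols <- vapply(curves, function(cv) {
    c(cv$volume, rep(0, nmax - length(cv$volume)))
  }, numeric(nmax))
  structure(list(dose = edges, volume = rowMeans(vols),
                 structure = "average",
                 volume_cc = mean(vapply(curves, `[[`, numeric(1),
                                         "volume_cc")),
                 bin_width = bw),
            class = "dvh_curve")
}

#' Plot one or more cumulative DVH curves
#' @param x a `dvh_curve`.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::lines()].
#' @export
plot.dvh_curve <- function(x, add = FALSE, ...) {
  if (!add)
    graphics::plot(x$dose, 100 * x$volume, type = "n", xlab = "Dose (Gy)",
                   ylab = "Volume (%)", ylim = c(0, 100),
                   main = "Cumulative dose-volume histogram")
  graphics::lines(x$dose, 100 * x$volume, ...)
  invisible(x)
}
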
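#' Configuration for the paired-CT cardiac phantom simulator
#'
#' The simulator emulates the statistical structure the translation pipeline
#' assumes: co-registered NCT/CECT pairs in HU on one grid, ground-truth
#' masks for the seven cardiac substructures (heart, left/right ventricle,
#' left/right atrium, LAD, RCA), and a known per-sample blood-pool
#' enhancement. Geometry is procedural and deterministic: an ellipsoidal
#' torso, two low-HU lungs, a four-chamber heart (ellipsoid split by two
#' curved septal surfaces, with a myocardial shell), two tube vessels on
#' deterministic surface splines, and a great-vessel stub.
#'
#' Tissue defaults are chosen so that windowing at [-150, 500] HU never
#' clips enhanced blood (45 + 150 + 50 = 245 HU at the jitter extreme).
#' The per-sample enhancement jitter (uniform on ± `enhancement_jitter`)
#' models protocol heterogeneity across contrast injections, so a trained
#' model must learn an averaged mapping.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 32).
#' @param spacing mm per axis.
#' @param body_hu,lung_hu,myocardium_hu,blood_hu baseline tissue intensities
#'   (HU).
#' @param enhancement_hu additive blood-pool enhancement (HU).
#' @param enhancement_jitter half-width of the uniform per-sample jitter on
#'   the enhancement (HU, >= 0).
#' @param noise_sigma Gaussian image-noise scale (HU, >= 0), independent
#'   between NCT and CECT.
#' @param vessel_radius coronary-vessel tube radius (mm).
#' @param n_samples number of samples the configuration describes.
#' @param seed integer seed; identical (config, seed, index) reproduces
#'   bit-identical samples.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(192L, 192L, 96L),
                           spacing = c(1, 1, 1.5),
                           body_hu = 40, lung_hu = -750,
                           myocardium_hu = 40, blood_hu = 45,
                           enhancement_hu = 150, enhancement_jitter = 50,
                           noise_sigma = 10, vessel_radius = 2.5,
                           n_samples = 8L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("grid too small to contain the heart model (all axes must be >= 32)")
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  if (enhancement_jitter < 0) stop("`enhancement_jitter` must be >= 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 body_hu = body_hu, lung_hu = lung_hu,
                 myocardium_hu = myocardium_hu, blood_hu = blood_hu,
                 enhancement_hu = enhancement_hu,
                 enhancement_jitter = enhancement_jitter,
                 noise_sigma = noise_sigma, vessel_radius = vessel_radius,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "phantom_config")
}

# Coordinate arrays (mm, voxel centers) for a grid.
coord_arrays <- function(d, spacing, origin = c(0, 0, 0)) {
  cx <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(d[3]) - 1) * spacing[3]
  list(X = array(cx, dim = d),
       Y = array(rep(cy, each = d[1]), dim = d),
       Z = array(rep(cz, each = d[1] * d[2]), dim = d),
       x = cx, y = cy, z = cz)
}

# Deterministic anatomy: all shapes are parameterized by the physical grid
# extent so the same anatomy (scaled) appears on any grid size.
phantom_geometry <- function(config) {
  d <- config$grid_shape
  sp <- config$spacing
  ext <- d * sp
  ctr <- (d - 1) * sp / 2
  co <- coord_arrays(d, sp)

  torso_ab <- c(0.45, 0.35) * ext[1:2]
  tz <- (co$Z - ctr[3]) / (0.5 * ext[3])
  tshrink <- sqrt(pmax(0.7, 1 - 0.3 * tz^2))
  torso <- ((co$X - ctr[1]) / (torso_ab[1] * tshrink))^2 +
    ((co$Y - ctr[2]) / (torso_ab[2] * tshrink))^2 <= 1

  lung_a <- c(0.16, 0.25, 0.42) * ext
  lungs <- array(FALSE, d)
  for (sgn in c(-1, 1)) {
    lc <- ctr + c(sgn * 0.24 * ext[1], 0.08 * ext[2], 0)
    lungs <- lungs | (((co$X - lc[1]) / lung_a[1])^2 +
                        ((co$Y - lc[2]) / lung_a[2])^2 +
                        ((co$Z - lc[3]) / lung_a[3])^2 <= 1)
  }

  hc <- ctr + c(0.08 * ext[1], -0.08 * ext[2], 0)
  ha <- c(0.17, 0.15, 0.22) * ext
  u <- (co$X - hc[1]) / ha[1]
  v <- (co$Y - hc[2]) / ha[2]
  w <- (co$Z - hc[3]) / ha[3]
  rho2 <- u^2 + v^2 + w^2
  heart <- rho2 <= 1
  interior <- rho2 <= 0.8^2
  myocardium <- heart & !interior

  # two curved septal surfaces partition the chamber interior
  f1 <- u + 0.25 * w^2 - 0.05      # > 0: patient-left chambers
  f2 <- 0.8 * w + 0.5 * v + 0.15 * u^2   # > 0: atria (superior/posterior)
  lv <- interior & f1 > 0 & f2 <= 0
  la <- interior & f1 > 0 & f2 > 0
  rv <- interior & f1 <= 0 & f2 <= 0
  ra <- interior & f1 <= 0 & f2 > 0

  lad <- vessel_mask(co, hc, ha, config$vessel_radius, curve = "lad")
  rca <- vessel_mask(co, hc, ha, config$vessel_radius, curve = "rca")

  # great-vessel stub: aortic-root cylinder rising from the heart base
  stub_r <- 0.35 * ha[1]
  stub <- ((co$X - hc[1])^2 + (co$Y - hc[2])^2 <= stub_r^2) &
    co$Z >= hc[3] + 0.5 * ha[3] & co$Z <= hc[3] + 1.3 * ha[3] & torso

  list(torso = torso, lungs = lungs, heart = heart,
       myocardium = myocardium, lv = lv, la = la, rv = rv, ra = ra,
       lad = lad, rca = rca, stub = stub,
       center = ctr, extent = ext, heart_center = hc, heart_axes = ha,
       torso_ab = torso_ab, coords = co)
}

# Tube around a deterministic spline on the heart-ellipsoid surface.
# LAD descends the anterior left-ventricular surface; the RCA runs in the
# right atrioventricular groove. Centerlines sampled every 0.5 mm.
vessel_mask <- function(co, hc, ha, radius, curve) {
  t <- seq(0, 1, length.out = 121)
  if (curve == "lad") {
    lambda <- 0.25 * pi + 0.55 * pi * t
    phi <- -1.25 + 0.55 * t
  } else {
    lambda <- pi / 2 - 0.25 + 0.5 * t
    phi <- pi + 0.55 - 1.1 * t
  }
  px <- hc[1] + ha[1] * sin(lambda) * cos(phi)
  py <- hc[2] + ha[2] * sin(lambda) * sin(phi)
  pz <- hc[3] + ha[3] * cos(lambda)

  d <- dim(co$X)
  mask <- array(FALSE, d)
  ix <- which(co$x >= min(px) - radius & co$x <= max(px) + radius)
  iy <- which(co$y >= min(py) - radius & co$y <= max(py) + radius)
  iz <- which(co$z >= min(pz) - radius & co$z <= max(pz) + radius)
  if (!length(ix) || !length(iy) || !length(iz)) return(mask)
  bb <- expand.grid(x = co$x[ix], y = co$y[iy], z = co$z[iz])
  mind <- rep(Inf, nrow(bb))
  for (k in seq_along(px)) {
    dk <- (bb$x - px[k])^2 + (bb$y - py[k])^2 + (bb$z - pz[k])^2
    mind <- pmin(mind, dk)
  }
  sub <- array(mind <= radius^2, dim = c(length(ix), length(iy), length(iz)))
  mask[ix, iy, iz] <- sub
  mask
}

#' Simulate one co-registered NCT/CECT phantom pair
#'
#' The NCT is the deterministic tissue template plus Gaussian noise; the
#' CECT is the same template plus the per-sample blood-pool enhancement
#' (`enhancement_hu` jittered uniformly on +/- `enhancement_jitter`) plus
#' independent noise. The applied per-voxel enhancement is returned as
#' ground truth (`truth_enhancement`), zero outside blood-pool voxels.
#'
#' @param config a [phantom_config()].
#' @param index sample index, 1-based, `<= n_samples`.
#' @return An object of class `phantom_sample`: `pair` ([paired_sample()]),
#'   `structures` (named list of the seven [structure_mask()]s),
#'   `blood_pool` (logical array), `truth_enhancement` (HU array),
#'   `applied_enhancement` (scalar HU), `config`, `index`.
#' @export
simulate_pair <- function(config, index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  index <- as.integer(index)
  if (index < 1L || index > config$n_samples)
    stop("`index` must be in 1..n_samples")
  geo <- phantom_geometry(config)
  d <- config$grid_shape

  template <- array(-1000, d)
  template[geo$torso] <- config$body_hu
  blood_pool <- geo$lv | geo$la | geo$rv | geo$ra | geo$lad | geo$rca |
    geo$stub
  lung_vis <- geo$lungs & !geo$heart & !blood_pool
  template[lung_vis] <- config$lung_hu
  template[geo$myocardium] <- config$myocardium_hu
  template[blood_pool] <- config$blood_hu

  seed_i <- (abs(config$seed) + 7919L * index) %% 2147483647L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed_i)

  e <- config$enhancement_hu +
    if (config$enhancement_jitter > 0)
      stats::runif(1, -config$enhancement_jitter, config$enhancement_jitter)
    else 0
  truth <- array(0, d)
  truth[blood_pool] <- e

  n <- prod(d)
  noise1 <- if (config$noise_sigma > 0)
    array(stats::rnorm(n, 0, config$noise_sigma), d) else 0
  noise2 <- if (config$noise_sigma > 0)
    array(stats::rnorm(n, 0, config$noise_sigma), d) else 0

  nct <- ct_volume(template + noise1, config$spacing)
  cect <- ct_volume(template + truth + noise2, config$spacing)

  sm <- function(name, m) structure_mask(name, m, config$spacing, c(0, 0, 0))
  structures <- list(heart = sm("heart", geo$heart),
                     lv = sm("lv", geo$lv), la = sm("la", geo$la),
                     rv = sm("rv", geo$rv), ra = sm("ra", geo$ra),
                     lad = sm("lad", geo$lad), rca = sm("rca", geo$rca))

  structure(list(pair = paired_sample(nct, cect), structures = structures,
                 blood_pool = blood_pool, truth_enhancement = truth,
                 applied_enhancement = e, config = config, index = index,
                 geometry = geo[c("center", "extent", "heart_center",
                                  "heart_axes", "torso_ab")]),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> index %d: grid %s, enhancement %.1f HU, %d blood-pool voxels\n",
              x$index, paste(dim(x$pair$nct$voxels), collapse = "x"),
              x$applied_enhancement, sum(x$blood_pool)))
  invisible(x)
}

#' Simulate a cohort of phantom samples
#'
#' @param config a [phantom_config()].
#' @param n number of samples (default `config$n_samples`).
#' @return list of [simulate_pair()] results.
#' @export
simulate_cohort <- function(config, n = config$n_samples) {
  lapply(seq_len(n), function(i) simulate_pair(config, i))
}

#' Simulate a tangential-field dose grid for a phantom
#'
#' A tangential wedge over the chest wall of the given side receives the
#' prescription; outside the field the dose decays exponentially with the
#' lateral distance from the field edge (configurable falloff length). This
#' emulates the steep lateral falloff of tangential breast fields; it is an
#' emulation, not a beam-model calculation. Under the default left-sided
#' geometry the whole-heart mean dose stays below 5 Gy, consistent with
#' tangential plans prescribed 40 Gy in 15 fractions.
#'
#' @param sample a [simulate_pair()] result.
#' @param laterality `"left"`, `"right"`, or `"bilateral"`.
#' @param prescription prescription dose (Gy) delivered inside the field.
#' @param falloff exponential falloff length (mm); `0` gives a hard-edged
#'   field (prescription inside, zero outside).
#' @param wedge_depth_frac fraction of the torso's lateral half-extent that
#'   the field chord cuts into the chest (default 0.2).
#' @return a [dose_grid()] on the sample's grid.
#' @export
simulate_dose <- function(sample, laterality = c("left", "right", "bilateral"),
                          prescription = 40, falloff = 20,
                          wedge_depth_frac = 0.2) {
  stopifnot(inherits(sample, "phantom_sample"))
  laterality <- match.arg(laterality)
  config <- sample$config
  geo <- phantom_geometry(config)
  co <- geo$coords
  ctr <- geo$center

  one_side <- function(sgn) {
    nrm <- c(sgn * 0.95, -0.31)
    tmax <- sqrt((nrm[1] * geo$torso_ab[1])^2 + (nrm[2] * geo$torso_ab[2])^2)
    t0 <- (1 - wedge_depth_frac) * tmax
    s <- nrm[1] * (co$X - ctr[1]) + nrm[2] * (co$Y - ctr[2]) - t0
    dist <- pmax(0, -s)
    if (falloff > 0) prescription * exp(-dist / falloff)
    else prescription * (dist == 0)
  }
  dv <- switch(laterality,
               left = one_side(1),
               right = one_side(-1),
               bilateral = pmax(one_side(1), one_side(-1)))
  dose_grid(array(dv, dim = config$grid_shape), config$spacing)
}

#' Write a phantom sample to disk
#'
#' NCT, CECT (and optionally dose) as NIfTI plus one NIfTI per structure and
#' a JSON manifest with the sample's truth parameters.
#'
#' @param sample a [phantom_sample].
#' @param dir output directory.
#' @param dose optional [dose_grid()] to include.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(sample, dir, dose = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ct(sample$pair$nct, file.path(dir, "nct.nii.gz"))
  write_ct(sample$pair$cect, file.path(dir, "cect.nii.gz"))
  write_structures(sample$structures, file.path(dir, "structures"))
  if (!is.null(dose)) write_dose(dose, file.path(dir, "dose.nii.gz"))
  manifest <- list(index = sample$index,
                   seed = sample$config$seed,
                   applied_enhancement_hu = sample$applied_enhancement,
                   grid_shape = sample$config$grid_shape,
                   spacing_mm = sample$config$spacing,
                   noise_sigma_hu = sample$config$noise_sigma)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
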
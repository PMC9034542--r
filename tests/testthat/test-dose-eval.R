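mkmask <- function(v, sp = c(1, 1, 1)) structure_mask("s", v, sp)

test_that("dose resampling is identity on the same grid and preserves constants", {
  ref <- ct_volume(array(0, c(10, 10, 5)))
  d <- dose_grid(array(40, c(10, 10, 5)))
  expect_equal(resample_dose_to_grid(d, ref)$voxels, d$voxels)
  coarse <- dose_grid(array(40, c(5, 5, 5)), spacing = c(2, 2, 1))
  r <- suppressWarnings(resample_dose_to_grid(coarse, ref))
  inside <- r$voxels[1:8, 1:8, ]
  expect_equal(unique(as.numeric(inside)), 40)
})

test_that("a linear dose gradient resamples exactly at new centers", {
  cc <- scectgan:::coord_arrays(c(12L, 10L, 6L), c(2, 2, 2))
  lin <- 1 + 0.5 * cc$X + 0.25 * cc$Y + 0.1 * cc$Z
  d <- dose_grid(lin, spacing = c(2, 2, 2))
  ref <- ct_volume(array(0, c(20, 16, 9)), spacing = c(1, 1, 1),
                   origin = c(1, 1, 1))
  r <- suppressWarnings(resample_dose_to_grid(d, ref))
  cr <- scectgan:::coord_arrays(c(20L, 16L, 9L), c(1, 1, 1), c(1, 1, 1))
  expected <- 1 + 0.5 * cr$X + 0.25 * cr$Y + 0.1 * cr$Z
  expect_equal(r$voxels, expected, tolerance = 1e-10)

  far <- dose_grid(array(1, c(4, 4, 4)), origin = c(1000, 1000, 1000))
  expect_error(resample_dose_to_grid(far, ref), "overlap")
})

test_that("DVH curves have the stated shape on constructed doses", {
  m <- array(TRUE, c(4, 4, 4))
  uni <- dose_grid(array(10, c(4, 4, 4)))
  cv <- compute_dvh(mkmask(m), uni, bin_width = 0.5)
  expect_equal(cv$volume[1], 1)                      # starts at 1 at 0 Gy
  expect_true(all(diff(cv$volume) <= 0))             # monotone
  expect_equal(cv$volume[cv$dose <= 10], rep(1, sum(cv$dose <= 10)))
  expect_equal(cv$volume[cv$dose > 10], rep(0, sum(cv$dose > 10)))

  half <- array(0, c(4, 4, 4)); half[1:2, , ] <- 20
  cv2 <- compute_dvh(mkmask(m), dose_grid(half), bin_width = 1)
  plateau <- cv2$volume[cv2$dose > 0 & cv2$dose <= 20]
  expect_equal(unique(plateau), 0.5)                 # 50% plateau

  # mean from the differential DVH equals voxelwise mean within bin/2
  set.seed(3)
  dv <- dose_grid(array(runif(64, 0, 30), c(4, 4, 4)))
  cv3 <- compute_dvh(mkmask(m), dv, bin_width = 0.01)
  dm <- dose_metrics(cv3)
  expect_lt(abs(dm$d_mean - mean(dv$voxels)), 0.005 + 1e-9)
  expect_lt(abs(dm$d_max - max(dv$voxels)), 0.01)
  expect_error(compute_dvh(mkmask(array(FALSE, c(4, 4, 4))), uni), "empty")
})

test_that("dose metrics match direct enumeration", {
  dm <- dose_metrics(c(2, 6, 12, 40))
  expect_equal(dm$d_max, 40)
  expect_equal(dm$d_mean, 15)
  expect_equal(unname(dm$v_at["V5Gy"]), 75)
  expect_equal(unname(dm$v_at["V10Gy"]), 50)
  expect_equal(unname(dm$v_at["V30Gy"]), 25)
  expect_equal(unname(dm$v_at["V40Gy"]), 25)        # inclusive threshold

  uni <- dose_metrics(rep(10, 5))
  expect_equal(uni$d_max, 10); expect_equal(uni$d_mean, 10)
  expect_equal(unname(uni$v_at["V5Gy"]), 100)
  expect_equal(unname(uni$v_at["V20Gy"]), 0)
  expect_equal(unname(dose_metrics(c(0, 3), thresholds = 0)$v_at["V0Gy"]),
               100)
  expect_error(dose_metrics(numeric(0)), "empty")
})

test_that("metrics from voxels and DVH agree on 100 random small structures", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    dv <- round(runif(n, 0, 45), 2)
    m <- array(FALSE, c(10, 10, 10)); m[seq_len(n)] <- TRUE
    grid <- dose_grid(array(0, c(10, 10, 10)))
    grid$voxels[seq_len(n)] <- dv
    direct <- dose_metrics(grid$voxels[m])
    curve <- dose_metrics(compute_dvh(mkmask(m), grid, bin_width = 0.01))
    expect_equal(direct$d_max, max(dv))
    expect_equal(direct$d_mean, mean(dv))
    expect_equal(direct$v_at,
                 vapply(c(5, 10, 20, 30, 40),
                        function(t) 100 * mean(dv >= t), numeric(1),
                        USE.NAMES = FALSE) |>
                   stats::setNames(names(direct$v_at)))
    expect_lt(abs(curve$d_mean - direct$d_mean), 0.005 + 1e-9)
    expect_lt(abs(curve$d_max - direct$d_max), 0.0100001)
    expect_equal(curve$v_at, direct$v_at, tolerance = 1e-9)
  }
})

test_that("V_t is monotone non-increasing and d_max >= d_mean", {
  set.seed(5)
  for (i in 1:20) {
    dv <- runif(sample(3:40, 1), 0, 50)
    dm <- dose_metrics(dv, thresholds = seq(0, 50, by = 5))
    expect_true(all(diff(dm$v_at) <= 0))
    expect_gte(dm$d_max, dm$d_mean)
    expect_true(all(dm$v_at >= 0 & dm$v_at <= 100))
  }
})

test_that("dosimetry comparison is zero for identical sets and dose-scale invariant", {
  s <- simulate_pair(tiny_phantom_config(noise_sigma = 0), 1)
  dose <- simulate_dose(s, "left")
  cmp <- compare_dosimetry(s$structures, s$structures, dose)
  expect_true(all(cmp$differences$abs_diff == 0))
  dose2 <- dose_grid(dose$voxels * 2, dose$spacing, dose$origin)
  cmp2 <- compare_dosimetry(s$structures, s$structures, dose2)
  expect_true(all(cmp2$differences$abs_diff == 0))

  # boundary perturbations far from the field edge move MHD little;
  # the same perturbation at the field edge moves it more
  margin <- min(s$structures$heart$spacing)
  pert <- s$structures
  pert$heart <- expand_margin(pert$heart, margin)
  cmpP <- compare_dosimetry(list(s$structures), list(pert), list(dose))
  mhd_far <- cmpP$differences$abs_diff[
    cmpP$differences$structure == "heart" &
      cmpP$differences$metric == "d_mean"]
  expect_lt(mhd_far, 0.5)

  # structure missing on one side is flagged, not dropped silently
  partial <- s$structures[setdiff(names(s$structures), "rca")]
  cmpM <- compare_dosimetry(s$structures, partial, dose)
  expect_true("rca" %in% cmpM$missing)
})

test_that("average_dvh is the pointwise mean with the stated edge cases", {
  m <- array(TRUE, c(3, 3, 3))
  c1 <- compute_dvh(mkmask(m), dose_grid(array(10, c(3, 3, 3))), 1)
  c2 <- compute_dvh(mkmask(m), dose_grid(array(20, c(3, 3, 3))), 1)
  expect_equal(average_dvh(list(c1))$volume, c1$volume)
  expect_equal(average_dvh(list(c1, c1))$volume, c1$volume)
  avg <- average_dvh(list(c1, c2))
  mid <- avg$volume[avg$dose > 10 & avg$dose <= 20]
  expect_equal(unique(mid), 0.5)                     # 50% plateau between
  c3 <- compute_dvh(mkmask(m), dose_grid(array(5, c(3, 3, 3))), 0.5)
  expect_error(average_dvh(list(c1, c3)), "bin width")
})
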
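test_that("ct_volume validates geometry and values", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2))), "finite")
  v <- ct_volume(array(1, c(2, 3, 4)), spacing = c(1, 2, 3),
                 origin = c(-1, 0, 5))
  expect_identical(dim(v$voxels), c(2L, 3L, 4L))
  cc <- scectgan:::voxel_centers(v)
  expect_equal(cc$y, c(0, 2, 4))
  expect_equal(cc$z, 5 + (0:3) * 3)
})

test_that("NIfTI round-trip preserves voxels and geometry", {
  set.seed(1)
  v <- ct_volume(array(round(rnorm(4 * 5 * 6, 0, 100)), c(4, 5, 6)),
                 spacing = c(0.9, 0.9, 1.0), origin = c(1, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_ct(v, f)
  r <- read_ct(f)
  expect_equal(r$voxels, v$voxels)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  unlink(f)
})

test_that("stored-value rescale arithmetic gives HU", {
  expect_equal(apply_rescale(1024, slope = 1, intercept = -1024), 0)
  expect_equal(apply_rescale(c(0, 2048), 1, -1024), c(-1024, 1024))
  expect_equal(apply_rescale(100, slope = 2, intercept = 10), 210)
})

test_that("dose reading applies grid scaling and rejects negatives", {
  d <- dose_grid(array(40000, c(3, 3, 3)))
  f <- tempfile(fileext = ".nii.gz")
  write_dose(d, f)
  r <- read_dose(f, scale = 0.001)
  expect_equal(unique(as.numeric(r$voxels)), 40)
  unlink(f)
  expect_error(dose_grid(array(-1, c(2, 2, 2))), "non-negative")
})

test_that("paired_sample requires identical grids", {
  a <- ct_volume(array(0, c(4, 4, 4)))
  b <- ct_volume(array(0, c(4, 4, 4)), spacing = c(2, 1, 1))
  expect_error(paired_sample(a, b), "share")
  expect_s3_class(paired_sample(a, a), "paired_sample")
})

test_that("embed_roi replaces exactly the half-open box", {
  base <- ct_volume(array(1, c(10, 10, 10)))
  patch <- ct_volume(array(0, c(4, 3, 2)))
  out <- embed_roi(base, patch, c(3, 4, 5))
  expect_equal(sum(out$voxels == 0), 4 * 3 * 2)
  expect_equal(out$voxels[3:6, 4:6, 5:6], array(0, c(4, 3, 2)))
  out$voxels[3:6, 4:6, 5:6] <- 1
  expect_equal(out$voxels, base$voxels)

  # identity patch and full-cover patch
  sub <- ct_volume(base$voxels[3:6, 4:6, 5:6])
  expect_equal(embed_roi(base, sub, c(3, 4, 5))$voxels, base$voxels)
  full <- ct_volume(array(7, c(10, 10, 10)))
  expect_equal(embed_roi(base, full, c(1, 1, 1))$voxels, full$voxels)

  expect_error(embed_roi(base, patch, c(8, 9, 10)), "overrun")
})

test_that("read_structures handles mask volumes and contour tables", {
  ref <- ct_volume(array(0, c(12, 12, 5)), spacing = c(1, 1, 2))
  m <- array(FALSE, c(12, 12, 5)); m[3:6, 3:6, 2:3] <- TRUE
  mv <- ct_volume(array(as.numeric(m), dim(m)), ref$spacing, ref$origin)
  f <- tempfile(fileext = ".nii.gz")
  write_ct(mv, f)

  # rectangle contour covering voxel centers 2..11 x 3..8 on 3 slices
  rect <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(x = c(0.5, 10.5, 10.5, 0.5), y = c(1.5, 1.5, 8.5, 8.5),
               z = (s - 1) * 2, ring = s)
  }))
  out <- read_structures(list(hrt = f, box = rect), ref,
                         name_map = c(hrt = "heart"))
  expect_named(out, c("heart", "box"))
  expect_equal(out$heart$mask, m)          # same grid: returned untouched
  expect_equal(sum(out$box$mask), 10 * 7 * 3)
  unlink(f)

  # empty structure flagged, not an error
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      ring = integer())
  res <- read_structures(list(e = empty), ref)
  expect_true(attr(res$e, "empty"))
})

test_that("mask volumes on a different grid are resampled nearest-neighbor", {
  ref <- ct_volume(array(0, c(10, 10, 4)), spacing = c(1, 1, 1))
  coarse <- array(FALSE, c(5, 5, 4)); coarse[2:3, 2:3, ] <- TRUE
  mv <- ct_volume(array(as.numeric(coarse), dim(coarse)),
                  spacing = c(2, 2, 1), origin = c(0, 0, 0))
  f <- tempfile(fileext = ".nii.gz")
  write_ct(mv, f)
  out <- read_structures(list(s = f), ref)
  # each coarse voxel covers ~2x2 fine voxels, 4 slices
  expect_gt(sum(out$s$mask), 30)
  expect_lt(sum(out$s$mask), 100)
  unlink(f)
})
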
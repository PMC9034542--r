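test_that("rasterization counts voxel centers under the even-odd rule", {
  ref <- ct_volume(array(0, c(16, 16, 4)))
  # rectangle strictly containing centers 3..11 x 4..10 on one slice
  rect <- data.frame(x = c(2.5, 11.5, 11.5, 2.5), y = c(3.5, 3.5, 10.5, 10.5),
                     z = 1, ring = 1)
  out <- rasterize_polygons(rect, ref)
  expect_equal(sum(out$mask), 9 * 7)
  expect_equal(sum(out$mask[, , 2]), 9 * 7)

  # donut: outer ring minus inner ring
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  outer_ring <- data.frame(x = 7.5 + 6 * cos(th), y = 7.5 + 6 * sin(th),
                           z = 0, ring = 1)
  inner_ring <- data.frame(x = 7.5 + 2.5 * cos(th), y = 7.5 + 2.5 * sin(th),
                           z = 0, ring = 2)
  donut <- rasterize_polygons(rbind(outer_ring, inner_ring), ref)
  full <- rasterize_polygons(outer_ring, ref)
  hole <- rasterize_polygons(inner_ring, ref)
  expect_equal(donut$mask, full$mask & !hole$mask)
  expect_gt(sum(hole$mask), 0)

  # degenerate ring flagged, empty result
  degen <- data.frame(x = c(1, 2), y = c(1, 2), z = 0, ring = 9)
  res <- rasterize_polygons(degen, ref)
  expect_equal(sum(res$mask), 0)
  expect_equal(res$degenerate_rings, 9)

  off <- data.frame(x = c(0, 5, 5), y = c(0, 0, 5), z = -0.9, ring = 1)
  expect_error(rasterize_polygons(off, ref), "off-grid")
})

test_that("expand_margin matches enumerated center distances", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  sm <- structure_mask("pt", m, spacing = c(1, 1, 1))
  ex <- expand_margin(sm, 1.0)
  expect_equal(sum(ex$mask), 7)            # center + 6 face neighbors
  expect_true(ex$mask[3, 4, 4] && ex$mask[4, 4, 5])
  expect_false(ex$mask[3, 3, 4])           # diagonal at sqrt(2) > 1
  expect_equal(expand_margin(sm, 0)$mask, sm$mask)   # identity
  expect_error(expand_margin(sm, -1), ">= 0")

  # anisotropy: 2 mm z-spacing keeps z-neighbors out at margin 1
  sm2 <- structure_mask("pt", m, spacing = c(1, 1, 2))
  ex2 <- expand_margin(sm2, 1.0)
  expect_false(ex2$mask[4, 4, 5])
  expect_true(ex2$mask[5, 4, 4])
})

test_that("expanding a tube by 5 mm grows its radius by about 5 mm", {
  d <- c(40L, 40L, 20L)
  cc <- scectgan:::coord_arrays(d, c(1, 1, 1))
  r0 <- 3
  tube <- (cc$X - 19.5)^2 + (cc$Y - 19.5)^2 <= r0^2
  sm <- structure_mask("tube", tube, c(1, 1, 1))
  ex <- expand_margin(sm, 5)
  # compare volume against analytic cylinders (end effects only in z)
  mid <- 5:16
  area0 <- mean(colSums(matrix(sm$mask[, , mid], prod(d[1:2]))))
  area1 <- mean(colSums(matrix(ex$mask[, , mid], prod(d[1:2]))))
  expect_equal(area1 / area0, ((r0 + 5) / r0)^2, tolerance = 0.25)
  expect_true(all(ex$mask[sm$mask]))       # extensive
  ex3 <- expand_margin(sm, 3)
  expect_true(all(ex$mask[ex3$mask]))      # monotone in margin
})

test_that("dsc matches counting cases and flags degenerate inputs", {
  mk <- function(v) structure_mask("x", v, c(1, 1, 1))
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1, 1] <- TRUE; a[1:2, 2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 2)); b[1:2, 2, 1] <- TRUE; b[1:2, 3, 1] <- TRUE
  expect_equal(dsc(mk(a), mk(b)), 0.5)     # |X|=|Y|=4, overlap 2
  expect_equal(dsc(mk(a), mk(a)), 1)
  disj <- array(FALSE, c(4, 4, 2)); disj[4, 4, 2] <- TRUE
  expect_equal(dsc(mk(a), mk(disj)), 0)
  empty <- mk(array(FALSE, c(4, 4, 2)))
  expect_equal(as.numeric(dsc(empty, empty)), 1)
  expect_true(attr(dsc(empty, empty), "degenerate"))
  expect_equal(as.numeric(dsc(mk(a), empty)), 0)
  wrong <- structure_mask("x", a, c(2, 1, 1))
  expect_error(dsc(mk(a), wrong), "registration|grid")
})

test_that("surface extraction enumerates boundary voxels", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  s <- extract_surface(structure_mask("c", cube, c(1, 1, 1)))
  expect_equal(s$n, 26)                    # 3^3 minus the center
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(extract_surface(structure_mask("s", single, c(1, 1, 1)))$n, 1)
  sheet <- array(FALSE, c(6, 6, 3)); sheet[2:5, 2:5, 2] <- TRUE
  expect_equal(extract_surface(structure_mask("sh", sheet, c(1, 1, 1)))$n, 16)
  # volume boundary counts as outside
  corner <- array(TRUE, c(2, 2, 2))
  expect_equal(extract_surface(structure_mask("k", corner, c(1, 1, 1)))$n, 8)
})

test_that("msd equals the brute-force oracle on random small masks", {
  mk <- function(v, sp) structure_mask("x", v, sp)
  two <- array(FALSE, c(9, 3, 3)); two[2, 2, 2] <- TRUE
  oth <- array(FALSE, c(9, 3, 3)); oth[5, 2, 2] <- TRUE
  expect_equal(msd(mk(two, c(1, 1, 1)), mk(oth, c(1, 1, 1))), 3)
  expect_equal(msd(mk(two, c(1, 1, 1)), mk(two, c(1, 1, 1))), 0)

  set.seed(17)
  for (i in 1:100) {
    d <- sample(4:12, 3, replace = TRUE)
    sp <- sample(c(0.5, 1, 1.5, 2.5), 3, replace = TRUE)
    a <- structure_mask("a", array(runif(prod(d)) < 0.2, d), sp)
    b <- structure_mask("b", array(runif(prod(d)) < 0.2, d), sp)
    if (!any(a$mask) || !any(b$mask)) next
    expect_equal(msd(a, b), msd_bruteforce(a, b), tolerance = 1e-9)
    expect_equal(msd(a, b), msd(b, a))     # symmetric by construction
  }
  empty <- structure_mask("e", array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  full <- structure_mask("f", array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_true(is.na(msd(empty, full)))
})

test_that("dsc and msd are invariant under simultaneous shifts and degrade with displacement", {
  base <- array(FALSE, c(16, 16, 8)); base[4:9, 4:9, 3:6] <- TRUE
  mk <- function(v) structure_mask("x", v, c(1, 1, 1))
  shift <- function(v, k) {
    out <- array(FALSE, dim(v))
    out[(1 + k):dim(v)[1], , ] <- v[1:(dim(v)[1] - k), , ]
    out
  }
  a <- mk(base); b <- mk(shift(base, 2))
  expect_equal(dsc(mk(shift(base, 3)), mk(shift(shift(base, 2), 3))),
               dsc(a, b), tolerance = 1e-12)
  d1 <- dsc(a, mk(shift(base, 1)))
  d2 <- dsc(a, mk(shift(base, 3)))
  expect_gt(d1, d2)                        # monotone under displacement
})

test_that("compare_structure_sets expands vessels on both sides and aggregates", {
  s <- simulate_pair(tiny_phantom_config(noise_sigma = 0), 1)
  same <- compare_structure_sets(s$structures, s$structures)
  expect_true(all(same$table$dsc == 1))
  expect_true(all(same$table$msd_mm == 0))

  # vessel rows are compared after 5 mm expansion: volumes reflect it
  lad_row <- same$table[same$table$structure == "lad", ]
  expect_gt(lad_row$volume_a_cc,
            sum(s$structures$lad$mask) * prod(s$structures$lad$spacing) / 1000)

  # a one-voxel dilation leaves DSC < 1 and MSD within a voxel
  dil <- s$structures
  dil$heart <- expand_margin(dil$heart, min(dil$heart$spacing))
  cmp <- compare_structure_sets(s$structures, dil)
  hr <- cmp$table[cmp$table$structure == "heart", ]
  expect_lt(hr$dsc, 1)
  expect_gt(hr$dsc, 0.8)
  expect_gt(hr$msd_mm, 0)
  expect_lt(hr$msd_mm, max(s$structures$heart$spacing))

  # equal-magnitude boundary perturbation hurts small structures more
  pert <- s$structures
  m <- min(s$structures$heart$spacing)
  pert$heart <- expand_margin(pert$heart, m)
  pert$lad <- expand_margin(pert$lad, m)
  cmp2 <- compare_structure_sets(s$structures, pert,
                                 vessel_names = character(0))
  expect_gt(cmp2$table$dsc[cmp2$table$structure == "heart"],
            cmp2$table$dsc[cmp2$table$structure == "lad"])

  # unmatched names are reported
  partial <- s$structures[c("heart", "lv")]
  cmp3 <- compare_structure_sets(partial, s$structures)
  expect_setequal(cmp3$unmatched, setdiff(names(s$structures),
                                          c("heart", "lv")))
  expect_error(compare_structure_sets(list(a = s$structures$lv),
                                      list(b = s$structures$lv)),
               "common")
})
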
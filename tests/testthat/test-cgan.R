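# Independent arithmetic oracle for the generator parameter count, mirroring
# the architecture definition (dense layer: BN + 3x3 conv; TD: BN + 1x1
# conv; TU: 2x2 transposed conv; stem 3x3; head 1x1).
gen_param_oracle <- function(cfg) {
  k <- cfg$growth_rate; L <- cfg$layers_per_block; F0 <- cfg$initial_features
  p <- 9 * F0 + F0
  cc <- F0
  skips <- integer(0)
  dense <- function(cin, n) {
    pp <- 0
    for (j in seq_len(n)) {
      pp <- pp + 2 * cin + 9 * cin * k + k
      cin <- cin + k
    }
    list(p = pp, c = cin)
  }
  for (i in seq_along(L)) {
    r <- dense(cc, L[i]); p <- p + r$p; cc <- r$c
    skips <- c(skips, cc)
    p <- p + 2 * cc + cc * cc + cc
  }
  r <- dense(cc, cfg$bottleneck_layers); p <- p + r$p
  m <- cfg$bottleneck_layers * k
  lastc <- NA
  for (i in rev(seq_along(L))) {
    p <- p + 4 * m * m + m
    r <- dense(skips[i] + m, L[i]); p <- p + r$p
    lastc <- r$c
    m <- L[i] * k
  }
  p + lastc + 1
}

disc_param_oracle <- function(cfg) {
  feats <- cfg$base_features * 2^(seq_len(cfg$n_transitions) - 1)
  cin <- 2; p <- 0
  for (i in seq_len(cfg$n_transitions)) {
    p <- p + 9 * cin * feats[i] + feats[i]
    if (i > 1) p <- p + 2 * feats[i]
    cin <- feats[i]
  }
  p + 9 * cin + 1
}

test_that("count_parameters matches closed-form counts and conv example", {
  ps <- scectgan:::nn_params()
  scectgan:::par_add(ps, "w", array(0, c(3, 3, 1, 8)))
  scectgan:::par_add(ps, "b", numeric(8))
  expect_equal(count_parameters(ps), 80)   # 3*3*1*8 + 8

  cfgs <- list(gan_generator_config(),
               gan_generator_config(n_transitions = 2L,
                                    layers_per_block = c(2L, 3L),
                                    bottleneck_layers = 2L,
                                    growth_rate = 4L,
                                    initial_features = 6L))
  for (cfg in cfgs) {
    set.seed(1)
    net <- build_generator(cfg)
    expect_equal(count_parameters(net), gen_param_oracle(cfg))
  }
  for (cfg in list(gan_discriminator_config(),
                   gan_discriminator_config(n_transitions = 2L,
                                            base_features = 6L))) {
    net <- build_discriminator(cfg)
    expect_equal(count_parameters(net), disc_param_oracle(cfg))
  }
})

test_that("frozen parameters are excluded from the count", {
  set.seed(1)
  net <- build_discriminator(gan_discriminator_config(n_transitions = 2L,
                                                      base_features = 4L))
  n0 <- count_parameters(net)
  net2 <- freeze_parameters(net, c("d1_conv_w", "d1_conv_b"))
  expect_equal(count_parameters(net2),
               n0 - length(net$ps$w$d1_conv_w) - length(net$ps$w$d1_conv_b))
})

test_that("generator is fully convolutional: output shape equals input shape", {
  set.seed(3)
  cfg <- gan_generator_config(n_transitions = 5L,
                              layers_per_block = rep(1L, 5),
                              bottleneck_layers = 1L, growth_rate = 2L,
                              initial_features = 2L, dropout_rate = 0)
  net <- build_generator(cfg)
  for (side in c(32L, 64L, 96L)) {
    x <- array(rnorm(side * side), c(side, side, 1L, 1L))
    y <- generator_forward(net, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(y >= -1 & y <= 1))   # bounded output activation
  }
  expect_error(generator_forward(net, array(0, c(33, 33, 1, 1))),
               "divisible")
})

test_that("discriminator emits a patch score map in [0, 1]", {
  set.seed(4)
  net <- build_discriminator(gan_discriminator_config())
  x <- array(rnorm(64 * 64 * 2 * 2), c(64, 64, 2, 2))
  p <- discriminator_forward(net, x)
  expect_identical(dim(p), c(4L, 4L, 1L, 2L))   # 4 halvings, patch map
  expect_true(all(p >= 0 & p <= 1))
  expect_error(discriminator_forward(net, array(0, c(64, 64, 1, 1))),
               "2 channels|\\[H, W, 2, N\\]")
  # zero weights give sigmoid(0) = 0.5 everywhere
  for (nm in names(net$ps$w)) net$ps$w[[nm]][] <- 0
  p0 <- discriminator_forward(net, x)
  expect_true(all(p0 == 0.5))
})

test_that("generator loss decomposes into closed-form BCE plus weighted L1", {
  pred <- array(0.5, c(4, 4, 1, 1))
  target <- pred
  d_fake <- array(0.5, c(2, 2, 1, 1))
  gl <- generator_loss(d_fake, pred, target, lambda_l1 = 100)
  expect_equal(gl$total, -log(0.5), tolerance = 1e-12)
  expect_equal(gl$l1, 0)

  gl2 <- generator_loss(d_fake, target + 0.1, target, lambda_l1 = 100)
  expect_equal(gl2$total, -log(0.5) + 10, tolerance = 1e-12)
  gl3 <- generator_loss(d_fake, target + 0.1, target, lambda_l1 = 0)
  expect_equal(gl3$total, gl3$adversarial)
  expect_error(generator_loss(d_fake, pred, array(0, c(2, 2, 1, 1))),
               "shape")
})

test_that("discriminator loss behaves at its limits", {
  half <- array(0.5, c(3, 3, 1, 1))
  expect_equal(discriminator_loss(half, half), 2 * -log(0.5),
               tolerance = 1e-12)
  eps <- 1e-6
  good <- discriminator_loss(array(1 - eps, dim(half)),
                             array(eps, dim(half)))
  expect_lt(good, 1e-5)
  swapped <- discriminator_loss(array(eps, dim(half)),
                                array(1 - eps, dim(half)))
  expect_gt(swapped, 2)
})

test_that("a short fit run is seed-reproducible and logs history", {
  set.seed(77)
  mkslice <- function() {
    x <- matrix(rnorm(16 * 16, 0, 0.1), 16, 16)
    list(nct = x, cect = x + 0.2)
  }
  tr <- replicate(6, mkslice(), simplify = FALSE)
  va <- replicate(2, mkslice(), simplify = FALSE)
  gcfg <- gan_generator_config(n_transitions = 1L, layers_per_block = 1L,
                               bottleneck_layers = 1L, growth_rate = 3L,
                               initial_features = 4L, dropout_rate = 0)
  dcfg <- gan_discriminator_config(n_transitions = 1L, base_features = 4L)
  ctrl <- gan_train_config(epochs = 3L, batch_size = 2L, seed = 5L,
                           lr_g = 1e-3)
  m1 <- scect_gan(tr, va, gcfg, dcfg, ctrl)
  m2 <- scect_gan(tr, va, gcfg, dcfg, ctrl)
  expect_equal(m1$history, m2$history)
  expect_equal(nrow(m1$history), 3L)
  expect_true(all(is.finite(m1$history$val_l1)))
  expect_error(scect_gan(list(), va, gcfg, dcfg, ctrl), "at least one")

  # inference determinism and ROI identity
  nct <- ct_volume(array(rnorm(16 * 16 * 4, 40, 20), c(16, 16, 4)))
  s1 <- predict(m1, nct)
  s2 <- predict(m1, nct)
  expect_identical(s1$voxels, s2$voxels)
  roi <- predict(m1, nct, roi_center = c(8, 8, 2), roi_size = c(8, 8, 2))
  inside <- array(FALSE, dim(nct$voxels))
  inside[4:11, 4:11, 1:2] <- TRUE   # half-open box centred at (8, 8, 2)
  expect_identical(roi$voxels[!inside], nct$voxels[!inside])
})
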
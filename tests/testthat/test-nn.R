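# Finite-difference validation of the reverse-mode tape. The oracle is the
# centered-difference quotient of the scalar loss; the network forward is
# deterministic given fixed weights and BN state.

fd_check <- function(net, forward, x, target, n_params = 8L, tol = 1e-6) {
  loss_fn <- function() mean((forward(x, FALSE) - target)^2)
  tp <- scectgan:::nn_tape(train = TRUE)
  id <- forward(x, TRUE, tp)
  pred <- tp$vals[[id]]
  scectgan:::par_zero_grads(net$ps)
  scectgan:::tn_backward(tp, id, 2 * (pred - target) / length(pred))
  worst <- 0
  nms <- names(net$ps$w)
  set.seed(99)
  for (nm in sample(nms, min(n_params, length(nms)))) {
    wv <- net$ps$w[[nm]]
    i <- sample.int(length(wv), 1)
    eps <- 1e-5
    st <- net$ps$state
    net$ps$w[[nm]][i] <- wv[i] + eps
    f1 <- loss_fn(); net$ps$state <- st
    net$ps$w[[nm]][i] <- wv[i] - eps
    f2 <- loss_fn(); net$ps$state <- st
    net$ps$w[[nm]][i] <- wv[i]
    num <- (f1 - f2) / (2 * eps)
    ana <- net$ps$g[[nm]][i]
    worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
  }
  worst
}

test_that("generator gradients match finite differences", {
  set.seed(21)
  net <- build_generator(gan_generator_config(
    n_transitions = 2L, layers_per_block = c(2L, 2L),
    bottleneck_layers = 1L, growth_rate = 3L, initial_features = 4L,
    dropout_rate = 0))
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fwd <- function(x, train, tape = NULL) {
    # training-mode forward recomputes batch statistics; the numeric
    # oracle must see the same statistics, so probe in training mode too
    if (is.null(tape)) generator_forward(net, x, train = TRUE)
    else generator_forward(net, x, tape = tape)
  }
  expect_lt(fd_check(net, fwd, x, y, n_params = 10L), 1e-6)
})

test_that("discriminator gradients match finite differences", {
  set.seed(22)
  net <- build_discriminator(gan_discriminator_config(n_transitions = 2L,
                                                      base_features = 4L))
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- array(0.3, c(2, 2, 1, 2))
  fwd <- function(x, train, tape = NULL) {
    if (is.null(tape)) discriminator_forward(net, x, train = TRUE)
    else discriminator_forward(net, x, tape = tape)
  }
  expect_lt(fd_check(net, fwd, x, y, n_params = 10L), 1e-5)
})

test_that("gradient flows through the discriminator to its input", {
  set.seed(23)
  net <- build_discriminator(gan_discriminator_config(n_transitions = 2L,
                                                      base_features = 4L))
  x <- array(rnorm(8 * 8 * 2 * 1), c(8, 8, 2, 1))
  tp <- scectgan:::nn_tape(train = FALSE)
  xid <- scectgan:::tn_input(tp, x)
  out <- discriminator_forward(net, xid, tape = tp)
  p <- tp$vals[[out]]
  scectgan:::par_zero_grads(net$ps)
  grads <- scectgan:::tn_backward(tp, out, array(1, dim(p)))
  gx <- grads[[xid]]
  expect_identical(dim(gx), dim(x))
  # numeric check against perturbing one input pixel
  eps <- 1e-5
  x2 <- x; x2[3, 4, 2, 1] <- x2[3, 4, 2, 1] + eps
  f1 <- sum(discriminator_forward(net, x2, train = FALSE))
  x2[3, 4, 2, 1] <- x[3, 4, 2, 1] - eps
  f2 <- sum(discriminator_forward(net, x2, train = FALSE))
  expect_equal(gx[3, 4, 2, 1], (f1 - f2) / (2 * eps), tolerance = 1e-5)
})

test_that("adam and sgd steps move parameters in the negative gradient direction", {
  ps <- scectgan:::nn_params()
  scectgan:::par_add(ps, "w", c(1, 2, 3))
  scectgan:::par_zero_grads(ps)
  scectgan:::par_acc(ps, "w", c(1, -1, 0))
  opt <- scectgan:::opt_adam(lr = 0.1)
  scectgan:::opt_step(opt, ps)
  expect_lt(ps$w[["w"]][1], 1)
  expect_gt(ps$w[["w"]][2], 2)
  expect_equal(ps$w[["w"]][3], 3)

  ps2 <- scectgan:::nn_params()
  scectgan:::par_add(ps2, "w", 5)
  scectgan:::par_zero_grads(ps2)
  scectgan:::par_acc(ps2, "w", 2)
  scectgan:::opt_step(scectgan:::opt_sgd(lr = 0.5), ps2)
  expect_equal(ps2$w[["w"]], 4)
})

test_that("max-pool routes gradient to the maximum entry only", {
  tp <- scectgan:::nn_tape(train = TRUE)
  x <- array(0, c(2, 2, 1, 1))
  x[1, 2, 1, 1] <- 5
  xid <- scectgan:::tn_input(tp, x)
  pid <- scectgan:::tn_maxpool2(tp, xid)
  expect_equal(as.numeric(tp$vals[[pid]]), 5)
  g <- scectgan:::tn_backward(tp, pid, array(2, c(1, 1, 1, 1)))
  dx <- g[[xid]]
  expect_equal(dx[1, 2, 1, 1], 2)
  expect_equal(sum(dx), 2)
})
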
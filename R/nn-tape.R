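# Minimal reverse-mode automatic differentiation for 2D convolutional
# networks. Tensors are [H, W, C, N] arrays (column-major). A tape records
# each op's output node and a backward closure; gradients are accumulated
# node-wise in reverse order, and parameter gradients side-effect into the
# parameter store. Everything is deterministic and single-threaded.

nn_params <- function() {
  ps <- new.env(parent = emptyenv())
  ps$w <- list()       # parameter arrays
  ps$g <- list()       # accumulated gradients
  ps$state <- list()   # per-parameter-set auxiliary state (BN running stats)
  ps
}

par_add <- function(ps, name, value) {
  ps$w[[name]] <- value
  ps$g[[name]] <- NULL
  name
}

par_zero_grads <- function(ps) {
  ps$g <- vector("list", length(ps$w))
  names(ps$g) <- names(ps$w)
  invisible(ps)
}

par_acc <- function(ps, name, grad) {
  cur <- ps$g[[name]]
  ps$g[[name]] <- if (is.null(cur)) grad else cur + grad
}

par_count <- function(ps) sum(vapply(ps$w, length, integer(1)))

nn_tape <- function(train = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$ops <- list()
  tp$n <- 0L
  tp$train <- train
  tp
}

tn_push <- function(tp, val, inputs = integer(), backward = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  tp$ops[[tp$n]] <- list(inputs = inputs, backward = backward)
  tp$n
}

tn_val <- function(tp, id) tp$vals[[id]]

tn_input <- function(tp, x) tn_push(tp, x)

# Backward pass seeded at one or more nodes (`ids` with matching `grads`
# list); returns the list of node gradients (NULL where unreached).
# Parameter gradients accumulate in their store via the op closures.
tn_backward <- function(tp, ids, grads_in) {
  if (!is.list(grads_in)) grads_in <- list(grads_in)
  grads <- vector("list", tp$n)
  for (j in seq_along(ids)) {
    k <- ids[j]
    grads[[k]] <- if (is.null(grads[[k]])) grads_in[[j]]
    else grads[[k]] + grads_in[[j]]
  }
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    op <- tp$ops[[i]]
    if (is.null(op$backward)) next
    gi <- op$backward(g)
    for (j in seq_along(op$inputs)) {
      if (is.null(gi[[j]])) next
      k <- op$inputs[j]
      grads[[k]] <- if (is.null(grads[[k]])) gi[[j]] else grads[[k]] + gi[[j]]
    }
  }
  grads
}

## ---- ops -------------------------------------------------------------

tn_conv3x3 <- function(tp, ps, xid, wname, bname) {
  x <- tp$vals[[xid]]
  y <- .conv3x3_fwd(x, ps$w[[wname]], ps$w[[bname]])
  force(wname); force(bname)
  tn_push(tp, y, xid, function(g) {
    r <- .conv3x3_bwd(x, ps$w[[wname]], g)
    par_acc(ps, wname, r$dw)
    par_acc(ps, bname, r$db)
    list(r$dx)
  })
}

# Per-channel broadcast helpers on [H, W, C, N] arrays, avoiding aperm:
# viewing x as (HW, C*N), column (c, n) maps to channel c.
bc_mul_add <- function(x, scale, shift) .ch_affine(x, scale, shift)

channel_stat <- function(x) .ch_sum(x)

tn_conv1x1 <- function(tp, ps, xid, wname, bname) {
  x <- tp$vals[[xid]]
  d <- dim(x)
  hw <- d[1] * d[2]
  W <- ps$w[[wname]]              # C_in x C_out
  b <- ps$w[[bname]]
  cout <- ncol(W)
  y <- array(0, c(d[1], d[2], cout, d[4]))
  xm <- x; dim(xm) <- c(hw, d[3], d[4])
  for (n in seq_len(d[4])) {
    ym <- xm[, , n] %*% W
    y[, , , n] <- ym + rep(b, each = hw)
  }
  tn_push(tp, y, xid, function(g) {
    gm <- g; dim(gm) <- c(hw, cout, d[4])
    dW <- matrix(0, d[3], cout)
    dx <- array(0, d)
    for (n in seq_len(d[4])) {
      gn <- gm[, , n]
      dW <- dW + crossprod(xm[, , n], gn)
      dx[, , , n] <- gn %*% t(W)
    }
    par_acc(ps, wname, dW)
    par_acc(ps, bname, channel_stat(g))
    list(dx)
  })
}

# 2x2 stride-2 transposed convolution (learned upsampling): each input
# pixel maps linearly onto a 2x2 output block; exactly the transpose of a
# 2x2 stride-2 convolution.
tn_convT2x2 <- function(tp, ps, xid, wname, bname) {
  x <- tp$vals[[xid]]
  d <- dim(x)                     # H W C N
  hw <- d[1] * d[2]
  W4 <- ps$w[[wname]]             # 2 x 2 x C_in x C_out
  Cout <- dim(W4)[4]
  Wm <- aperm(W4, c(3, 1, 2, 4))  # C_in x (kh, kw, C_out)
  dim(Wm) <- c(d[3], 4 * Cout)
  b <- ps$w[[bname]]
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * d[2], 2L); j2 <- j1 + 1L
  xm <- x; dim(xm) <- c(hw, d[3], d[4])
  y <- array(0, c(2 * d[1], 2 * d[2], Cout, d[4]))
  for (n in seq_len(d[4])) {
    yb <- xm[, , n] %*% Wm        # (HW) x (kh, kw, Cout)
    dim(yb) <- c(d[1], d[2], 2, 2, Cout)
    y[i1, j1, , n] <- yb[, , 1, 1, ]
    y[i2, j1, , n] <- yb[, , 2, 1, ]
    y[i1, j2, , n] <- yb[, , 1, 2, ]
    y[i2, j2, , n] <- yb[, , 2, 2, ]
  }
  y <- y + rep(rep(b, times = d[4]), each = 4 * hw)
  dim(y) <- c(2 * d[1], 2 * d[2], Cout, d[4])
  tn_push(tp, y, xid, function(g) {
    dW <- matrix(0, d[3], 4 * Cout)
    dx <- array(0, d)
    gb <- array(0, c(d[1], d[2], 2, 2, Cout))
    for (n in seq_len(d[4])) {
      gb[, , 1, 1, ] <- g[i1, j1, , n]
      gb[, , 2, 1, ] <- g[i2, j1, , n]
      gb[, , 1, 2, ] <- g[i1, j2, , n]
      gb[, , 2, 2, ] <- g[i2, j2, , n]
      gm <- gb; dim(gm) <- c(hw, 4 * Cout)
      dW <- dW + crossprod(xm[, , n], gm)
      dx[, , , n] <- gm %*% t(Wm)
    }
    dim(dW) <- c(d[3], 2, 2, Cout)
    par_acc(ps, wname, aperm(dW, c(2, 3, 1, 4)))
    par_acc(ps, bname, channel_stat(g))
    list(dx)
  })
}

# Batch normalization over (H, W, N) per channel. Training mode uses batch
# statistics and updates running estimates (momentum 0.1); eval mode uses
# the stored running statistics.
tn_bn <- function(tp, ps, xid, gname, bname, sname, eps = 1e-5,
                  momentum = 0.1) {
  x <- tp$vals[[xid]]
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  gamma <- ps$w[[gname]]; beta <- ps$w[[bname]]
  st <- ps$state[[sname]]
  if (is.null(st)) st <- list(mean = numeric(d[3]), var = rep(1, d[3]))
  train_stats <- tp$train && m > 1
  if (train_stats) {
    mu <- channel_stat(x) / m
    ctr <- .ch_center(x, mu)
    xc <- ctr$centered
    va <- ctr$sumsq / m
    ps$state[[sname]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                              var = (1 - momentum) * st$var + momentum * va)
  } else {
    mu <- st$mean; va <- st$var
    xc <- bc_mul_add(x, NULL, -mu)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- bc_mul_add(xc, inv, NULL)
  y <- bc_mul_add(xhat, gamma, beta)
  tn_push(tp, y, xid, function(g) {
    dgamma <- .ch_dot(g, xhat)
    dbeta <- channel_stat(g)
    par_acc(ps, gname, dgamma)
    par_acc(ps, bname, dbeta)
    if (train_stats) {
      t1 <- bc_mul_add(g, NULL, -dbeta / m)
      t2 <- bc_mul_add(xhat, dgamma / m, NULL)
      dx <- bc_mul_add(t1 - t2, gamma * inv, NULL)
    } else {
      dx <- bc_mul_add(g, gamma * inv, NULL)
    }
    list(dx)
  })
}

tn_relu <- function(tp, xid) {
  x <- tp$vals[[xid]]
  tn_push(tp, .lrelu_fwd(x, 0), xid,
          function(g) list(.lrelu_bwd(x, g, 0)))
}

tn_lrelu <- function(tp, xid, alpha = 0.2) {
  x <- tp$vals[[xid]]
  tn_push(tp, .lrelu_fwd(x, alpha), xid,
          function(g) list(.lrelu_bwd(x, g, alpha)))
}

tn_tanh <- function(tp, xid) {
  y <- tanh(tp$vals[[xid]])
  tn_push(tp, y, xid, function(g) list(g * (1 - y^2)))
}

tn_sigmoid <- function(tp, xid) {
  y <- 1 / (1 + exp(-tp$vals[[xid]]))
  tn_push(tp, y, xid, function(g) list(g * y * (1 - y)))
}

tn_maxpool2 <- function(tp, xid) {
  x <- tp$vals[[xid]]
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("max-pool requires even spatial dims")
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, e); dim(y) <- dim(a)
  tn_push(tp, y, xid, function(g) {
    dx <- array(0, d)
    m1 <- a == y
    m2 <- (b == y) & !m1
    m3 <- (cc == y) & !m1 & !m2
    m4 <- (e == y) & !m1 & !m2 & !m3
    dx[i1, j1, , ] <- g * m1
    dx[i2, j1, , ] <- g * m2
    dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + g * m3
    dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + g * m4
    list(dx)
  })
}

tn_dropout <- function(tp, xid, rate) {
  if (!tp$train || rate <= 0) return(xid)
  x <- tp$vals[[xid]]
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim = dim(x))
  tn_push(tp, x * mask, xid, function(g) list(g * mask))
}

tn_concat <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp$vals[[i]])
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  tn_push(tp, .cat_ch(vals), ids, function(g) .split_ch(g, cs))
}

## ---- optimizers ------------------------------------------------------

opt_adam <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$m <- list(); e$v <- list(); e$t <- 0L
  class(e) <- "nn_opt_adam"
  e
}

opt_sgd <- function(lr = 2e-5) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  class(e) <- "nn_opt_sgd"
  e
}

opt_step <- function(opt, ps, params = names(ps$w)) UseMethod("opt_step")

#' @export
opt_step.nn_opt_adam <- function(opt, ps, params = names(ps$w)) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in params) {
    g <- ps$g[[nm]]
    if (is.null(g)) next
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    ps$w[[nm]] <- ps$w[[nm]] - opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps)
  }
  invisible(ps)
}

#' @export
opt_step.nn_opt_sgd <- function(opt, ps, params = names(ps$w)) {
  for (nm in params) {
    g <- ps$g[[nm]]
    if (is.null(g)) next
    ps$w[[nm]] <- ps$w[[nm]] - opt$lr * g
  }
  invisible(ps)
}
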
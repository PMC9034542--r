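#' Training configuration for the translation model
#'
#' Defaults reproduce the reference training setting: adversarial + L1
#' objective with `lambda_l1 = 100`, batch size 4, Adam (learning rate
#' 2e-4, betas 0.5/0.999) for the generator and plain SGD (2e-5) for the
#' discriminator, 200 epochs with the checkpoint chosen by lowest
#' validation L1. Scaled-down runs lower `epochs` and typically raise
#' `lr_g`, trading the long saturation schedule for fewer, larger steps.
#'
#' @param lambda_l1 weight of the L1 term (100 reproduces the reference
#'   setting).
#' @param batch_size slices per training step.
#' @param epochs training epochs.
#' @param lr_g,lr_d starting learning rates for generator (Adam) and
#'   discriminator (SGD).
#' @param beta1,beta2 Adam moment decay rates.
#' @param crop in-plane random-crop size applied (paired) to training
#'   slices; `NULL` disables cropping.
#' @param seed integer seed governing weight init, shuffling, cropping and
#'   dropout.
#' @param checkpoint keep and restore the weights with the lowest
#'   validation L1.
#' @param verbose print per-epoch losses.
#' @return An object of class `gan_train_config`.
#' @export
gan_train_config <- function(lambda_l1 = 100, batch_size = 4L,
                             epochs = 200L, lr_g = 2e-4, lr_d = 2e-5,
                             beta1 = 0.5, beta2 = 0.999, crop = NULL,
                             seed = 1L, checkpoint = TRUE, verbose = FALSE) {
  if (any(c(lambda_l1, batch_size, epochs, lr_g, lr_d) < 0))
    stop("training parameters must be non-negative")
  structure(list(lambda_l1 = lambda_l1, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_g = lr_g, lr_d = lr_d,
                 beta1 = beta1, beta2 = beta2, crop = crop,
                 seed = as.integer(seed), checkpoint = isTRUE(checkpoint),
                 verbose = isTRUE(verbose)),
            class = "gan_train_config")
}

slices_to_batch <- function(slices, idx) {
  d <- dim(slices[[idx[1]]]$nct)
  n <- length(idx)
  x <- array(0, c(d[1], d[2], 1L, n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (j in seq_along(idx)) {
    x[, , 1, j] <- slices[[idx[j]]]$nct
    y[, , 1, j] <- slices[[idx[j]]]$cect
  }
  list(x = x, y = y)
}

#' Fit the conditional-GAN translation model
#'
#' Trains the generator against the patch discriminator with alternating
#' updates (one discriminator step, one generator step per batch). The
#' discriminator sees the 2-channel (NCT, CECT) concatenation as real and
#' (NCT, SCECT) with the generated slice detached as fake; the generator
#' receives the non-saturating adversarial gradient through the
#' discriminator plus the weighted L1 gradient. Per-epoch validation L1 is
#' logged; with `checkpoint = TRUE` the returned model carries the weights
#' of the best validation epoch. Training aborts with diagnostics if a loss
#' becomes non-finite.
#'
#' @param train_slices,val_slices lists of paired slices: each element
#'   `list(nct = <matrix>, cect = <matrix>)` on the normalized intensity
#'   scale (see [phantom_slice_pairs()] / [window_normalize()]).
#' @param generator a [gan_generator_config()] (or prebuilt
#'   [build_generator()] network).
#' @param discriminator a [gan_discriminator_config()] (or prebuilt
#'   network).
#' @param control a [gan_train_config()].
#' @param preprocess the [preprocess_config()] used to normalize the
#'   slices; stored for inference-time denormalization.
#' @return An object of class `scect_gan` with components `generator`,
#'   `discriminator`, `history` (per-epoch data frame), `best_epoch`,
#'   `control`, `preprocess`.
#' @export
scect_gan <- function(train_slices, val_slices,
                      generator = gan_generator_config(),
                      discriminator = gan_discriminator_config(),
                      control = gan_train_config(),
                      preprocess = preprocess_config()) {
  if (!length(train_slices) || !length(val_slices))
    stop("at least one training and one validation slice pair is required")
  set.seed(control$seed)
  net_g <- if (inherits(generator, "scect_generator")) generator
  else build_generator(generator)
  net_d <- if (inherits(discriminator, "scect_discriminator")) discriminator
  else build_discriminator(discriminator)
  opt_g <- opt_adam(control$lr_g, control$beta1, control$beta2)
  opt_d <- opt_sgd(control$lr_d)

  n <- length(train_slices)
  bs <- max(1L, min(control$batch_size, n))
  hist <- data.frame(epoch = integer(), d_loss = numeric(),
                     g_adv = numeric(), g_l1 = numeric(),
                     g_total = numeric(), val_l1 = numeric())
  best <- list(val = Inf, w = NULL, state = NULL, epoch = NA_integer_)

  for (epoch in seq_len(control$epochs)) {
    perm <- sample.int(n)
    ep <- c(d_loss = 0, g_adv = 0, g_l1 = 0, g_total = 0)
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      b <- slices_to_batch(train_slices, idx)
      if (!is.null(control$crop)) {
        cr <- as.integer(control$crop)
        xb <- array(0, c(cr, cr, 1L, length(idx)))
        yb <- array(0, c(cr, cr, 1L, length(idx)))
        for (j in seq_along(idx)) {
          rc <- random_crop_pair(b$x[, , 1, j], b$y[, , 1, j], cr)
          xb[, , 1, j] <- rc$nct
          yb[, , 1, j] <- rc$cect
        }
        b <- list(x = xb, y = yb)
      }

      # --- generator forward (training mode) ---
      tp <- nn_tape(train = TRUE)
      xid <- tn_input(tp, b$x)
      gid <- generator_forward(net_g, xid, tape = tp)
      pred <- tp$vals[[gid]]

      # --- discriminator update (detached fake) ---
      par_zero_grads(net_d$ps)
      tpd <- nn_tape(train = TRUE)
      real_id <- tn_input(tpd, abind_ch(b$x, b$y))
      fake_id <- tn_input(tpd, abind_ch(b$x, pred))
      dr_id <- discriminator_forward(net_d, real_id, tape = tpd)
      df_id <- discriminator_forward(net_d, fake_id, tape = tpd)
      d_real <- tpd$vals[[dr_id]]
      d_fake <- tpd$vals[[df_id]]
      d_loss <- discriminator_loss(d_real, d_fake)
      gr <- -(1 / pmax(d_real, 1e-12)) / length(d_real)
      gf <- (1 / pmax(1 - d_fake, 1e-12)) / length(d_fake)
      dim(gr) <- dim(d_real); dim(gf) <- dim(d_fake)
      tn_backward(tpd, c(dr_id, df_id), list(gr, gf))
      opt_step(opt_d, net_d$ps, setdiff(names(net_d$ps$w), net_d$frozen))

      # --- generator update (adversarial gradient through D + L1) ---
      par_zero_grads(net_g$ps)
      par_zero_grads(net_d$ps)    # discarded; D is not stepped here
      pair_id <- tn_concat(tp, c(xid, gid))
      df2_id <- discriminator_forward(net_d, pair_id, tape = tp)
      d_fake2 <- tp$vals[[df2_id]]
      gl <- generator_loss(d_fake2, pred, b$y, control$lambda_l1)
      gadv <- -(1 / pmax(d_fake2, 1e-12)) / length(d_fake2)
      dim(gadv) <- dim(d_fake2)
      gl1 <- control$lambda_l1 * sign(pred - b$y) / length(pred)
      tn_backward(tp, c(df2_id, gid), list(gadv, gl1))
      opt_step(opt_g, net_g$ps, setdiff(names(net_g$ps$w), net_g$frozen))

      if (!is.finite(d_loss) || !is.finite(gl$total))
        stop(sprintf(paste0("training diverged at epoch %d (d_loss = %g, ",
                            "g_loss = %g); lower the learning rates"),
                     epoch, d_loss, gl$total))
      ep <- ep + c(d_loss, gl$adversarial, gl$l1, gl$total)
      nb <- nb + 1L
    }
    val_l1 <- validation_l1(net_g, val_slices, bs)
    hist <- rbind(hist, data.frame(epoch = epoch, d_loss = ep[1] / nb,
                                   g_adv = ep[2] / nb, g_l1 = ep[3] / nb,
                                   g_total = ep[4] / nb, val_l1 = val_l1))
    if (control$verbose)
      message(sprintf("epoch %3d  D %.4f  G %.4f (adv %.4f, L1 %.5f)  val L1 %.5f",
                      epoch, ep[1] / nb, ep[4] / nb, ep[2] / nb, ep[3] / nb,
                      val_l1))
    if (control$checkpoint && val_l1 < best$val) {
      best <- list(val = val_l1, w = net_g$ps$w, state = net_g$ps$state,
                   epoch = epoch)
    }
  }
  if (control$checkpoint && !is.null(best$w)) {
    net_g$ps$w <- best$w
    net_g$ps$state <- best$state
  } else best$epoch <- control$epochs

  structure(list(generator = net_g, discriminator = net_d, history = hist,
                 best_epoch = best$epoch, control = control,
                 preprocess = preprocess),
            class = "scect_gan")
}

abind_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

validation_l1 <- function(net_g, val_slices, batch_size) {
  tot <- 0
  cnt <- 0
  for (start in seq(1L, length(val_slices), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(val_slices))
    b <- slices_to_batch(val_slices, idx)
    pred <- generator_forward(net_g, b$x, train = FALSE)
    tot <- tot + sum(abs(pred - b$y))
    cnt <- cnt + length(pred)
  }
  tot / cnt
}

#' Extract normalized paired training slices from phantom samples
#'
#' Selects axial slices intersecting the heart (optionally subsampled) and
#' returns window-normalized NCT/CECT matrices ready for [scect_gan()].
#'
#' @param samples list of [simulate_pair()] results.
#' @param config a [preprocess_config()].
#' @param stride keep every `stride`-th heart slice.
#' @return list of `list(nct, cect, sample, slice)` elements.
#' @export
phantom_slice_pairs <- function(samples, config = preprocess_config(),
                                stride = 1L) {
  out <- list()
  for (s in samples) {
    hz <- which(apply(s$structures$heart$mask, 3, any))
    keep <- hz[seq(1L, length(hz), by = stride)]
    nctn <- window_normalize(s$pair$nct$voxels, config)
    cectn <- window_normalize(s$pair$cect$voxels, config)
    for (z in keep) {
      out[[length(out) + 1L]] <- list(nct = nctn[, , z], cect = cectn[, , z],
                                      sample = s$index, slice = z)
    }
  }
  out
}

#' @export
print.scect_gan <- function(x, ...) {
  cat("Conditional GAN for synthetic contrast-enhanced CT\n")
  cat(sprintf("  generator:     %.1f M parameters\n",
              count_parameters(x$generator) / 1e6))
  cat(sprintf("  discriminator: %.1f M parameters\n",
              count_parameters(x$discriminator) / 1e6))
  cat(sprintf("  trained %d epochs; best validation L1 %.5f at epoch %d\n",
              nrow(x$history), min(x$history$val_l1), x$best_epoch))
  invisible(x)
}

#' @export
summary.scect_gan <- function(object, ...) {
  h <- object$history
  cat("Training history (normalized intensity scale):\n")
  print(utils::tail(h, 5), row.names = FALSE)
  cat(sprintf("\nvalidation L1: first %.5f, best %.5f (epoch %d), final %.5f\n",
              h$val_l1[1], min(h$val_l1), object$best_epoch,
              h$val_l1[nrow(h)]))
  invisible(object)
}

#' @export
plot.scect_gan <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$g_l1, h$val_l1), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "L1 (normalized scale)",
                    main = "Generator reconstruction loss", ...)
  graphics::legend("topright", c("training L1", "validation L1"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Generate an SCECT volume from an NCT volume
#'
#' Runs the trained generator slice-by-slice over the ROI (the whole volume
#' by default), denormalizes back to HU, and embeds the result into a copy
#' of the NCT so voxels outside the ROI stay bit-identical to the input.
#' Inference is deterministic: evaluation mode disables dropout and uses BN
#' running statistics. Slices whose sides do not divide `2^n_transitions`
#' are symmetrically padded and cropped back.
#'
#' @param object a fitted [scect_gan()] model.
#' @param nct a [ct_volume()] of non-contrast CT.
#' @param roi_center,roi_size optional voxel triple pair restricting
#'   generation to a box (see [crop_roi()]); default is the full volume.
#' @param batch_size slices per forward pass.
#' @param ... unused.
#' @return a [ct_volume()] SCECT.
#' @export
predict.scect_gan <- function(object, nct, roi_center = NULL,
                              roi_size = NULL, batch_size = 8L, ...) {
  stopifnot(inherits(nct, "ct_volume"))
  cfg <- object$preprocess
  if (!is.null(roi_size)) {
    if (is.null(roi_center))
      roi_center <- as.integer(round(dim(nct$voxels) / 2))
    roi <- crop_roi(nct, roi_center, roi_size, pad_value = cfg$window[1])
    roi_origin <- attr(roi, "roi_origin")
    if (any(roi_origin < 1L) ||
        any(roi_origin + dim(roi$voxels) - 1L > dim(nct$voxels)))
      stop("ROI must lie inside the volume for inference embedding")
  } else {
    roi <- nct
    roi_origin <- c(1L, 1L, 1L)
  }
  norm <- window_normalize(roi$voxels, cfg)
  d <- dim(norm)
  div <- 2^object$generator$config$n_transitions
  out <- array(0, d)
  for (start in seq(1L, d[3], by = batch_size)) {
    zs <- start:min(start + batch_size - 1L, d[3])
    pads <- lapply(zs, function(z) pad_to_multiple(norm[, , z], div))
    pd <- dim(pads[[1]]$slice)
    xb <- array(0, c(pd[1], pd[2], 1L, length(zs)))
    for (j in seq_along(zs)) xb[, , 1, j] <- pads[[j]]$slice
    yb <- generator_forward(object$generator, xb, train = FALSE)
    for (j in seq_along(zs))
      out[, , zs[j]] <- pads[[j]]$trim(yb[, , 1, j])
  }
  hu <- denormalize_hu(out, cfg)
  patch <- ct_volume(hu, roi$spacing, roi$origin)
  embed_roi(nct, patch, roi_origin)
}

#' @rdname predict.scect_gan
#' @param model a fitted [scect_gan()] model.
#' @export
infer_volume <- function(model, nct, roi_center = NULL, roi_size = NULL,
                         batch_size = 8L) {
  predict(model, nct, roi_center = roi_center, roi_size = roi_size,
          batch_size = batch_size)
}
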
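#' Generator objective: adversarial + weighted L1
#'
#' The adversarial term is the non-saturating binary cross-entropy of the
#' discriminator's patch map against the real label (1), averaged over
#' patches; the reconstruction term is `lambda_l1` times the mean absolute
#' difference between prediction and target. The decomposition is exact:
#' `total = adversarial + lambda_l1 * mae(pred, target)`.
#'
#' @param d_fake discriminator patch map on the generated pair, values in
#'   (0, 1).
#' @param pred,target generated and reference images (same shape).
#' @param lambda_l1 weight of the L1 term (default 100).
#' @param eps probability clamp guarding `log(0)`.
#' @return list with `total`, `adversarial`, `l1` (the unweighted MAE).
#' @export
generator_loss <- function(d_fake, pred, target, lambda_l1 = 100,
                           eps = 1e-12) {
  if (!identical(dim(pred), dim(target)))
    stop("`pred` and `target` must share shape")
  adv <- -mean(log(pmax(d_fake, eps)))
  l1 <- mean(abs(pred - target))
  list(total = adv + lambda_l1 * l1, adversarial = adv, l1 = l1)
}

#' Discriminator objective
#'
#' Patch-averaged binary cross-entropy pushing real pairs toward 1 and
#' generated pairs toward 0: `BCE(d_real, 1) + BCE(d_fake, 0)`.
#'
#' @param d_real,d_fake discriminator patch maps in (0, 1).
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake, eps = 1e-12) {
  -mean(log(pmax(d_real, eps))) - mean(log(pmax(1 - d_fake, eps)))
}
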
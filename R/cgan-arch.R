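#' Generator configuration (densely connected encoder-decoder)
#'
#' The generator is a 2D fully convolutional densely connected
#' encoder-decoder: a stem convolution, five dense-block / transition-down
#' stages whose concatenated features feed skip connections, a bottleneck
#' dense block, and five transition-up / dense-block stages that concatenate
#' the skips back in, ending in a 1x1 convolution with a bounded (tanh)
#' activation onto the normalized intensity range. Each dense layer is
#' batch-normalization, ReLU, 3x3 convolution, dropout, with its
#' `growth_rate` new feature maps concatenated onto the stack; transition
#' down is BN, ReLU, 1x1 convolution, dropout, 2x2 max-pool; transition up
#' is a 2x2 stride-2 transposed convolution applied to the preceding block's
#' newly produced features.
#'
#' The default depths and growth rate are calibrated so the trainable
#' parameter count is 5.4 M (to one decimal in millions).
#'
#' @param n_transitions number of down/up stages (default 5).
#' @param layers_per_block dense layers in each down stage (mirrored on the
#'   up path); length `n_transitions`.
#' @param bottleneck_layers dense layers in the bottleneck block.
#' @param growth_rate feature maps added per dense layer.
#' @param initial_features stem convolution width.
#' @param dropout_rate dropout after each convolution (training only).
#' @return An object of class `gan_generator_config`.
#' @export
gan_generator_config <- function(n_transitions = 5L,
                                 layers_per_block = c(4L, 5L, 6L, 7L, 8L),
                                 bottleneck_layers = 12L,
                                 growth_rate = 16L,
                                 initial_features = 44L,
                                 dropout_rate = 0.2) {
  n_transitions <- as.integer(n_transitions)
  layers_per_block <- as.integer(layers_per_block)
  if (length(layers_per_block) != n_transitions)
    stop("`layers_per_block` must have length `n_transitions`")
  if (any(c(layers_per_block, bottleneck_layers, growth_rate,
            initial_features) < 1))
    stop("all depth/width counts must be positive")
  structure(list(n_transitions = n_transitions,
                 layers_per_block = layers_per_block,
                 bottleneck_layers = as.integer(bottleneck_layers),
                 growth_rate = as.integer(growth_rate),
                 initial_features = as.integer(initial_features),
                 dropout_rate = dropout_rate),
            class = "gan_generator_config")
}

#' Patch discriminator configuration
#'
#' A patch discriminator over the 2-channel (NCT, candidate) concatenation:
#' four transition-down stages (3x3 convolution, batch normalization except
#' on the first stage, leaky ReLU, 2x2 max-pool) with width doubling each
#' stage, then a 3x3 convolution to a 1-channel map of per-patch sigmoid
#' scores in [0, 1]. The default width is calibrated to 1.6 M trainable
#' parameters.
#'
#' @param n_transitions down-stage count (default 4).
#' @param base_features width of the first stage (doubles per stage).
#' @param patch_output must remain `TRUE`: the output is a score map, not a
#'   scalar.
#' @return An object of class `gan_discriminator_config`.
#' @export
gan_discriminator_config <- function(n_transitions = 4L,
                                     base_features = 64L,
                                     patch_output = TRUE) {
  if (!isTRUE(patch_output))
    stop("the discriminator is patch-based; `patch_output` must be TRUE")
  structure(list(n_transitions = as.integer(n_transitions),
                 base_features = as.integer(base_features),
                 patch_output = TRUE),
            class = "gan_discriminator_config")
}

init_conv <- function(kh, kw, cin, cout, gain = 2) {
  array(stats::rnorm(kh * kw * cin * cout, 0,
                     sqrt(gain / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

add_conv3x3 <- function(ps, name, cin, cout, gain = 2) {
  par_add(ps, paste0(name, "_w"), init_conv(3, 3, cin, cout, gain))
  par_add(ps, paste0(name, "_b"), numeric(cout))
}

add_conv1x1 <- function(ps, name, cin, cout, gain = 2) {
  par_add(ps, paste0(name, "_w"),
          matrix(stats::rnorm(cin * cout, 0, sqrt(gain / cin)), cin, cout))
  par_add(ps, paste0(name, "_b"), numeric(cout))
}

add_convT2x2 <- function(ps, name, cin, cout) {
  par_add(ps, paste0(name, "_w"), init_conv(2, 2, cin, cout))
  par_add(ps, paste0(name, "_b"), numeric(cout))
}

add_bn <- function(ps, name, c) {
  par_add(ps, paste0(name, "_g"), rep(1, c))
  par_add(ps, paste0(name, "_b"), numeric(c))
}

#' Build the generator network
#'
#' Allocates and initializes all trainable parameters (He initialization for
#' inner convolutions, Glorot for the output convolution; BN gamma 1, beta
#' 0). Initialization draws from R's global RNG, so seed beforehand for
#' reproducible weights.
#'
#' @param config a [gan_generator_config()].
#' @return An object of class `scect_generator`.
#' @export
build_generator <- function(config = gan_generator_config()) {
  stopifnot(inherits(config, "gan_generator_config"))
  ps <- nn_params()
  k <- config$growth_rate
  L <- config$layers_per_block
  nt <- config$n_transitions

  add_dense_block <- function(prefix, cin, nlayers) {
    for (j in seq_len(nlayers)) {
      nm <- sprintf("%s_l%d", prefix, j)
      add_bn(ps, paste0(nm, "_bn"), cin)
      add_conv3x3(ps, paste0(nm, "_conv"), cin, k)
      cin <- cin + k
    }
    cin
  }

  add_conv3x3(ps, "stem", 1L, config$initial_features)
  cc <- config$initial_features
  skips <- integer(nt)
  for (i in seq_len(nt)) {
    cc <- add_dense_block(sprintf("down%d", i), cc, L[i])
    skips[i] <- cc
    add_bn(ps, sprintf("td%d_bn", i), cc)
    add_conv1x1(ps, sprintf("td%d_conv", i), cc, cc)
  }
  add_dense_block("bottleneck", cc, config$bottleneck_layers)
  m <- config$bottleneck_layers * k
  for (i in rev(seq_len(nt))) {
    add_convT2x2(ps, sprintf("tu%d", i), m, m)
    cin <- skips[i] + m
    lastc <- add_dense_block(sprintf("up%d", i), cin, L[i])
    m <- L[i] * k
  }
  add_conv1x1(ps, "head", lastc, 1L, gain = 1)

  structure(list(config = config, ps = ps, skips = skips,
                 frozen = character(0)),
            class = c("scect_generator", "scect_network"))
}

# Dense block on the tape; returns list(full = concat id, new = id of the
# concatenation of the block's newly produced features).
tape_dense_block <- function(net, tp, xid, prefix, nlayers, cin, dropout) {
  ps <- net$ps
  k <- net$config$growth_rate
  cur <- xid
  new_ids <- integer(nlayers)
  for (j in seq_len(nlayers)) {
    nm <- sprintf("%s_l%d", prefix, j)
    h <- tn_bn(tp, ps, cur, paste0(nm, "_bn_g"), paste0(nm, "_bn_b"),
               paste0(nm, "_bn"))
    h <- tn_relu(tp, h)
    h <- tn_conv3x3(tp, ps, h, paste0(nm, "_conv_w"), paste0(nm, "_conv_b"))
    h <- tn_dropout(tp, h, dropout)
    new_ids[j] <- h
    cur <- tn_concat(tp, c(cur, h))
  }
  list(full = cur, new = if (nlayers == 1L) new_ids else tn_concat(tp, new_ids))
}

#' Run the generator forward on a batch of slices
#'
#' @param net a [build_generator()] result.
#' @param x `[H, W, 1, N]` array on the normalized intensity scale; H and W
#'   must be divisible by `2^n_transitions`.
#' @param train logical; enables batch statistics and dropout.
#' @param tape optionally, an existing tape (used internally for training).
#' @return with `tape` supplied, the output node id; otherwise the `[H, W,
#'   1, N]` output array.
#' @export
generator_forward <- function(net, x, train = FALSE, tape = NULL) {
  cfg <- net$config
  ret_id <- !is.null(tape)
  tp <- if (ret_id) tape else nn_tape(train = train)
  is_id <- is.null(dim(x)) && length(x) == 1L
  d <- if (is_id) dim(tp$vals[[x]]) else dim(x)
  if (is.null(d) || length(d) != 4L) stop("input must be [H, W, C, N]")
  div <- 2^cfg$n_transitions
  if (d[1] %% div || d[2] %% div)
    stop(sprintf(paste0("generator input sides must be divisible by %d ",
                        "(got %d x %d); pad the slice first ",
                        "(see pad_to_multiple())"), div, d[1], d[2]))
  ps <- net$ps
  xid <- if (is_id) x else tn_input(tp, x)
  h <- tn_conv3x3(tp, ps, xid, "stem_w", "stem_b")
  skips <- integer(cfg$n_transitions)
  for (i in seq_len(cfg$n_transitions)) {
    cin <- dim(tp$vals[[h]])[3]
    db <- tape_dense_block(net, tp, h, sprintf("down%d", i),
                           cfg$layers_per_block[i], cin, cfg$dropout_rate)
    skips[i] <- db$full
    t <- tn_bn(tp, ps, db$full, sprintf("td%d_bn_g", i),
               sprintf("td%d_bn_b", i), sprintf("td%d_bn", i))
    t <- tn_relu(tp, t)
    t <- tn_conv1x1(tp, ps, t, sprintf("td%d_conv_w", i),
                    sprintf("td%d_conv_b", i))
    t <- tn_dropout(tp, t, cfg$dropout_rate)
    h <- tn_maxpool2(tp, t)
  }
  cin <- dim(tp$vals[[h]])[3]
  db <- tape_dense_block(net, tp, h, "bottleneck", cfg$bottleneck_layers,
                         cin, cfg$dropout_rate)
  up <- db$new
  for (i in rev(seq_len(cfg$n_transitions))) {
    u <- tn_convT2x2(tp, ps, up, sprintf("tu%d_w", i), sprintf("tu%d_b", i))
    hcat <- tn_concat(tp, c(skips[i], u))
    cin <- dim(tp$vals[[hcat]])[3]
    db <- tape_dense_block(net, tp, hcat, sprintf("up%d", i),
                           cfg$layers_per_block[i], cin, cfg$dropout_rate)
    up <- db$new
    full <- db$full
  }
  out <- tn_conv1x1(tp, ps, full, "head_w", "head_b")
  out <- tn_tanh(tp, out)
  if (ret_id) out else tp$vals[[out]]
}

#' Build the patch discriminator network
#'
#' @param config a [gan_discriminator_config()].
#' @return An object of class `scect_discriminator`.
#' @export
build_discriminator <- function(config = gan_discriminator_config()) {
  stopifnot(inherits(config, "gan_discriminator_config"))
  ps <- nn_params()
  feats <- config$base_features * 2^(seq_len(config$n_transitions) - 1)
  cin <- 2L
  for (i in seq_len(config$n_transitions)) {
    add_conv3x3(ps, sprintf("d%d_conv", i), cin, feats[i])
    if (i > 1) add_bn(ps, sprintf("d%d_bn", i), feats[i])
    cin <- feats[i]
  }
  add_conv3x3(ps, "d_head", cin, 1L, gain = 1)
  structure(list(config = config, ps = ps, frozen = character(0)),
            class = c("scect_discriminator", "scect_network"))
}

#' Run the discriminator forward
#'
#' @param net a [build_discriminator()] result.
#' @param x `[H, W, 2, N]` array: NCT concatenated with the candidate
#'   (CECT or generated SCECT) along the channel axis.
#' @param train logical; batch statistics when `TRUE`.
#' @param tape optional existing tape (training use).
#' @return with `tape`, the sigmoid-map node id; otherwise the `[H', W', 1,
#'   N]` array of per-patch scores in \[0, 1\].
#' @export
discriminator_forward <- function(net, x, train = FALSE, tape = NULL) {
  cfg <- net$config
  ret_id <- !is.null(tape)
  tp <- if (ret_id) tape else nn_tape(train = train)
  is_id <- is.null(dim(x)) && length(x) == 1L
  if (is_id) {
    xid <- x
    if (dim(tp$vals[[xid]])[3] != 2L)
      stop("discriminator input must have 2 channels (NCT, candidate)")
  } else {
    if (length(dim(x)) != 4L || dim(x)[3] != 2L)
      stop("discriminator input must be [H, W, 2, N] (NCT, candidate)")
    xid <- tn_input(tp, x)
  }
  ps <- net$ps
  h <- xid
  for (i in seq_len(cfg$n_transitions)) {
    h <- tn_conv3x3(tp, ps, h, sprintf("d%d_conv_w", i),
                    sprintf("d%d_conv_b", i))
    if (i > 1)
      h <- tn_bn(tp, ps, h, sprintf("d%d_bn_g", i), sprintf("d%d_bn_b", i),
                 sprintf("d%d_bn", i))
    h <- tn_lrelu(tp, h)
    h <- tn_maxpool2(tp, h)
  }
  h <- tn_conv3x3(tp, ps, h, "d_head_w", "d_head_b")
  out <- tn_sigmoid(tp, h)
  if (ret_id) out else tp$vals[[out]]
}

#' Count trainable parameters of a network
#'
#' Sums the lengths of all trainable parameter arrays (convolution kernels
#' and biases, BN scale/shift); frozen parameters and BN running statistics
#' are excluded.
#'
#' @param network a `scect_network`, or a parameter store.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(network) {
  ps <- if (inherits(network, "scect_network")) network$ps else network
  frozen <- if (inherits(network, "scect_network")) network$frozen
  else character(0)
  nm <- setdiff(names(ps$w), frozen)
  sum(vapply(ps$w[nm], length, integer(1)))
}

#' Freeze named parameters (excluded from counting and updates)
#' @param network a `scect_network`.
#' @param names parameter names to freeze.
#' @export
freeze_parameters <- function(network, names) {
  network$frozen <- union(network$frozen, names)
  network
}

#' @export
print.scect_network <- function(x, ...) {
  kind <- if (inherits(x, "scect_generator")) "generator" else "discriminator"
  cat(sprintf("<scect %s> %s trainable parameters (%.1f M)\n", kind,
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}
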
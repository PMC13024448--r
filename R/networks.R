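# ---------------------------------------------------------------------------
# MyoNet and ResMyoNet: five-level spatiotemporal U-Nets regressing
# normalized x/y displacement fields from binary cine mask sequences.
#
# Each level pairs a spatial 1x3x3 convolution with a temporal 3x1x1
# convolution (alternating kernels); the two deepest encoder levels dilate
# them (spatial 1x2x2, temporal 2x1x1) to widen the receptive field. Pooling
# is spatial-only (1x2x2): the temporal axis is never downsampled (20-frame
# sequences cannot be halved five times). The decoder mirrors the encoder
# with nearest-neighbor 1x2x2 upsampling and skip concatenation; the head is
# a 1x1x1 convolution to 2 channels with a sigmoid, bounding outputs to the
# normalized displacement scale (0, 1).
#
# MyoNet levels are conv-BN-ReLU pairs. ResMyoNet levels are residual
# blocks: main path conv-BN-ReLU-conv-BN, identity (or 1x1x1 projection)
# shortcut, summed then passed through tanh.
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' @param variant `"myonet"` or `"resmyonet"`.
#' @param base_channels channels of the first level (doubled per level).
#' @param channel_cap maximum channels at depth.
#' @param dilated_levels encoder levels (1-based, of 5) whose convolutions
#'   are dilated; default the two deepest.
#' @param seed RNG seed for parameter initialization.
#' @return a `network_config` object. Levels (5), kernel sizes, dilation
#'   rates and output channels (2) are architectural constants.
#' @export
network_config <- function(variant = c("myonet", "resmyonet"),
                           base_channels = 16, channel_cap = 256,
                           dilated_levels = c(4L, 5L), seed = 1L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, levels = 5L,
                 base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap),
                 spatial_kernel = c(1L, 3L, 3L), temporal_kernel = c(3L, 1L, 1L),
                 spatial_dilation = c(1L, 2L, 2L), temporal_dilation = c(2L, 1L, 1L),
                 dilated_levels = as.integer(dilated_levels),
                 out_channels = 2L, seed = as.integer(seed)),
            class = "network_config")
}

make_block <- function(cfg, cin, cout, dilated = FALSE) {
  sd_ <- if (dilated) cfg$spatial_dilation else c(1L, 1L, 1L)
  td_ <- if (dilated) cfg$temporal_dilation else c(1L, 1L, 1L)
  if (cfg$variant == "myonet") {
    list(kind = "seq", layers = list(
      make_conv(cin, cout, cfg$spatial_kernel, sd_),
      make_bn(cout), make_act("relu"),
      make_conv(cout, cout, cfg$temporal_kernel, td_),
      make_bn(cout), make_act("relu")))
  } else {
    list(kind = "res",
         main = list(
           make_conv(cin, cout, cfg$spatial_kernel, sd_),
           make_bn(cout), make_act("relu"),
           make_conv(cout, cout, cfg$temporal_kernel, td_),
           make_bn(cout)),
         shortcut = if (cin == cout) NULL else make_conv(cin, cout, c(1L, 1L, 1L)))
  }
}

block_forward <- function(block, x, train) {
  if (block$kind == "seq") {
    r <- seq_forward(block$layers, x, train)
    block$layers <- r$layers
    return(list(y = r$y, cache = list(seq = r$caches), block = block))
  }
  rm_ <- seq_forward(block$main, x, train)
  block$main <- rm_$layers
  if (is.null(block$shortcut)) {
    s <- x
    sc_cache <- NULL
  } else {
    rs <- conv_forward(block$shortcut, x)
    s <- rs$y
    sc_cache <- rs$cache
  }
  z <- rm_$y + s
  y <- tanh(z)
  list(y = y, cache = list(seq = rm_$caches, sc = sc_cache, tanh_y = y),
       block = block)
}

block_backward <- function(block, cache, dy) {
  if (block$kind == "seq") {
    r <- seq_backward(block$layers, cache$seq, dy)
    return(list(dx = r$dx, grads = list(seq = r$grads)))
  }
  dz <- dy * (1 - cache$tanh_y^2)
  rmain <- seq_backward(block$main, cache$seq, dz)
  if (is.null(block$shortcut)) {
    dx <- rmain$dx + dz
    gsc <- NULL
  } else {
    rsc <- conv_backward(block$shortcut, cache$sc, dz)
    dx <- rmain$dx + rsc$dx
    gsc <- rsc$grads
  }
  list(dx = dx, grads = list(seq = rmain$grads, sc = gsc))
}

#' Build a MyoNet or ResMyoNet model
#'
#' Parameter initialization is Kaiming fan-in for convolution weights and
#' zeros for biases, drawn from a seeded RNG so two builds from the same
#' configuration are identical.
#'
#' @param cfg a [network_config].
#' @param in_channels input channels (1 for binary cine masks).
#' @return a `myonet_model` list: encoder blocks, decoder blocks, head.
#' @export
build_network <- function(cfg, in_channels = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  if (!cfg$variant %in% c("myonet", "resmyonet"))
    stop("unsupported variant: ", cfg$variant)
  set.seed(cfg$seed)
  ch <- pmin(cfg$base_channels * 2^(seq_len(cfg$levels) - 1), cfg$channel_cap)
  enc <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    cin <- if (l == 1) in_channels else ch[l - 1]
    enc[[l]] <- make_block(cfg, cin, ch[l], dilated = l %in% cfg$dilated_levels)
  }
  dec <- vector("list", cfg$levels - 1)
  for (l in seq_len(cfg$levels - 1)) {  # decoder level l consumes ch[l+1] + ch[l]
    dec[[l]] <- make_block(cfg, ch[l + 1] + ch[l], ch[l], dilated = FALSE)
  }
  head_ <- make_conv(ch[1], cfg$out_channels, c(1L, 1L, 1L))
  structure(list(cfg = cfg, channels = ch, enc = enc, dec = dec, head = head_,
                 in_channels = as.integer(in_channels)),
            class = "myonet_model")
}

#' @export
print.myonet_model <- function(x, ...) {
  cat(sprintf("<%s> levels %d, channels %s, %d parameters\n",
              x$cfg$variant, x$cfg$levels, paste(x$channels, collapse = "-"),
              parameter_count(x)))
  invisible(x)
}

count_layer <- function(l) {
  if (is.null(l)) return(0L)
  switch(l$type,
         conv = length(l$W) + length(l$b),
         bn = length(l$gamma) + length(l$beta),
         0L)
}

count_block <- function(b) {
  if (b$kind == "seq") sum(vapply(b$layers, count_layer, integer(1)))
  else sum(vapply(b$main, count_layer, integer(1))) + count_layer(b$shortcut)
}

#' Number of trainable parameters of a model
#' @param model a `myonet_model`.
#' @return integer count.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$enc, count_block, integer(1))) +
    sum(vapply(model$dec, count_block, integer(1))) +
    count_layer(model$head)
}

# full forward pass; returns prediction plus caches for backprop and the
# model with updated batch-norm running statistics
net_forward <- function(model, x, train = FALSE) {
  d <- dim(x)
  div <- 2^(model$cfg$levels - 1)
  if (d[3] %% div != 0 || d[4] %% div != 0)
    stop(sprintf("H and W must be divisible by %d (5 levels); got %dx%d",
                 div, d[3], d[4]))
  L <- model$cfg$levels
  skips <- vector("list", L - 1)
  enc_caches <- vector("list", L)
  pool_caches <- vector("list", L - 1)
  h <- x
  for (l in seq_len(L - 1)) {
    r <- block_forward(model$enc[[l]], h, train)
    model$enc[[l]] <- r$block
    enc_caches[[l]] <- r$cache
    skips[[l]] <- r$y
    p <- maxpool_forward(r$y)
    pool_caches[[l]] <- p$cache
    h <- p$y
  }
  r <- block_forward(model$enc[[L]], h, train)
  model$enc[[L]] <- r$block
  enc_caches[[L]] <- r$cache
  h <- r$y
  dec_caches <- vector("list", L - 1)
  up_caches <- vector("list", L - 1)
  cat_c1 <- integer(L - 1)
  for (l in rev(seq_len(L - 1))) {
    u <- upsample_forward(h)
    up_caches[[l]] <- u$cache
    cc <- concat_channels(u$y, skips[[l]])
    cat_c1[l] <- cc$c1
    r <- block_forward(model$dec[[l]], cc$y, train)
    model$dec[[l]] <- r$block
    dec_caches[[l]] <- r$cache
    h <- r$y
  }
  hf <- conv_forward(model$head, h)
  y <- 1 / (1 + exp(-hf$y))
  list(y = y, model = model,
       cache = list(enc = enc_caches, pool = pool_caches, dec = dec_caches,
                    up = up_caches, cat_c1 = cat_c1, head = hf$cache, sig_y = y))
}

net_backward <- function(model, cache, dy) {
  L <- model$cfg$levels
  dz <- dy * cache$sig_y * (1 - cache$sig_y)
  rh <- conv_backward(model$head, cache$head, dz)
  g <- list(enc = vector("list", L), dec = vector("list", L - 1), head = rh$grads)
  dh <- rh$dx
  dskips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    r <- block_backward(model$dec[[l]], cache$dec[[l]], dh)
    g$dec[[l]] <- r$grads
    sp <- split_channels(r$dx, cache$cat_c1[l])
    dskips[[l]] <- sp$db
    dh <- upsample_backward(cache$up[[l]], sp$da)
  }
  r <- block_backward(model$enc[[L]], cache$enc[[L]], dh)
  g$enc[[L]] <- r$grads
  dh <- r$dx
  for (l in rev(seq_len(L - 1))) {
    dpool <- maxpool_backward(cache$pool[[l]], dh)
    r <- block_backward(model$enc[[l]], cache$enc[[l]], dpool + dskips[[l]])
    g$enc[[l]] <- r$grads
    dh <- r$dx
  }
  list(grads = g, dx = dh)
}

#' Run a model on a cine mask sequence
#'
#' @param model a `myonet_model` (evaluation mode: batch-norm running
#'   statistics are used; the pass is deterministic).
#' @param masks a [cine_sequence], or a numeric array `(1, T, H, W)`.
#' @return predicted normalized displacement array `(2, T, H, W)`, all
#'   values in (0, 1): channel 1 = x, channel 2 = y.
#' @export
forward <- function(model, masks) {
  stopifnot(inherits(model, "myonet_model"))
  x <- if (inherits(masks, "cine_sequence")) {
    d <- dim(masks$frames)
    array(aperm(masks$frames, c(3, 1, 2)), dim = c(1, d[3], d[1], d[2]))
  } else as.array(masks)
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  r <- net_forward(model, x, train = FALSE)
  y <- r$y
  dim(y) <- dim(y)[1:4]
  y
}

# --- RMSprop ---------------------------------------------------------------

rmsprop_layer <- function(l, g, lr, alpha, eps) {
  if (is.null(g)) return(l)
  upd <- function(p, gr, v) {
    if (is.null(v)) v <- p * 0
    v <- alpha * v + (1 - alpha) * gr^2
    list(p = p - lr * gr / (sqrt(v) + eps), v = v)
  }
  if (l$type == "conv") {
    uW <- upd(l$W, g$W, l$vW); ub <- upd(l$b, g$b, l$vb)
    l$W <- uW$p; l$vW <- uW$v; l$b <- ub$p; l$vb <- ub$v
  } else if (l$type == "bn") {
    ug <- upd(l$gamma, g$gamma, l$vgamma); ub <- upd(l$beta, g$beta, l$vbeta)
    l$gamma <- ug$p; l$vgamma <- ug$v; l$beta <- ub$p; l$vbeta <- ub$v
  }
  l
}

rmsprop_block <- function(b, g, lr, alpha, eps) {
  if (b$kind == "seq") {
    for (i in seq_along(b$layers))
      b$layers[[i]] <- rmsprop_layer(b$layers[[i]], g$seq[[i]], lr, alpha, eps)
  } else {
    for (i in seq_along(b$main))
      b$main[[i]] <- rmsprop_layer(b$main[[i]], g$seq[[i]], lr, alpha, eps)
    if (!is.null(b$shortcut))
      b$shortcut <- rmsprop_layer(b$shortcut, g$sc, lr, alpha, eps)
  }
  b
}

rmsprop_step <- function(model, grads, lr = 1e-3, alpha = 0.99, eps = 1e-8) {
  for (l in seq_along(model$enc))
    model$enc[[l]] <- rmsprop_block(model$enc[[l]], grads$enc[[l]], lr, alpha, eps)
  for (l in seq_along(model$dec))
    model$dec[[l]] <- rmsprop_block(model$dec[[l]], grads$dec[[l]], lr, alpha, eps)
  model$head <- rmsprop_layer(model$head, grads$head, lr, alpha, eps)
  model
}

# --- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Stores parameters, configuration, the attached displacement scale and
#' training metadata in a single file (RDS).
#'
#' @param model a `myonet_model`.
#' @param path output file.
#' @param scale [affine_scale] used for the training targets.
#' @param meta list of metadata (epoch, validation loss, seed...).
#' @export
save_checkpoint <- function(model, path, scale = NULL, meta = list()) {
  saveRDS(list(model = model, scale = scale, meta = meta,
               parameter_count = parameter_count(model)), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return list with `model`, `scale`, `meta`, `parameter_count`.
#' @export
load_checkpoint <- function(path) readRDS(path)
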
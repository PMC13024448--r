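# ---------------------------------------------------------------------------
# Scan-level splitting, flip augmentation, the RMSprop training loop, and
# the 1 - normalized-MSE accuracy metric.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol: RMSprop at learning rate 1e-3,
#' batch size 4, 100 epochs, 80/10/10 scan-level split, random horizontal
#' and vertical flips, model selection by best validation loss.
#'
#' @param learning_rate RMSprop learning rate.
#' @param batch_size samples per optimization step.
#' @param epochs training epochs.
#' @param split train/val/test fractions summing to 1.
#' @param augment_flips character subset of `c("horizontal", "vertical")`.
#' @param flip_prob per-axis flip probability per training sample per epoch.
#' @param seed seed for data order and augmentation.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 4L, epochs = 100L,
                         split = c(0.8, 0.1, 0.1),
                         augment_flips = c("horizontal", "vertical"),
                         flip_prob = 0.5, seed = 1L) {
  stopifnot(batch_size >= 1, abs(sum(split) - 1) < 1e-9)
  structure(list(optimizer = "rmsprop", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 split = split, augment_flips = augment_flips,
                 flip_prob = flip_prob, seed = as.integer(seed),
                 selection = "best_validation_loss"),
            class = "train_config")
}

#' Deterministic scan-level train/validation/test split
#'
#' Scans (not slices) are shuffled by seed and assigned whole to one set, so
#' no slice of a scan can leak across sets. Validation and test each receive
#' `max(1, round(fraction * N))` scans; the remainder trains.
#'
#' @param scan_ids character/atomic vector of unique scan identifiers (>= 3).
#' @param fractions train/val/test fractions.
#' @param seed integer seed.
#' @return a `split_assignment`: list with `train`, `val`, `test` id vectors
#'   and `assignment`, a named vector scan_id -> set.
#' @export
split_scans <- function(scan_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  scan_ids <- unique(scan_ids)
  N <- length(scan_ids)
  if (N < 3) stop("need at least 3 scans to form train/val/test sets")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  perm <- local({ set.seed(seed); sample(scan_ids) })
  n_val <- max(1L, round(fractions[2] * N))
  n_test <- max(1L, round(fractions[3] * N))
  if (n_val + n_test >= N)
    stop("split leaves no training scans")
  test <- perm[seq_len(n_test)]
  val <- perm[n_test + seq_len(n_val)]
  train <- perm[-(seq_len(n_test + n_val))]
  asn <- setNames(rep(c("test", "val", "train"), c(n_test, n_val, N - n_val - n_test)),
                  c(test, val, train))
  structure(list(train = train, val = val, test = test,
                 assignment = asn[scan_ids]),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d train / %d val / %d test scans\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Jointly flip a cine sequence and its displacement sequence
#'
#' Mirrors the images along the chosen axis and fixes up the vector field:
#' a horizontal flip (mirroring columns) negates the x component, a vertical
#' flip (mirroring rows) negates the y component; both component fields are
#' mirrored. The negation happens on the signed (mm) scale; normalized
#' fields are re-derived through the attached scale.
#'
#' @param cine a [cine_sequence].
#' @param disp a [displacement_sequence].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return list `cine`, `displacement`, flipped.
#' @export
augment_flip <- function(cine, disp, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  flip_arr <- function(a) {
    if (axis == "horizontal") a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
    else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  }
  m <- flip_arr(cine$frames)
  ux <- flip_arr(disp$ux); uy <- flip_arr(disp$uy)
  if (axis == "horizontal") ux <- -ux else uy <- -uy
  fg <- flip_arr(disp$foreground_mask * 1) != 0
  out <- displacement_sequence(ux, uy, fg, disp$pixel_spacing,
                               disp$scan_id, disp$slice_id)
  if (!is.null(disp$scale)) out <- attach_scale(out, disp$scale)
  list(cine = cine_sequence(m, cine$pixel_spacing, cine$scan_id, cine$slice_id),
       displacement = out)
}

# flip of packed training tensors: input (1,T,H,W), target normalized
# (2,T,H,W). Spatial axes of the packed layout are dims 3 (rows) and 4
# (cols). Negation of the flipped component goes through the signed scale.
flip_sample <- function(input, target, axis, scale) {
  flip4 <- function(a, d) {
    idx <- rev(seq_len(dim(a)[d]))
    if (d == 3) a[, , idx, , drop = FALSE] else a[, , , idx, drop = FALSE]
  }
  d <- if (axis == "horizontal") 4L else 3L
  input <- flip4(input, d)
  target <- flip4(target, d)
  comp <- if (axis == "horizontal") 1L else 2L
  v <- target[comp, , , , drop = FALSE]
  fg <- v >= FOREGROUND_THRESHOLD
  signed <- denormalize_displacement(v, scale)
  v2 <- v
  v2[fg] <- normalize_displacement(-signed[fg], scale)
  target[comp, , , ] <- v2
  list(input = input, target = target)
}

#' Training accuracy: one minus the normalized mean squared error
#'
#' MSE is taken on the normalized \[0, 1\] displacement scale (unit dynamic
#' range), so a perfect prediction scores 1.
#'
#' @param pred,target arrays `(2, T, H, W[, B])` on the normalized scale.
#' @return scalar in `(-Inf, 1]`.
#' @export
accuracy <- function(pred, target) 1 - mse_loss(pred, target)

stack_samples <- function(samples, field) {
  arrs <- lapply(samples, `[[`, field)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(d, length(arrs)))
  for (i in seq_along(arrs)) out[, , , , i] <- arrs[[i]]
  out
}

#' Train a model on displacement-regression samples
#'
#' Minimizes the combined loss ([total_loss()]) with RMSprop, recording a
#' per-epoch history for the training and validation sets and returning the
#' parameters of the epoch with the lowest validation total loss. Fully
#' seeded: data order, augmentation draws and (via [build_network()]) the
#' initialization are reproducible.
#'
#' @param model a freshly built `myonet_model`.
#' @param data list with `train` and `val`: lists of samples, each a list
#'   with `input` `(1, T, H, W)` mask tensor and `target` `(2, T, H, W)`
#'   normalized displacement tensor; and `scale`, the [affine_scale] of the
#'   targets (needed for flip augmentation).
#' @param cfg a [train_config].
#' @return list: `model` (best-validation parameters), `history` tibble
#'   (epoch, split, l_mse, l_smooth, l_custom, l_total, accuracy),
#'   `best_epoch`.
#' @export
train_model <- function(model, data, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(data$train) == 0 || length(data$val) == 0)
    stop("train and validation sets must be nonempty")
  set.seed(cfg$seed)
  # prior-matched head initialization: start the sigmoid output at the mean
  # of the training targets instead of 0.5, so early steps fit displacement
  # structure rather than the background level
  mt <- mean(vapply(data$train, function(s) mean(s$target), numeric(1)))
  mt <- min(max(mt, 1e-3), 1 - 1e-3)
  model$head$b[] <- log(mt / (1 - mt))
  hist <- list()
  best <- list(loss = Inf, epoch = NA_integer_, model = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(data$train))
    ep_loss <- c(l_mse = 0, l_smooth = 0, l_custom = 0, l_total = 0)
    n_seen <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      batch <- lapply(data$train[idx], function(s) {
        for (ax in cfg$augment_flips)
          if (runif(1) < cfg$flip_prob) {
            fs <- flip_sample(s$input, s$target, ax, data$scale)
            s$input <- fs$input; s$target <- fs$target
          }
        s
      })
      x <- stack_samples(batch, "input")
      tg <- stack_samples(batch, "target")
      fw <- net_forward(model, x, train = TRUE)
      model <- fw$model
      lb <- total_loss(fw$y, tg)
      if (!is.finite(lb$l_total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      dy <- total_loss_grad(fw$y, tg)
      bw <- net_backward(model, fw$cache, dy)
      model <- rmsprop_step(model, bw$grads, lr = cfg$learning_rate)
      w <- length(idx)
      ep_loss <- ep_loss + w * c(lb$l_mse, lb$l_smooth, lb$l_custom, lb$l_total)
      n_seen <- n_seen + w
    }
    ep_loss <- ep_loss / n_seen
    hist[[length(hist) + 1]] <- tibble::tibble(
      epoch = epoch, split = "train",
      l_mse = ep_loss[1], l_smooth = ep_loss[2], l_custom = ep_loss[3],
      l_total = ep_loss[4], accuracy = 1 - ep_loss[1])
    # validation in evaluation mode
    xv <- stack_samples(data$val, "input")
    tv <- stack_samples(data$val, "target")
    fv <- net_forward(model, xv, train = FALSE)
    lv <- total_loss(fv$y, tv)
    hist[[length(hist) + 1]] <- tibble::tibble(
      epoch = epoch, split = "val",
      l_mse = lv$l_mse, l_smooth = lv$l_smooth, l_custom = lv$l_custom,
      l_total = lv$l_total, accuracy = accuracy(fv$y, tv))
    if (lv$l_total < best$loss) {
      best$loss <- lv$l_total
      best$epoch <- epoch
      best$model <- model
    }
  }
  list(model = best$model, history = dplyr::bind_rows(hist),
       best_epoch = best$epoch)
}

#' Predict a signed displacement sequence from a cine sequence
#'
#' Runs the model in evaluation mode and inverts the affine normalization:
#' pixels whose predicted normalized value falls below the foreground
#' threshold in either component are background (signed fields set to 0 and
#' excluded from the foreground mask).
#'
#' @param model a trained `myonet_model`.
#' @param cine a [cine_sequence].
#' @param scale the [affine_scale] the model was trained against.
#' @return a [displacement_sequence] with both signed and normalized fields.
#' @export
predict_displacement <- function(model, cine, scale) {
  y <- forward(model, cine)          # (2, T, H, W), normalized
  d <- dim(cine$frames)              # (H, W, T)
  nx <- aperm(y[1, , , , drop = TRUE], c(2, 3, 1))
  ny <- aperm(y[2, , , , drop = TRUE], c(2, 3, 1))
  fg <- nx >= FOREGROUND_THRESHOLD & ny >= FOREGROUND_THRESHOLD
  ux <- denormalize_displacement(nx, scale)
  uy <- denormalize_displacement(ny, scale)
  ux[!fg] <- 0; uy[!fg] <- 0
  ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
  out <- displacement_sequence(ux, uy, fg, cine$pixel_spacing,
                               cine$scan_id, cine$slice_id)
  out$scale <- scale
  out$normalized_x <- nx
  out$normalized_y <- ny
  out
}
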
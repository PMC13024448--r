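# ---------------------------------------------------------------------------
# Training objective: L_total = L_MSE + L_smooth + L_custom
#
# All three terms operate on NORMALIZED displacement fields (the scale the
# networks predict on): arrays of shape (2, T, H, W) or (2, T, H, W, B),
# channel 1 = x, channel 2 = y. Conventions:
#   * L_MSE: per-frame mean over pixels of (dx^2 + dy^2), then mean over
#     frames (and batch).
#   * L_smooth: component-wise Huber with delta = 1 (0.5 d^2 below, |d|-0.5
#     above), summed over the two components, averaged over pixels/frames.
#   * L_custom: squared error restricted to pixels where BOTH target
#     components exceed the 0.125 foreground threshold, normalized by the
#     per-frame foreground count m (0 when m = 0), averaged over frames.
# ---------------------------------------------------------------------------

check_pair <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("prediction and target shapes differ: [",
         paste(dim(pred), collapse = ","), "] vs [",
         paste(dim(target), collapse = ","), "]")
  nd <- length(dim(pred))
  if (!(nd %in% c(4L, 5L)) || dim(pred)[1] != 2L)
    stop("displacement tensors must be (2, T, H, W) or (2, T, H, W, B)")
}

# reshape to (2, T, P, B) with P = H*W for frame-wise reductions
as_frames <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) d <- c(d, 1L)
  array(x, dim = c(d[1], d[2], d[3] * d[4], d[5]))
}

#' Mean-squared-error displacement loss
#'
#' Mean over frames (and batch) of the per-frame pixel mean of
#' `(x - x_hat)^2 + (y - y_hat)^2` on the normalized scale.
#'
#' @param pred,target numeric arrays `(2, T, H, W[, B])`.
#' @return nonnegative scalar.
#' @export
mse_loss <- function(pred, target) {
  check_pair(pred, target)
  d <- as_frames(pred - target)
  # sum over components, mean over pixels, frames, batch
  mean(apply(d^2, c(2, 3, 4), sum))
}

#' Smooth-L1 displacement loss
#'
#' Per pixel: `0.5 (dx^2 + dy^2)` when both `|dx| < 1` and `|dy| < 1`, and
#' `|dx| + |dy| - 0.5` otherwise, averaged over pixels, frames and batch.
#' Quadratic near zero like L2, linear in the tails like L1; continuous at
#' the branch boundary when one component crosses 1 while the other is 0.
#'
#' @inheritParams mse_loss
#' @return nonnegative scalar.
#' @export
smooth_l1_loss <- function(pred, target) {
  check_pair(pred, target)
  d <- as_frames(pred - target)
  dims <- dim(d)[-1]
  dx <- array(d[1, , , , drop = FALSE], dim = dims)
  dy <- array(d[2, , , , drop = FALSE], dim = dims)
  small <- abs(dx) < 1 & abs(dy) < 1
  h <- ifelse(small, 0.5 * (dx^2 + dy^2), abs(dx) + abs(dy) - 0.5)
  mean(h)
}

#' Foreground-masked displacement loss
#'
#' Emphasizes errors on the tagged myocardium: per frame, the squared error
#' `z = (x - x_hat)^2 + (y - y_hat)^2` is accumulated only at pixels where
#' both TARGET components exceed the foreground threshold 0.125, divided by
#' the count `m` of such pixels (0 when the frame has none), then averaged
#' over frames and batch. Thresholding on the target (not the prediction)
#' keeps gradients alive exactly where learning is needed.
#'
#' @inheritParams mse_loss
#' @param debug return per-frame terms alongside the scalar.
#' @return scalar, or (with `debug`) list with `loss`, per-frame `m` and
#'   per-frame loss values.
#' @export
custom_masked_loss <- function(pred, target, debug = FALSE) {
  check_pair(pred, target)
  p <- as_frames(pred); tg <- as_frames(target)
  fg <- (tg[1, , , , drop = FALSE] > FOREGROUND_THRESHOLD) &
        (tg[2, , , , drop = FALSE] > FOREGROUND_THRESHOLD)
  fg <- array(fg, dim = dim(p)[-1])            # (T, P, B)
  z <- (p[1, , , ] - tg[1, , , ])^2 + (p[2, , , ] - tg[2, , , ])^2
  z <- array(z, dim = dim(fg))
  z[!fg] <- 0
  m <- apply(fg, c(1, 3), sum)                  # (T, B) foreground counts
  s <- apply(z, c(1, 3), sum)
  per_frame <- ifelse(m > 0, s / pmax(m, 1), 0)
  loss <- mean(per_frame)
  if (debug) list(loss = loss, m = m, per_frame = per_frame) else loss
}

#' Combined training loss
#'
#' @inheritParams mse_loss
#' @param debug include per-frame foreground bookkeeping of the masked term.
#' @return a `loss_breakdown` list: `l_mse`, `l_smooth`, `l_custom`,
#'   `l_total` (exact sum of the three).
#' @export
total_loss <- function(pred, target, debug = FALSE) {
  check_pair(pred, target)
  l1 <- mse_loss(pred, target)
  l2 <- smooth_l1_loss(pred, target)
  cm <- custom_masked_loss(pred, target, debug = debug)
  l3 <- if (debug) cm$loss else cm
  out <- list(l_mse = l1, l_smooth = l2, l_custom = l3,
              l_total = l1 + l2 + l3)
  if (debug) out$custom_detail <- cm
  structure(out, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.6g = mse %.6g + smooth %.6g + custom %.6g\n",
              x$l_total, x$l_mse, x$l_smooth, x$l_custom))
  invisible(x)
}

# Gradient of the combined loss wrt the prediction; same shape as pred.
# Kept internal: only the optimizer needs it.
total_loss_grad <- function(pred, target) {
  check_pair(pred, target)
  d0 <- dim(pred)
  batched <- length(d0) == 5L
  p <- as_frames(pred); tg <- as_frames(target)
  d <- p - tg
  Tn <- dim(d)[2]; P <- dim(d)[3]; B <- dim(d)[4]
  # MSE: d/dpred mean_frames mean_pix sum_c d^2 = 2 d / (T*P*B)
  g_mse <- 2 * d / (Tn * P * B)
  # smooth L1 (joint branch condition): quadratic branch -> d_c, linear
  # branch -> sign(d_c), per component
  dxs <- array(d[1, , , , drop = FALSE], dim = c(Tn, P, B))
  dys <- array(d[2, , , , drop = FALSE], dim = c(Tn, P, B))
  small <- abs(dxs) < 1 & abs(dys) < 1
  g_sm <- array(0, dim = dim(d))
  g_sm[1, , , ] <- ifelse(small, dxs, sign(dxs)) / (Tn * P * B)
  g_sm[2, , , ] <- ifelse(small, dys, sign(dys)) / (Tn * P * B)
  # custom: 2 d * fg / (T * B * m_frame)
  fg <- (tg[1, , , , drop = FALSE] > FOREGROUND_THRESHOLD) &
        (tg[2, , , , drop = FALSE] > FOREGROUND_THRESHOLD)
  fg <- array(fg, dim = c(Tn, P, B))
  m <- apply(fg, c(1, 3), sum)                  # (T, B)
  minv <- ifelse(m > 0, 1 / m, 0)
  # broadcast (T, B) over pixels
  wfull <- aperm(array(minv, dim = c(Tn, B, P)), c(1, 3, 2)) * fg
  d1 <- array(d[1, , , , drop = FALSE], dim = c(Tn, P, B))
  d2 <- array(d[2, , , , drop = FALSE], dim = c(Tn, P, B))
  g_cu <- array(0, dim = dim(d))
  g_cu[1, , , ] <- 2 * d1 * wfull / (Tn * B)
  g_cu[2, , , ] <- 2 * d2 * wfull / (Tn * B)
  g <- g_mse + g_sm + g_cu
  array(g, dim = d0)
}
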
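# Shared fixtures: everything is generated in code at test time.

# small phantom used across tests: 32x32, 8 frames, 1 mm/px
tiny_spec <- function(...) small_phantom_spec(grid_size = 32, n_frames = 8, ...)

# a seeded pair of random normalized displacement tensors (2, T, H, W)
random_pair <- function(seed = 1, Tn = 3, H = 4, W = 5, B = NULL) {
  set.seed(seed)
  d <- c(2, Tn, H, W, B)
  pred <- array(runif(prod(d)), dim = d)
  target <- array(runif(prod(d)), dim = d)
  list(pred = pred, target = target)
}

# annulus mask on an H x H grid (pixel units), center at half-integer
annulus_mask <- function(H = 41, ri = 6, ro = 14, center = c((H - 1) / 2, (H - 1) / 2)) {
  dy <- matrix((seq_len(H) - 1) - center[1], H, H)
  dx <- matrix((seq_len(H) - 1) - center[2], H, H, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  list(mask = (r >= ri & r <= ro) * 1, dx = dx, dy = dy, center = center)
}

# naive double-loop loss oracles (independent of the vectorized implementation)
naive_mse <- function(pred, target) {
  d <- dim(pred)
  acc <- 0
  for (t in seq_len(d[2])) {
    s <- 0
    for (h in seq_len(d[3])) for (w in seq_len(d[4]))
      s <- s + (pred[1, t, h, w] - target[1, t, h, w])^2 +
               (pred[2, t, h, w] - target[2, t, h, w])^2
    acc <- acc + s / (d[3] * d[4])
  }
  acc / d[2]
}

naive_smooth_l1 <- function(pred, target) {
  d <- dim(pred)
  acc <- 0
  for (t in seq_len(d[2])) {
    s <- 0
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      dx <- pred[1, t, h, w] - target[1, t, h, w]
      dy <- pred[2, t, h, w] - target[2, t, h, w]
      s <- s + if (abs(dx) < 1 && abs(dy) < 1) 0.5 * (dx^2 + dy^2)
               else abs(dx) + abs(dy) - 0.5
    }
    acc <- acc + s / (d[3] * d[4])
  }
  acc / d[2]
}

naive_custom <- function(pred, target, thr = 0.125) {
  d <- dim(pred)
  acc <- 0
  for (t in seq_len(d[2])) {
    s <- 0; m <- 0
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      if (target[1, t, h, w] > thr && target[2, t, h, w] > thr) {
        m <- m + 1
        s <- s + (pred[1, t, h, w] - target[1, t, h, w])^2 +
                 (pred[2, t, h, w] - target[2, t, h, w])^2
      }
    }
    acc <- acc + if (m > 0) s / m else 0
  }
  acc / d[2]
}

# windowed brute-force SSIM oracle: explicit loop over valid window centers
loop_ssim <- function(a, b, L = 1) {
  r <- 5
  g1 <- exp(-(-r:r)^2 / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  wts <- outer(g1, g1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in (r + 1):(H - r)) for (j in (r + 1):(W - r)) {
    wa <- a[(i - r):(i + r), (j - r):(j + r)]
    wb <- b[(i - r):(i + r), (j - r):(j + r)]
    mua <- sum(wts * wa); mub <- sum(wts * wb)
    va <- sum(wts * wa^2) - mua^2
    vb <- sum(wts * wb^2) - mub^2
    cab <- sum(wts * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# two-way ANOVA ICC(2,1) oracle via stats::aov mean squares
aov_icc21 <- function(x, y) {
  n <- length(x)
  df <- data.frame(y = c(x, y),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# textbook paired t-test oracle
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# pooled predicted-vs-analytic peak segment strains of a pipeline result
peak_strain_pairs <- function(result) {
  out <- lapply(result$test, function(d) {
    pk_pred <- peak_strain(d$strain[d$strain$segment != "global", ])
    tru <- d$truth
    pk_tru <- peak_strain(tibble::tibble(
      frame = tru$frame, segment = as.character(tru$segment),
      Ecc_percent = tru$Ecc_percent, Err_percent = tru$Err_percent))
    m <- match(pk_pred$segment, pk_tru$segment)
    list(pred = c(pk_pred$Ecc_peak_percent, pk_pred$Err_peak_percent),
         truth = c(pk_tru$Ecc_peak_percent[m], pk_tru$Err_peak_percent[m]))
  })
  list(pred = unlist(lapply(out, `[[`, "pred")),
       truth = unlist(lapply(out, `[[`, "truth")))
}
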
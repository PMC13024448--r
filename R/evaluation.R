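# ---------------------------------------------------------------------------
# Method-agreement statistics: image-level (SSIM, RMSE, EPE) and
# strain-level (ICC(2,1), Pearson r, CV, Bland-Altman, paired t-tests with
# Bonferroni correction).
# ---------------------------------------------------------------------------

gaussian_kernel_1d <- function(radius = 5, sigma = 1.5) {
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Gaussian-weighted local filtering restricted to window positions fully
# inside the image ("valid" windows); returns an (H-2r) x (W-2r) matrix.
gfilter_valid <- function(x, g) {
  r <- (length(g) - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H - 2 * r, W - 2 * r)
  Hc <- H - 2 * r; Wc <- W - 2 * r
  for (i in seq_along(g)) for (j in seq_along(g)) {
    out <- out + g[i] * g[j] *
      x[(i - 1) + seq_len(Hc), (j - 1) + seq_len(Wc)]
  }
  out
}

#' Structural similarity index between two images
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, population (weighted) variances, averaged over all window
#' positions fully inside the image.
#'
#' @param a,b numeric matrices of equal size (at least 11x11).
#' @param dynamic_range value range `L` of the data (1 for normalized
#'   displacement images).
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(a, b, dynamic_range = 1) {
  if (!identical(dim(a), dim(b))) stop("ssim: image shapes differ")
  if (nrow(a) < 11 || ncol(a) < 11) stop("ssim: images must be at least 11x11")
  g <- gaussian_kernel_1d(5, 1.5)
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mu_a <- gfilter_valid(a, g); mu_b <- gfilter_valid(b, g)
  va <- gfilter_valid(a * a, g) - mu_a^2
  vb <- gfilter_valid(b * b, g) - mu_b^2
  cab <- gfilter_valid(a * b, g) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' RMSE per component and mean endpoint error over a mask
#'
#' @param pred,target [displacement_sequence] objects (signed mm) or lists
#'   with `ux`, `uy` arrays of equal shape.
#' @param mask logical/binary array matching the field shape (or `H x W`,
#'   recycled over frames); metrics use mask pixels only.
#' @return list: `rmse_x`, `rmse_y` (mm), `epe` (mm).
#' @export
rmse_epe <- function(pred, target, mask = NULL) {
  px <- pred$ux; py <- pred$uy; tx <- target$ux; ty <- target$uy
  if (!identical(dim(px), dim(tx))) stop("rmse_epe: field shapes differ")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(px))
  m <- as.array(mask) != 0
  if (length(dim(m)) == 2L) m <- array(m, dim = dim(px))
  if (!any(m)) stop("rmse_epe: empty mask")
  dx <- (px - tx)[m]; dy <- (py - ty)[m]
  list(rmse_x = sqrt(mean(dx^2)), rmse_y = sqrt(mean(dy^2)),
       epe = mean(sqrt(dx^2 + dy^2)))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' two-way ANOVA mean squares with subjects = pairs and two raters
#' (methods). Penalizes systematic offsets, unlike Pearson correlation.
#'
#' @param x,y paired measurements (n >= 3).
#' @return scalar in \[-1, 1\].
#' @export
icc <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("icc: need at least 3 pairs")
  dat <- cbind(x, y)
  k <- 2
  grand <- mean(dat)
  subj_means <- rowMeans(dat)
  rater_means <- colMeans(dat)
  sst <- sum((dat - grand)^2)
  ssbs <- k * sum((subj_means - grand)^2)
  ssbr <- n * sum((rater_means - grand)^2)
  sse <- sst - ssbs - ssbr
  if (sst == 0) stop("icc: zero total variance, ICC undefined")
  msr <- ssbs / (n - 1)
  msc <- ssbr / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Pearson correlation and per-method coefficients of variation
#'
#' @param x,y paired measurements (n >= 3).
#' @return list: `r`, `cv_x`, `cv_y` (percent, `100 * sd / |mean|`; `NA`
#'   with a warning when a mean is zero).
#' @export
pearson_cv <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  r <- if (sd(x) == 0 || sd(y) == 0) {
    warning("pearson_cv: zero variance, correlation undefined")
    NA_real_
  } else cor(x, y)
  cv1 <- function(v) {
    if (mean(v) == 0) { warning("pearson_cv: zero mean, CV undefined"); return(NA_real_) }
    100 * sd(v) / abs(mean(v))
  }
  list(r = r, cv_x = cv1(x), cv_y = cv1(y))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: mean bias, sample SD of the differences, and
#' limits of agreement `bias +/- 1.96 SD`.
#'
#' @param x,y paired measurements (n >= 2).
#' @return list: `bias`, `sd_diff`, `loa_low`, `loa_high`, plus `means` and
#'   `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("bland_altman: need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       means = (x + y) / 2, diffs = d)
}

#' Per-segment paired t-tests between two methods' strain tables
#'
#' For each AHA segment and each strain component, a paired Student t-test
#' across slices comparing method A with method B, with Bonferroni
#' correction over the 6 segments within each strain family. Identical
#' values in every slice (zero differences) yield `t = 0`, `p = 1` by
#' convention.
#'
#' @param tables_a,tables_b lists of per-slice strain tables (one
#'   [segment_strain_table()]-style tibble per slice, same slice order, at a
#'   common frame, e.g. peak).
#' @return tibble: `strain` ("Ecc"/"Err"), `segment`, `t`, `p_raw`,
#'   `p_adjusted` (`min(1, 6 p_raw)`).
#' @export
segment_ttests <- function(tables_a, tables_b) {
  if (length(tables_a) != length(tables_b))
    stop("segment_ttests: the two methods must cover the same slices")
  if (length(tables_a) < 3) stop("segment_ttests: need at least 3 slices")
  get_seg <- function(tabs, seg, col)
    vapply(tabs, function(tb) tb[[col]][tb$segment == seg], numeric(1))
  rows <- list()
  for (strain in c("Ecc", "Err")) {
    col <- paste0(strain, "_percent")
    praw <- numeric(6); tval <- numeric(6)
    for (s in 1:6) {
      va <- get_seg(tables_a, as.character(s), col)
      vb <- get_seg(tables_b, as.character(s), col)
      d <- va - vb
      if (all(abs(d) < .Machine$double.eps * 100) || sd(d) == 0) {
        tval[s] <- 0; praw[s] <- 1
      } else {
        tt <- t.test(va, vb, paired = TRUE)
        tval[s] <- unname(tt$statistic); praw[s] <- tt$p.value
      }
    }
    padj <- p.adjust(praw, method = "bonferroni")  # family = 6 segments
    rows[[strain]] <- tibble::tibble(strain = strain, segment = as.character(1:6),
                                     t = tval, p_raw = praw, p_adjusted = padj)
  }
  dplyr::bind_rows(rows)
}

#' Full agreement report between predicted and reference data
#'
#' Displacement-level metrics (SSIM on the normalized fields, RMSE/EPE in mm
#' over the foreground) and strain-level metrics (ICC(2,1), Pearson, CV,
#' Bland-Altman on pooled per-segment values; paired per-segment t-tests
#' when >= 3 slices are available).
#'
#' @param pred,ref lists with per-slice entries: `displacement`
#'   ([displacement_sequence] with scale attached) and `strain` (per-frame
#'   strain table from [strain_analysis()]).
#' @return an `agreement_report` list.
#' @export
agreement_report <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 1)
  ssim_x <- ssim_y <- rx <- ry <- ep <- numeric(0)
  ecc_a <- ecc_b <- err_a <- err_b <- numeric(0)
  for (i in seq_along(pred)) {
    dp <- pred[[i]]$displacement; dr <- ref[[i]]$displacement
    for (t in seq_len(dp$n)) {
      ssim_x <- c(ssim_x, ssim(dp$normalized_x[, , t], dr$normalized_x[, , t], 1))
      ssim_y <- c(ssim_y, ssim(dp$normalized_y[, , t], dr$normalized_y[, , t], 1))
    }
    m <- rmse_epe(dp, dr, dr$foreground_mask)
    rx <- c(rx, m$rmse_x); ry <- c(ry, m$rmse_y); ep <- c(ep, m$epe)
    sa <- pred[[i]]$strain; sb <- ref[[i]]$strain
    seg <- sa$segment != "global"
    ecc_a <- c(ecc_a, sa$Ecc_percent[seg]); ecc_b <- c(ecc_b, sb$Ecc_percent[seg])
    err_a <- c(err_a, sa$Err_percent[seg]); err_b <- c(err_b, sb$Err_percent[seg])
  }
  strain_stats <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    pc <- pearson_cv(a, b)
    list(icc = icc(a, b), pearson = pc$r, cv_pred = pc$cv_x, cv_ref = pc$cv_y,
         bland_altman = bland_altman(a, b)[c("bias", "sd_diff", "loa_low", "loa_high")])
  }
  out <- list(
    displacement = list(ssim_x = mean(ssim_x), ssim_y = mean(ssim_y),
                        rmse_x_mm = mean(rx), rmse_y_mm = mean(ry),
                        epe_mm = mean(ep)),
    ecc = strain_stats(ecc_a, ecc_b),
    err = strain_stats(err_a, err_b))
  if (length(pred) >= 3) {
    tabs_a <- lapply(pred, function(p) p$strain_peak)
    tabs_b <- lapply(ref, function(p) p$strain_peak)
    if (!any(vapply(tabs_a, is.null, logical(1))))
      out$ttests <- segment_ttests(tabs_a, tabs_b)
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report>\n  SSIM x/y: %.4f / %.4f; RMSE x/y: %.4g / %.4g mm; EPE %.4g mm\n",
              x$displacement$ssim_x, x$displacement$ssim_y,
              x$displacement$rmse_x_mm, x$displacement$rmse_y_mm,
              x$displacement$epe_mm))
  cat(sprintf("  Ecc: ICC %.3f, r %.3f, bias %.3g%%\n",
              x$ecc$icc, x$ecc$pearson, x$ecc$bland_altman$bias))
  cat(sprintf("  Err: ICC %.3f, r %.3f, bias %.3g%%\n",
              x$err$icc, x$err$pearson, x$err$bland_altman$bias))
  invisible(x)
}
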
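test_that("ssim is 1 on identical images, penalizes offsets, matches oracles", {
  set.seed(42)
  H <- 40
  a <- matrix(runif(H * H), H, H)
  b <- pmin(pmax(a + 0.1 * matrix(rnorm(H * H), H, H), 0), 1)
  expect_equal(ssim(a, a), 1)
  expect_lt(ssim(a, a + 0.5, dynamic_range = 1), 1)
  expect_equal(ssim(a, b), loop_ssim(a, b), tolerance = 1e-9)
  # frozen reference value computed with an independent implementation
  # (scikit-image structural_similarity, gaussian window 11 / sigma 1.5,
  # population covariance, data_range 1) on this exact seeded fixture
  expect_equal(ssim(a, b, 1), 0.9461688375, tolerance = 1e-6)
  expect_error(ssim(a, b[1:20, 1:20]), "differ")
  expect_equal(ssim(a, b), ssim(b, a))
})

test_that("rmse and endpoint error follow their definitions on masks", {
  ph <- make_phantom(tiny_spec(seed = 4))
  ref <- ph$displacement
  # constant (3, 4) error over the foreground: 3-4-5
  pred <- ref
  fg <- ref$foreground_mask
  pred$ux <- ref$ux + 3 * fg
  pred$uy <- ref$uy + 4 * fg
  m <- rmse_epe(pred, ref, fg)
  expect_equal(c(m$rmse_x, m$rmse_y, m$epe), c(3, 4, 5), tolerance = 1e-12)
  z <- rmse_epe(ref, ref, fg)
  expect_equal(c(z$rmse_x, z$rmse_y, z$epe), c(0, 0, 0))
  # random fields against a naive loop oracle
  set.seed(13)
  p2 <- ref
  p2$ux <- ref$ux + array(rnorm(length(ref$ux)), dim = dim(ref$ux))
  p2$uy <- ref$uy + array(rnorm(length(ref$uy)), dim = dim(ref$uy))
  got <- rmse_epe(p2, ref, fg)
  dx <- (p2$ux - ref$ux)[fg]; dy <- (p2$uy - ref$uy)[fg]
  acc_x <- acc_y <- acc_e <- 0
  for (i in seq_along(dx)) {
    acc_x <- acc_x + dx[i]^2; acc_y <- acc_y + dy[i]^2
    acc_e <- acc_e + sqrt(dx[i]^2 + dy[i]^2)
  }
  expect_equal(got$rmse_x, sqrt(acc_x / length(dx)), tolerance = 1e-12)
  expect_equal(got$rmse_y, sqrt(acc_y / length(dy)), tolerance = 1e-12)
  expect_equal(got$epe, acc_e / length(dx), tolerance = 1e-12)
  expect_error(rmse_epe(p2, ref, fg & FALSE), "empty")
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and penalizes offsets", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  expect_equal(icc(x, y), aov_icc21(x, y), tolerance = 1e-9)
  expect_lt(icc(x, y), 1)                       # offset: ICC < 1 though r = 1
  expect_equal(pearson_cv(x, y)$r, 1)
  expect_lt(icc(x, y), abs(cor(x, y)))          # ICC <= |r| under pure offset
  set.seed(21)
  xr <- rnorm(15); yr <- xr + rnorm(15, sd = 0.3)
  expect_equal(icc(xr, yr), aov_icc21(xr, yr), tolerance = 1e-9)
  expect_equal(icc(xr, xr), 1, tolerance = 1e-12)
  # independent noise: ICC near zero
  set.seed(31)
  expect_lt(abs(icc(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(icc(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("pearson and CV follow their closed forms", {
  x <- c(10, 12, 8, 10)
  pc <- pearson_cv(x, 2 * x)
  expect_equal(pc$r, 1)
  expect_equal(pc$cv_x, 100 * sd(x) / 10, tolerance = 1e-12)
  expect_equal(pearson_cv(x, -x)$r, -1)
  expect_warning(pearson_cv(c(-1, 0, 1), c(1, 2, 3)), "zero mean")
  expect_warning(pearson_cv(rep(2, 3), c(1, 2, 3)), "zero variance")
})

test_that("Bland-Altman bias, limits and coverage behave as defined", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x + 1)
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1, -1))
  z <- bland_altman(x, x)
  expect_equal(c(z$bias, z$sd_diff, z$loa_low, z$loa_high), rep(0, 4))
  # antisymmetry under swapping methods
  set.seed(3)
  a <- rnorm(50); b <- a + rnorm(50, 0.2, 0.1)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  # about 95% of Gaussian differences fall inside the limits
  set.seed(17)
  xg <- rnorm(1000); yg <- xg + rnorm(1000, sd = 0.5)
  bg <- bland_altman(xg, yg)
  inside <- mean(bg$diffs >= bg$loa_low & bg$diffs <= bg$loa_high)
  expect_gte(inside, 0.94)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("paired segment t-tests match the textbook formula with Bonferroni", {
  mk_tab <- function(ecc, err) tibble::tibble(
    frame = 4L, segment = as.character(1:6), n_pixels = 50L,
    Ecc_percent = ecc, Err_percent = err)
  set.seed(9)
  base <- matrix(rnorm(4 * 6, -10, 2), 4, 6)
  tabs_a <- lapply(1:4, function(i) mk_tab(base[i, ], base[i, ] + 20))
  shift <- matrix(rnorm(4 * 6, 0.5, 0.4), 4, 6)
  tabs_b <- lapply(1:4, function(i) mk_tab(base[i, ] + shift[i, ], base[i, ] + 20))
  tt <- segment_ttests(tabs_a, tabs_b)
  expect_equal(nrow(tt), 12)
  for (s in 1:6) {
    a <- base[, s]; b <- base[, s] + shift[, s]
    orc <- paired_t_oracle(a, b)
    row <- tt[tt$strain == "Ecc" & tt$segment == as.character(s), ]
    expect_equal(row$t, orc$t, tolerance = 1e-9)
    expect_equal(row$p_raw, orc$p, tolerance = 1e-9)
  }
  expect_equal(tt$p_adjusted, pmin(1, 6 * tt$p_raw), tolerance = 1e-12)
  # identical tables: t = 0, adjusted p = 1 by convention
  same <- segment_ttests(tabs_a, tabs_a)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_adjusted == 1))
  expect_error(segment_ttests(tabs_a, tabs_b[1:2]), "same slices")
})
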
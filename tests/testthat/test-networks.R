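test_that("output shape mirrors input with 2 channels and sigmoid range", {
  for (variant in c("myonet", "resmyonet")) {
    net <- build_network(network_config(variant, base_channels = 2, seed = 1))
    x <- array(runif(1 * 2 * 16 * 16), dim = c(1, 2, 16, 16))
    y <- forward(net, x)
    expect_equal(dim(y), c(2, 2, 16, 16))
    expect_gt(min(y), 0)
    expect_lt(max(y), 1)
    x2 <- array(runif(1 * 3 * 32 * 32), dim = c(1, 3, 32, 32))
    expect_equal(dim(forward(net, x2)), c(2, 3, 32, 32))
  }
  # temporal dimension is never pooled: odd T works at depth 5
  net <- build_network(network_config("myonet", base_channels = 2, seed = 1))
  x3 <- array(runif(1 * 5 * 16 * 16), dim = c(1, 5, 16, 16))
  expect_equal(dim(forward(net, x3))[2], 5)
  # non-divisible spatial size is a descriptive error
  bad <- array(0.5, dim = c(1, 2, 20, 20))
  expect_error(forward(net, bad), "divisible by 16")
})

test_that("builds are deterministic in parameters and outputs for a fixed seed", {
  cfg <- network_config("resmyonet", base_channels = 2, seed = 42)
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_identical(parameter_count(n1), parameter_count(n2))
  expect_identical(n1$enc[[3]]$main[[1]]$W, n2$enc[[3]]$main[[1]]$W)
  x <- array(runif(1 * 2 * 16 * 16), dim = c(1, 2, 16, 16))
  expect_identical(forward(n1, x), forward(n2, x))
  # parameter count is a pure function of the configuration
  n3 <- build_network(network_config("resmyonet", base_channels = 2, seed = 7))
  expect_identical(parameter_count(n1), parameter_count(n3))
  # channel schedule doubles and caps
  n4 <- build_network(network_config("myonet", base_channels = 16, channel_cap = 64))
  expect_equal(n4$channels, c(16, 32, 64, 64, 64))
  expect_error(build_network(structure(list(variant = "foo"), class = "network_config")),
               "variant")
})

test_that("residual blocks apply tanh after the shortcut sum and pass gradients", {
  cfg <- network_config("resmyonet", base_channels = 2, seed = 3)
  blk <- myostrain:::make_block(cfg, 2, 4)
  x <- array(rnorm(2 * 2 * 4 * 4), dim = c(2, 2, 4, 4, 1))
  fw <- myostrain:::block_forward(blk, x, train = TRUE)
  expect_true(all(abs(fw$y) < 1))
  # zero the main path's final BN gamma: output must equal tanh(shortcut)
  blk0 <- blk
  blk0$main[[5]]$gamma[] <- 0
  blk0$main[[5]]$beta[] <- 0
  fw0 <- myostrain:::block_forward(blk0, x, train = TRUE)
  rs <- myostrain:::conv_forward(blk0$shortcut, x)
  expect_equal(fw0$y, tanh(rs$y), tolerance = 1e-12)
  # gradient still reaches the input and the shortcut weights through the skip
  bw0 <- myostrain:::block_backward(blk0, fw0$cache, fw0$y * 0 + 1)
  expect_gt(max(abs(bw0$dx)), 0)
  expect_gt(max(abs(bw0$grads$sc$W)), 0)
})

test_that("convolution and batch-norm backward match numeric differentiation", {
  set.seed(8)
  l <- myostrain:::make_conv(2, 3, c(3L, 3L, 3L), dil = c(2L, 1L, 1L))
  x <- array(rnorm(2 * 4 * 5 * 5 * 2), dim = c(2, 4, 5, 5, 2))
  fw <- myostrain:::conv_forward(l, x)
  dy <- array(rnorm(length(fw$y)), dim = dim(fw$y))
  bw <- myostrain:::conv_backward(l, fw$cache, dy)
  f <- function(ll, xx) sum(myostrain:::conv_forward(ll, xx)$y * dy)
  eps <- 1e-6
  for (i in sample(length(l$W), 5)) {
    l1 <- l; l1$W[i] <- l1$W[i] + eps
    l2 <- l; l2$W[i] <- l2$W[i] - eps
    expect_equal(bw$grads$W[i], (f(l1, x) - f(l2, x)) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(x), 5)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    expect_equal(bw$dx[i], (f(l, x1) - f(l, x2)) / (2 * eps), tolerance = 1e-5)
  }
  bn <- myostrain:::make_bn(3)
  bn$gamma <- runif(3, 0.5, 1.5); bn$beta <- rnorm(3)
  xb <- array(rnorm(3 * 2 * 4 * 4 * 2), dim = c(3, 2, 4, 4, 2))
  fb <- myostrain:::bn_forward(bn, xb, train = TRUE)
  dyb <- array(rnorm(length(fb$y)), dim = dim(fb$y))
  bb <- myostrain:::bn_backward(bn, fb$cache, dyb)
  g <- function(xx) sum(myostrain:::bn_forward(bn, xx, TRUE)$y * dyb)
  for (i in sample(length(xb), 5)) {
    x1 <- xb; x1[i] <- x1[i] + eps
    x2 <- xb; x2[i] <- x2[i] - eps
    expect_equal(bb$dx[i], (g(x1) - g(x2)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("checkpoints restore the model, scale and metadata", {
  net <- build_network(network_config("myonet", base_channels = 2, seed = 5))
  td <- withr::local_tempdir()
  p <- file.path(td, "ckpt.rds")
  save_checkpoint(net, p, scale = affine_scale(1.5), meta = list(epoch = 7))
  ck <- load_checkpoint(p)
  expect_equal(ck$scale$d_max, 1.5)
  expect_equal(ck$meta$epoch, 7)
  expect_identical(ck$parameter_count, parameter_count(net))
  x <- array(runif(1 * 2 * 16 * 16), dim = c(1, 2, 16, 16))
  expect_identical(forward(ck$model, x), forward(net, x))
})
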
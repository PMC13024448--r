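test_that("scan-level split applies the rounding rule and is deterministic", {
  ids22 <- sprintf("rat%02d", 1:22)
  sp <- split_scans(ids22, seed = 1)
  expect_equal(c(length(sp$train), length(sp$val), length(sp$test)), c(18, 2, 2))
  ids10 <- sprintf("s%02d", 1:10)
  sp10 <- split_scans(ids10, seed = 4)
  expect_equal(c(length(sp10$train), length(sp10$val), length(sp10$test)), c(8, 1, 1))
  sp3 <- split_scans(c("a", "b", "c"), seed = 9)
  expect_equal(lengths(sp3[c("train", "val", "test")]), c(train = 1L, val = 1L, test = 1L))
  expect_identical(split_scans(ids22, seed = 33), split_scans(ids22, seed = 33))
  expect_false(identical(split_scans(ids22, seed = 1)$test, split_scans(ids22, seed = 2)$test))
  expect_error(split_scans(c("a", "b")), "at least 3")
})

test_that("split sets are disjoint and cover every scan, so slices cannot leak", {
  for (seed in 1:25) {
    N <- 3 + (seed * 7) %% 38
    ids <- sprintf("scan%03d", seq_len(N))
    slices <- setNames(lapply(ids, function(i) paste0(i, "_sl", 1:3)), ids)
    sp <- split_scans(ids, seed = seed)
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_setequal(all_ids, ids)
    expect_equal(length(all_ids), N)           # disjoint
    slice_sets <- lapply(slices, function(sl) unique(sp$assignment[sub("_sl.*", "", sl)]))
    expect_true(all(lengths(slice_sets) == 1)) # all slices of a scan share its set
  }
})

test_that("flip augmentation is an involution and negates the right component", {
  ph <- make_phantom(tiny_spec(seed = 6))
  disp <- attach_scale(ph$displacement, affine_scale(2))
  f1 <- augment_flip(ph$cine, disp, "horizontal")
  f2 <- augment_flip(f1$cine, f1$displacement, "horizontal")
  expect_equal(f2$cine$frames, ph$cine$frames)
  expect_equal(f2$displacement$ux, disp$ux, tolerance = 1e-12)
  expect_equal(f2$displacement$normalized_x, disp$normalized_x, tolerance = 1e-12)
  # horizontal flip negates u_x (mirrored), keeps u_y magnitude pattern
  W <- dim(disp$ux)[2]
  expect_equal(f1$displacement$ux, -disp$ux[, rev(seq_len(W)), , drop = FALSE],
               tolerance = 1e-12)
  fv <- augment_flip(ph$cine, disp, "vertical")
  H <- dim(disp$uy)[1]
  expect_equal(fv$displacement$uy, -disp$uy[rev(seq_len(H)), , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("joint flips leave the training loss invariant", {
  scale <- affine_scale(2)
  ph1 <- make_phantom(tiny_spec(seed = 1))
  ph2 <- make_phantom(tiny_spec(seed = 2))
  s1 <- myostrain:::pack_sample(ph1, scale)
  s2 <- myostrain:::pack_sample(ph2, scale)
  l0 <- total_loss(s2$target, s1$target)$l_total
  for (ax in c("horizontal", "vertical")) {
    fp <- myostrain:::flip_sample(s2$input, s2$target, ax, scale)
    ft <- myostrain:::flip_sample(s1$input, s1$target, ax, scale)
    expect_equal(total_loss(fp$target, ft$target)$l_total, l0, tolerance = 1e-9)
  }
})

test_that("accuracy is one minus normalized MSE with the stated examples", {
  tg <- array(0.4, dim = c(2, 2, 4, 4))
  expect_equal(accuracy(tg, tg), 1)
  expect_equal(accuracy(tg + 0.1, tg), 0.98, tolerance = 1e-12)
  # monotone decrease as a single pixel's error grows
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4), function(e) {
    p <- tg; p[1, 1, 1, 1] <- p[1, 1, 1, 1] + e
    accuracy(p, tg)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("a tiny training run is reproducible and selects the best epoch", {
  scans <- make_phantom_cohort(4, small_phantom_spec(grid_size = 16, n_frames = 4),
                               seed = 2, jitter = 0.05)
  scale <- fit_scale(lapply(scans, `[[`, "displacement"), margin = 0.1)
  data <- list(train = lapply(scans[1:3], myostrain:::pack_sample, scale = scale),
               val = lapply(scans[4], myostrain:::pack_sample, scale = scale),
               scale = scale)
  cfg <- train_config(epochs = 3, batch_size = 2, seed = 11)
  run <- function() {
    model <- build_network(network_config("myonet", base_channels = 2, seed = 11))
    train_model(model, data, cfg)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  val <- f1$history[f1$history$split == "val", ]
  expect_equal(f1$best_epoch, val$epoch[which.min(val$l_total)])
  expect_true(all(val$l_total[f1$best_epoch] <= val$l_total))
  expect_identical(f1$model$head$W, f2$model$head$W)
})
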
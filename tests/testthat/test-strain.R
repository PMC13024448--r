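test_that("lv_center finds the annulus centroid and is translation-equivariant", {
  an <- annulus_mask(41, 6, 14, center = c(20, 20))
  expect_equal(lv_center(an$mask), c(20, 20), tolerance = 0.01)
  shifted <- annulus_mask(61, 6, 14, center = c(25, 17))
  expect_equal(lv_center(shifted$mask), c(25, 17), tolerance = 0.01)
  # C-shaped mask: centroid still returned, with a warning
  cmask <- an$mask
  cmask[1:20, ] <- 0
  expect_warning(cen <- lv_center(cmask), "C-shaped|annular")
  expect_true(all(is.finite(cen)))
  expect_error(lv_center(matrix(0, 5, 5)), "empty")
})

test_that("affine displacement fields yield exact strains (rigid zero, scaling 0.105)", {
  an <- annulus_mask(41, 5, 15)
  # uniform scaling lambda = 1.1 about the center: Ecc = Err = 0.105 exactly
  sm <- compute_strain_maps(0.1 * an$dx, 0.1 * an$dy, an$mask, pixel_spacing = 1)
  expect_lt(max(abs(sm$Ecc[sm$valid] - 0.105)), 1e-9)
  expect_lt(max(abs(sm$Err[sm$valid] - 0.105)), 1e-9)
  # rigid rotation by 10 degrees + translation: E identically zero
  th <- 10 * pi / 180
  ux <- cos(th) * an$dx - sin(th) * an$dy - an$dx + 3.2
  uy <- sin(th) * an$dx + cos(th) * an$dy - an$dy - 1.7
  sm2 <- compute_strain_maps(ux, uy, an$mask, pixel_spacing = 1)
  for (i in 1:2) for (j in 1:2)
    expect_lt(max(abs(sm2$E[, , i, j][sm2$valid])), 1e-9)
  # E is exactly symmetric and u = 0 gives zero strain
  sm3 <- compute_strain_maps(an$dx * 0, an$dy * 0, an$mask, pixel_spacing = 1)
  expect_equal(sm3$E[, , 1, 2], sm3$E[, , 2, 1])
  expect_lt(max(abs(sm3$Ecc[sm3$valid])), 1e-12)
})

test_that("strain maps respect pixel spacing through the mm-to-pixel conversion", {
  an <- annulus_mask(41, 5, 15)
  sp <- 0.5
  # same physical uniform scaling expressed in mm on a 0.5 mm grid
  sm <- compute_strain_maps(0.1 * an$dx * sp, 0.1 * an$dy * sp, an$mask, pixel_spacing = sp)
  expect_lt(max(abs(sm$Ecc[sm$valid] - 0.105)), 1e-9)
})

test_that("AHA segment labels partition the annulus into six balanced sectors", {
  an <- annulus_mask(120, 20, 52)   # half-integer center at 59.5
  lab <- aha_segment_labels(an$mask, center = an$center, reference_angle = 90)
  expect_setequal(unique(lab[!is.na(lab)]), 1:6)
  counts <- tabulate(lab[!is.na(lab)], 6)
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.02)
  # a pixel 30 degrees past the reference angle is in segment 1
  cen <- an$center
  r <- 25
  ang <- (90 + 30) * pi / 180
  px <- round(cen[1] - r * sin(ang)) + 1   # row (image up = -row)
  py <- round(cen[2] + r * cos(ang)) + 1
  expect_equal(lab[px, py], 1L)
  # rotating the reference angle by 60 degrees shifts labels cyclically
  lab2 <- aha_segment_labels(an$mask, center = an$center, reference_angle = 150)
  ok <- !is.na(lab) & !is.na(lab2)
  expect_true(all((lab[ok] - 1 - 1) %% 6 + 1 == (lab2[ok] - 1) %% 6 + 1))
})

test_that("segment table averages, weights the global row, and drops empty segments", {
  an <- annulus_mask(61, 8, 22)
  lab <- aha_segment_labels(an$mask, center = an$center)
  valid <- an$mask != 0
  ecc <- matrix(0.105, 61, 61)
  err <- matrix(-0.02, 61, 61)
  tab <- segment_strain_table(ecc, err, lab, valid, frame = 3)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$Ecc_percent[tab$segment != "global"], rep(10.5, 6))
  expect_equal(tab$Ecc_percent[tab$segment == "global"], 10.5)
  expect_equal(tab$Err_percent[tab$segment == "global"], -2)
  expect_equal(sum(tab$n_pixels[tab$segment != "global"]), sum(an$mask))
  # invalidate one segment entirely -> NA there, global over the rest
  valid2 <- valid & (is.na(lab) | lab != 4)
  tab2 <- segment_strain_table(ecc, err, lab, valid2, frame = 0)
  expect_true(is.na(tab2$Ecc_percent[tab2$segment == "4"]))
  expect_equal(tab2$Ecc_percent[tab2$segment == "global"], 10.5)
  expect_error(segment_strain_table(ecc, err, lab, valid & FALSE), "no valid")
})

test_that("peak strain keeps the signed maximal-magnitude value and its frame", {
  tab <- dplyr::bind_rows(lapply(0:4, function(f)
    tibble::tibble(frame = f, segment = as.character(1:6),
                   Ecc_percent = -c(0, 2, 5, 3, 1)[f + 1],
                   Err_percent = c(0, 3, 8, 4, 2)[f + 1])))
  pk <- peak_strain(tab)
  expect_equal(pk$Ecc_peak_percent, rep(-5, 6))
  expect_equal(pk$Ecc_peak_frame, rep(2L, 6))
  expect_equal(pk$Err_peak_percent, rep(8, 6))
  # all-zero sequence: 0 at frame 0
  tab0 <- dplyr::bind_rows(lapply(0:2, function(f)
    tibble::tibble(frame = f, segment = "1", Ecc_percent = 0, Err_percent = 0)))
  pk0 <- peak_strain(tab0)
  expect_equal(pk0$Ecc_peak_percent, 0)
  expect_equal(pk0$Ecc_peak_frame, 0L)
  # phantom: every segment peaks at the specified peak frame
  ph <- make_phantom(tiny_spec(seed = 3))
  tabs <- strain_analysis(ph$displacement)
  pk2 <- peak_strain(tabs[tabs$segment != "global", ])
  expect_true(all(pk2$Ecc_peak_frame == ph$spec$peak_frame))
  expect_true(all(pk2$Err_peak_frame == ph$spec$peak_frame))
})

test_that("pixelwise strain converges to the closed form with grid refinement", {
  errs <- vapply(c(32, 64, 128), function(G) {
    s <- small_phantom_spec(grid_size = G, n_frames = 4)
    ph <- make_phantom(s)
    tab <- strain_analysis(ph$displacement)
    pk <- s$peak_frame
    seg <- tab[tab$frame == pk & tab$segment != "global", ]
    an <- analytic_segment_strain(s, pk)
    max(abs(seg$Err_percent - an$Err_percent[1]) / 100)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))               # monotone decrease
  expect_gt(log2(errs[1] / errs[3]) / 2, 0.9)    # observed order about 1+
})
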
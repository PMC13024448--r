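# ---------------------------------------------------------------------------
# Lagrangian strain from dense displacement fields
#
# Pipeline per frame: displacement u (mm, on the frame-0 reference grid)
# -> pixel units -> spatial gradient by central finite differences inside
# the myocardium mask (one-sided at mask edges) -> deformation gradient
# F = I + grad(u) -> Green-Lagrange tensor E = (F'F - I)/2 -> projection on
# the local circumferential/radial directions -> AHA 6-segment averages.
# ---------------------------------------------------------------------------

#' Centroid of a myocardium mask
#'
#' Sub-pixel centroid of the mask pixels, used as the pole of the polar
#' coordinate frame. C-shaped or otherwise non-annular masks still return
#' their centroid, with a warning when the centroid itself lies on myocardium
#' (a hint the mask is not an annulus around a blood pool).
#'
#' @param mask binary `H x W` matrix.
#' @return `(row, col)` in 0-based pixel coordinates.
#' @export
lv_center <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask: cannot locate the LV center")
  cen <- colMeans(w) - 1  # 0-based
  ri <- round(cen[1]) + 1; ci <- round(cen[2]) + 1
  if (ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask) &&
      mask[ri, ci] != 0)
    warning("mask centroid lies on myocardium; mask may not be annular (e.g. C-shaped)")
  unname(cen)
}

#' Polar unit-vector frame about a center
#'
#' @param dim_hw image dimensions `c(H, W)`.
#' @param center `(row, col)` pole, 0-based pixels.
#' @return list of `H x W` matrices: `er_x`, `er_y` (radial unit vector,
#'   x = column / y = row components) and `ec_x`, `ec_y` (circumferential,
#'   radial rotated +90 degrees counterclockwise in image-up convention).
#' @export
polar_frame <- function(dim_hw, center) {
  H <- dim_hw[1]; W <- dim_hw[2]
  dy <- matrix((seq_len(H) - 1) - center[1], H, W)         # row offset
  dx <- matrix((seq_len(W) - 1) - center[2], H, W, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  r[r == 0] <- 1
  er_x <- dx / r; er_y <- dy / r
  # +90deg CCW with image "up" = decreasing row: (x, y) -> (y, -x) in
  # (col, row) components expressed with y pointing down
  ec_x <- er_y; ec_y <- -er_x
  list(er_x = er_x, er_y = er_y, ec_x = ec_x, ec_y = ec_y)
}

# masked finite-difference gradient along rows or cols: central where both
# neighbors are inside the mask, one-sided where exactly one is, NA where
# neither. `f` and `mask` are H x W; returns d f / d index (pixel units).
masked_gradient <- function(f, mask, along = c("row", "col")) {
  along <- match.arg(along)
  H <- nrow(f); W <- ncol(f)
  m <- mask != 0
  shift <- function(x, dr, dc) {
    out <- matrix(NA_real_, H, W)
    src_r <- seq_len(H) + dr
    src_c <- seq_len(W) + dc
    rok <- which(src_r >= 1 & src_r <= H)
    cok <- which(src_c >= 1 & src_c <= W)
    out[rok, cok] <- x[src_r[rok], src_c[cok]]
    out
  }
  dr <- if (along == "row") 1L else 0L
  dc <- if (along == "col") 1L else 0L
  f_plus <- shift(f, dr, dc); f_minus <- shift(f, -dr, -dc)
  m_plus <- shift(m * 1, dr, dc); m_minus <- shift(m * 1, -dr, -dc)
  m_plus[is.na(m_plus)] <- 0; m_minus[is.na(m_minus)] <- 0
  g <- matrix(NA_real_, H, W)
  both <- m & m_plus == 1 & m_minus == 1
  up <- m & m_plus == 1 & m_minus == 0
  dn <- m & m_plus == 0 & m_minus == 1
  g[both] <- (f_plus[both] - f_minus[both]) / 2
  g[up] <- f_plus[up] - f[up]
  g[dn] <- f[dn] - f_minus[dn]
  g
}

#' Per-pixel deformation gradient and Green-Lagrange strain of one frame
#'
#' @param ux,uy `H x W` signed displacement in mm on the reference grid.
#' @param mask binary `H x W` myocardium mask (reference configuration).
#' @param pixel_spacing mm per pixel (u is converted to pixel units so F is
#'   dimensionless).
#' @param frame optional [polar_frame]; computed from the mask centroid when
#'   missing.
#' @return list: `F` array `H x W x 2 x 2`; `E` array `H x W x 2 x 2`
#'   (symmetric); `Ecc`, `Err` `H x W` projection maps; `valid` logical map
#'   of pixels with computable gradients.
#' @export
compute_strain_maps <- function(ux, uy, mask, pixel_spacing, frame = NULL) {
  if (sum(mask != 0) == 0L) stop("empty myocardium mask")
  upx <- ux / pixel_spacing
  upy <- uy / pixel_spacing
  # gradient components in pixel units; x = col direction, y = row direction
  dux_dx <- masked_gradient(upx, mask, "col")
  dux_dy <- masked_gradient(upx, mask, "row")
  duy_dx <- masked_gradient(upy, mask, "col")
  duy_dy <- masked_gradient(upy, mask, "row")
  valid <- !is.na(dux_dx) & !is.na(dux_dy) & !is.na(duy_dx) & !is.na(duy_dy)
  if (!any(valid))
    stop("mask is thinner than one pixel everywhere: no computable gradients")
  H <- nrow(ux); W <- ncol(ux)
  Fm <- array(NA_real_, c(H, W, 2, 2))
  Fm[, , 1, 1] <- 1 + dux_dx; Fm[, , 1, 2] <- dux_dy
  Fm[, , 2, 1] <- duy_dx;     Fm[, , 2, 2] <- 1 + duy_dy
  # E = (F'F - I)/2 componentwise
  E11 <- 0.5 * (Fm[, , 1, 1]^2 + Fm[, , 2, 1]^2 - 1)
  E22 <- 0.5 * (Fm[, , 1, 2]^2 + Fm[, , 2, 2]^2 - 1)
  E12 <- 0.5 * (Fm[, , 1, 1] * Fm[, , 1, 2] + Fm[, , 2, 1] * Fm[, , 2, 2])
  Em <- array(NA_real_, c(H, W, 2, 2))
  Em[, , 1, 1] <- E11; Em[, , 2, 2] <- E22
  Em[, , 1, 2] <- E12; Em[, , 2, 1] <- E12
  if (is.null(frame)) frame <- polar_frame(c(H, W), lv_center(mask))
  # quadratic forms e' E e with e in (x, y) components
  Ecc <- frame$ec_x^2 * E11 + 2 * frame$ec_x * frame$ec_y * E12 + frame$ec_y^2 * E22
  Err <- frame$er_x^2 * E11 + 2 * frame$er_x * frame$er_y * E12 + frame$er_y^2 * E22
  Ecc[!valid] <- NA; Err[!valid] <- NA
  list(F = Fm, E = Em, Ecc = Ecc, Err = Err, valid = valid & mask != 0)
}

#' AHA six-segment labels for a short-axis mask
#'
#' Mask pixels are assigned by polar angle about `center` into six 60-degree
#' sectors starting at `reference_angle` (degrees, measured counterclockwise
#' from the image x axis with "up" positive, i.e. 90 = image top), ordered
#' counterclockwise: 1 anterior, 2 anteroseptal, 3 inferoseptal, 4 inferior,
#' 5 inferolateral, 6 anterolateral.
#'
#' @param mask binary `H x W`.
#' @param center `(row, col)` 0-based; defaults to [lv_center()].
#' @param reference_angle degrees; default 90 (anterior insertion at image
#'   top).
#' @return integer `H x W` matrix, 1..6 on mask, `NA` off mask.
#' @export
aha_segment_labels <- function(mask, center = NULL,
                               reference_angle = 90) {
  if (sum(mask != 0) == 0L) stop("empty mask")
  if (is.null(center)) center <- suppressWarnings(lv_center(mask))
  H <- nrow(mask); W <- ncol(mask)
  dy <- matrix((seq_len(H) - 1) - center[1], H, W)
  dx <- matrix((seq_len(W) - 1) - center[2], H, W, byrow = TRUE)
  # angle CCW with image up: flip the row axis
  ang <- atan2(-dy, dx) * 180 / pi
  rel <- (ang - reference_angle) %% 360
  lab <- (floor(rel / 60) %% 6) + 1
  lab[mask == 0] <- NA
  matrix(as.integer(lab), H, W)
}

#' Segment-averaged strain table for one frame
#'
#' Per-segment means of the pixelwise Ecc/Err maps over valid pixels,
#' reported in percent, plus a pixel-count-weighted global row. Segments
#' without valid pixels are reported as `NA`.
#'
#' @param Ecc,Err `H x W` strain maps (fractions).
#' @param labels integer segment map from [aha_segment_labels()].
#' @param valid logical map of usable pixels.
#' @param frame 0-based frame index recorded in the table.
#' @return tibble with columns `frame`, `segment` ("1".."6", "global"),
#'   `n_pixels`, `Ecc_percent`, `Err_percent`.
#' @export
segment_strain_table <- function(Ecc, Err, labels, valid, frame = 0L) {
  stopifnot(identical(dim(Ecc), dim(labels)), identical(dim(Err), dim(labels)))
  use <- valid & !is.na(labels) & !is.na(Ecc) & !is.na(Err)
  if (!any(use)) stop("no valid pixels in any segment")
  seg <- lapply(1:6, function(s) {
    sel <- use & labels == s
    n <- sum(sel, na.rm = TRUE)
    tibble::tibble(frame = as.integer(frame), segment = as.character(s),
                   n_pixels = n,
                   Ecc_percent = if (n > 0) 100 * mean(Ecc[sel]) else NA_real_,
                   Err_percent = if (n > 0) 100 * mean(Err[sel]) else NA_real_)
  })
  tab <- dplyr::bind_rows(seg)
  ntot <- sum(tab$n_pixels)
  glob <- tibble::tibble(
    frame = as.integer(frame), segment = "global", n_pixels = ntot,
    Ecc_percent = sum(tab$Ecc_percent * tab$n_pixels, na.rm = TRUE) / ntot,
    Err_percent = sum(tab$Err_percent * tab$n_pixels, na.rm = TRUE) / ntot)
  dplyr::bind_rows(tab, glob)
}

#' Full strain analysis of a displacement sequence
#'
#' Runs [compute_strain_maps()] and [segment_strain_table()] on every frame
#' of a Lagrangian displacement sequence, using the frame-0 mask as the
#' reference configuration.
#'
#' @param disp a [displacement_sequence] (signed mm).
#' @param mask reference binary `H x W` mask; default: the sequence's
#'   foreground mask at frame 1.
#' @param reference_angle degrees, passed to [aha_segment_labels()].
#' @return tibble of per-frame tables bound together.
#' @export
strain_analysis <- function(disp, mask = NULL, reference_angle = 90) {
  stopifnot(inherits(disp, "displacement_sequence"))
  if (is.null(mask)) mask <- disp$foreground_mask[, , 1] * 1
  center <- suppressWarnings(lv_center(mask))
  pf <- polar_frame(dim(mask), center)
  labels <- aha_segment_labels(mask, center, reference_angle)
  out <- lapply(seq_len(disp$n), function(t) {
    sm <- compute_strain_maps(disp$ux[, , t], disp$uy[, , t], mask,
                              disp$pixel_spacing, frame = pf)
    segment_strain_table(sm$Ecc, sm$Err, labels, sm$valid, frame = t - 1L)
  })
  dplyr::bind_rows(out)
}

#' Peak (maximal-magnitude) strain per segment across frames
#'
#' For each segment and strain component, the signed value with the largest
#' absolute magnitude over the cycle, with the frame at which it occurs
#' (ties resolve to the earliest frame).
#'
#' @param tables a bound per-frame table from [strain_analysis()].
#' @return tibble: `segment`, `Ecc_peak_percent`, `Ecc_peak_frame`,
#'   `Err_peak_percent`, `Err_peak_frame`.
#' @export
peak_strain <- function(tables) {
  stopifnot(length(unique(tables$frame)) >= 2)
  pick <- function(v, f) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    i <- which.max(abs(v))
    c(v[i], f[i])
  }
  segs <- unique(tables$segment)
  out <- lapply(segs, function(s) {
    d <- tables[tables$segment == s, ]
    e <- pick(d$Ecc_percent, d$frame)
    r <- pick(d$Err_percent, d$frame)
    tibble::tibble(segment = s,
                   Ecc_peak_percent = e[1], Ecc_peak_frame = as.integer(e[2]),
                   Err_peak_percent = r[1], Err_peak_frame = as.integer(r[2]))
  })
  dplyr::bind_rows(out)
}
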
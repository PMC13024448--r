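#' @importFrom stats rnorm runif sd var cor pt qt t.test p.adjust
#' @importFrom utils head tail write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Domain containers
#
# Coordinate convention (used throughout the package): arrays are indexed
# [row, col]; u_x is displacement along the column direction, u_y along the
# row direction, both in mm. Indices reported to users are 0-based pixel
# coordinates so that analytic geometry (centers, radii) matches the NIfTI
# voxel grid.
# ---------------------------------------------------------------------------

#' Construct a cine mask sequence
#'
#' A stack of binary left-ventricular myocardium masks across the cardiac
#' cycle, the input of the displacement-regression networks.
#'
#' @param frames numeric array `H x W x T` with values in \{0, 1\}.
#' @param pixel_spacing in-plane pixel size in mm.
#' @param scan_id,slice_id identifiers used for scan-level data splitting.
#' @return A `cine_sequence` object.
#' @export
cine_sequence <- function(frames, pixel_spacing, scan_id = "scan", slice_id = "slice") {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (H x W x T); got ", length(dim(frames)), " dims")
  if (dim(frames)[3] < 2L) stop("a cine sequence needs at least 2 frames")
  if (!all(frames %in% c(0, 1)))
    stop("mask values must be binary (0/1)")
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("`pixel_spacing` must be a positive scalar (mm)")
  structure(
    list(frames = frames, pixel_spacing = pixel_spacing,
         scan_id = scan_id, slice_id = slice_id,
         n = dim(frames)[3]),
    class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> %s/%s: %d frames of %dx%d, %.3g mm/px\n",
              x$scan_id, x$slice_id, d[3], d[1], d[2], x$pixel_spacing))
  invisible(x)
}

#' Construct a displacement-field sequence
#'
#' Per-frame signed in-plane displacement fields in mm, Lagrangian with
#' respect to frame 0 (every frame's field lives on the reference grid of the
#' first frame). Background pixels (outside the myocardium) are 0 in the
#' signed fields and excluded by `foreground_mask`.
#'
#' @param ux,uy numeric arrays `H x W x T`, column-direction (x) and
#'   row-direction (y) displacement in mm.
#' @param foreground_mask logical/binary `H x W` (shared across frames) or
#'   `H x W x T` array marking pixels where the field is defined.
#' @param pixel_spacing mm per pixel.
#' @param scan_id,slice_id identifiers.
#' @param scale optional [affine_scale] already attached; when present,
#'   `normalized_x`/`normalized_y` are populated.
#' @return A `displacement_sequence` object.
#' @export
displacement_sequence <- function(ux, uy, foreground_mask, pixel_spacing,
                                  scan_id = "scan", slice_id = "slice",
                                  scale = NULL) {
  ux <- as.array(ux); uy <- as.array(uy)
  if (!identical(dim(ux), dim(uy)))
    stop("ux and uy must share dimensions")
  if (length(dim(ux)) != 3L)
    stop("displacement fields must be H x W x T arrays")
  fm <- as.array(foreground_mask) != 0
  if (length(dim(fm)) == 2L)
    fm <- array(fm, dim = dim(ux))
  if (!identical(dim(fm), dim(ux)))
    stop("foreground_mask dimensions must match the fields (H x W or H x W x T)")
  obj <- structure(
    list(ux = ux, uy = uy, foreground_mask = fm,
         pixel_spacing = pixel_spacing,
         scan_id = scan_id, slice_id = slice_id,
         n = dim(ux)[3],
         scale = NULL, normalized_x = NULL, normalized_y = NULL),
    class = "displacement_sequence")
  if (!is.null(scale)) obj <- attach_scale(obj, scale)
  obj
}

#' @export
print.displacement_sequence <- function(x, ...) {
  d <- dim(x$ux)
  cat(sprintf("<displacement_sequence> %s/%s: %d frames of %dx%d, |u| max %.3g mm%s\n",
              x$scan_id, x$slice_id, d[3], d[1], d[2],
              max(abs(c(x$ux[x$foreground_mask], x$uy[x$foreground_mask], 0))),
              if (is.null(x$scale)) "" else sprintf(", normalized (d_max %.3g mm)", x$scale$d_max)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Invertible affine normalization
# ---------------------------------------------------------------------------

#' Affine displacement normalization scale
#'
#' Signed displacements in \eqn{[-d_{max}, +d_{max}]} mm are mapped to 8-bit
#' intensities in \[32, 255\] (background fixed at 0) and then divided by 255,
#' so normalized foreground values lie in \[32/255, 1\]. The lower bound
#' 32/255 = 0.1255 sits just above the 0.125 foreground threshold used by the
#' masked loss, cleanly separating foreground from the 0 background. The map
#' is strictly monotone and exactly invertible on the foreground.
#'
#' @param d_max symmetric half-range in mm; must be > 0.
#' @return An `affine_scale` object with fields `d_max`, `intensity_lo` (32),
#'   `intensity_hi` (255), `background_sentinel` (0).
#' @export
affine_scale <- function(d_max) {
  if (!is.numeric(d_max) || length(d_max) != 1L || !is.finite(d_max) || d_max <= 0)
    stop("`d_max` must be a positive finite scalar (mm); degenerate scale")
  structure(list(d_max = as.numeric(d_max),
                 intensity_lo = 32, intensity_hi = 255,
                 background_sentinel = 0),
            class = "affine_scale")
}

#' @export
print.affine_scale <- function(x, ...) {
  cat(sprintf("<affine_scale> d_max = %.6g mm -> intensities [32, 255]/255\n", x$d_max))
  invisible(x)
}

#' Normalized value below which a pixel is treated as background
#' @export
FOREGROUND_THRESHOLD <- 0.125

#' Fit the normalization scale to a collection of displacement sequences
#'
#' `d_max` is the maximum absolute signed displacement over both components
#' and all foreground pixels of the collection, optionally padded by a
#' relative margin (so unseen data slightly outside the training range still
#' normalizes without clamping).
#'
#' @param displacements a `displacement_sequence` or list of them.
#' @param margin relative pad, e.g. 0.1 for 10%; default 0.
#' @return An [affine_scale].
#' @export
fit_scale <- function(displacements, margin = 0) {
  if (inherits(displacements, "displacement_sequence"))
    displacements <- list(displacements)
  m <- 0
  any_fg <- FALSE
  for (d in displacements) {
    stopifnot(inherits(d, "displacement_sequence"))
    fg <- d$foreground_mask
    if (any(fg)) {
      any_fg <- TRUE
      m <- max(m, abs(d$ux[fg]), abs(d$uy[fg]))
    }
  }
  if (!any_fg) stop("cannot fit a scale: no foreground pixels in the collection")
  if (m == 0) stop("cannot fit a scale: all foreground displacements are zero (degenerate)")
  affine_scale(m * (1 + margin))
}

#' Map signed displacement (mm) to the normalized [0,1] scale
#'
#' Foreground values follow `(32 + (d + d_max) * 223 / (2 d_max)) / 255`;
#' background pixels map to exactly 0 regardless of `d`. Values beyond
#' `d_max` in magnitude are clamped to the bound with a warning reporting the
#' clamp count.
#'
#' @param d numeric vector/array of signed displacements in mm.
#' @param scale an [affine_scale].
#' @param foreground logical vector/array, recycled like `d`; default all TRUE.
#' @return normalized values, same shape as `d`.
#' @export
normalize_displacement <- function(d, scale, foreground = TRUE) {
  stopifnot(inherits(scale, "affine_scale"))
  dm <- scale$d_max
  fg <- rep_len(as.logical(foreground), length(d))
  n_clamp <- sum(abs(d[fg]) > dm, na.rm = TRUE)
  if (n_clamp > 0) {
    warning(sprintf("%d displacement value(s) exceed d_max = %g mm; clamped", n_clamp, dm))
    d <- pmin(pmax(d, -dm), dm)
  }
  intensity <- scale$intensity_lo +
    (d + dm) * (scale$intensity_hi - scale$intensity_lo) / (2 * dm)
  v <- intensity / 255
  v[!fg] <- scale$background_sentinel
  dim(v) <- dim(d)
  v
}

#' Invert the affine normalization
#'
#' Exact algebraic inverse of [normalize_displacement()] on foreground.
#' Values below the foreground threshold (default 0.125) are background and
#' return `NA` (masked out).
#'
#' @param v normalized values in \[0, 1\].
#' @param scale an [affine_scale].
#' @param threshold foreground decision threshold on the normalized scale.
#' @return signed displacement in mm; `NA` where background.
#' @export
denormalize_displacement <- function(v, scale, threshold = FOREGROUND_THRESHOLD) {
  stopifnot(inherits(scale, "affine_scale"))
  dm <- scale$d_max
  d <- (v * 255 - scale$intensity_lo) * (2 * dm) /
    (scale$intensity_hi - scale$intensity_lo) - dm
  d[v < threshold] <- NA_real_
  d
}

#' Attach a scale to a displacement sequence, populating normalized fields
#'
#' @param d a `displacement_sequence`.
#' @param scale an [affine_scale].
#' @return the sequence with `scale`, `normalized_x`, `normalized_y` set.
#' @export
attach_scale <- function(d, scale) {
  stopifnot(inherits(d, "displacement_sequence"), inherits(scale, "affine_scale"))
  fg <- d$foreground_mask
  d$normalized_x <- normalize_displacement(d$ux, scale, fg)
  d$normalized_y <- normalize_displacement(d$uy, scale, fg)
  d$scale <- scale
  d
}

# ---------------------------------------------------------------------------
# Volume I/O (NIfTI + JSON sidecar)
# ---------------------------------------------------------------------------

#' Write a cine or displacement sequence as NIfTI
#'
#' Masks are written `H x W x T`; displacement sequences `H x W x T x 2`
#' (channel 1 = ux, channel 2 = uy, signed mm) with a JSON sidecar
#' `<path>.json` recording the pixel spacing, foreground mask definition and,
#' when a scale is attached, the affine normalization parameters so the
#' inverse map is reproducible.
#'
#' @param obj a `cine_sequence` or `displacement_sequence`.
#' @param path output file, conventionally ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "cine_sequence")) {
    img <- RNifti::asNifti(obj$frames)
    RNifti::pixdim(img) <- c(obj$pixel_spacing, obj$pixel_spacing, 1)
    RNifti::writeNifti(img, path)
    side <- list(kind = "cine", pixel_spacing = obj$pixel_spacing,
                 scan_id = obj$scan_id, slice_id = obj$slice_id,
                 n = dim(obj$frames)[3])
  } else if (inherits(obj, "displacement_sequence")) {
    arr <- array(0, dim = c(dim(obj$ux), 2))
    arr[, , , 1] <- obj$ux
    arr[, , , 2] <- obj$uy
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(obj$pixel_spacing, obj$pixel_spacing, 1, 1)
    RNifti::writeNifti(img, path)
    side <- list(kind = "displacement", pixel_spacing = obj$pixel_spacing,
                 scan_id = obj$scan_id, slice_id = obj$slice_id,
                 n = dim(obj$ux)[3],
                 foreground_shared = all(obj$foreground_mask ==
                                           obj$foreground_mask[, , rep(1, dim(obj$ux)[3])]))
    if (!is.null(obj$scale))
      side$scale <- list(d_max = obj$scale$d_max,
                         intensity_lo = obj$scale$intensity_lo,
                         intensity_hi = obj$scale$intensity_hi)
  } else stop("unsupported object of class ", paste(class(obj), collapse = "/"))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read a volume written by [write_volume()]
#'
#' @param path NIfTI file with JSON sidecar.
#' @return a `cine_sequence` or `displacement_sequence`.
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(as.array(img)), dim = dim(img))  # plain array, no NIfTI attrs
  if (identical(side$kind, "cine")) {
    if (length(dim(arr)) != 3L)
      stop("cine volume must have shape (H, W, T); axis count is ", length(dim(arr)))
    if (dim(arr)[3] != side$n)
      stop("frame axis length ", dim(arr)[3], " disagrees with sidecar n = ", side$n)
    cine_sequence(arr, side$pixel_spacing, side$scan_id, side$slice_id)
  } else if (identical(side$kind, "displacement")) {
    if (length(dim(arr)) != 4L || dim(arr)[4] != 2L)
      stop("displacement volume must have shape (H, W, T, 2); got axes [",
           paste(dim(arr), collapse = ", "), "]")
    if (dim(arr)[3] != side$n)
      stop("frame axis length ", dim(arr)[3], " disagrees with sidecar n = ", side$n)
    ux <- arr[, , , 1, drop = TRUE]
    uy <- arr[, , , 2, drop = TRUE]
    fg <- (ux != 0) | (uy != 0)
    # frame 0 is identically zero in the Lagrangian convention; take the
    # union over frames so the reference mask covers it
    fg_any <- apply(fg, c(1, 2), any)
    fg <- array(fg_any, dim = dim(ux))
    d <- displacement_sequence(ux, uy, fg, side$pixel_spacing,
                               side$scan_id, side$slice_id)
    if (!is.null(side$scale)) d <- attach_scale(d, affine_scale(side$scale$d_max))
    d
  } else stop("sidecar does not identify a known volume kind")
}

#' Center-crop an image stack
#'
#' @param stack array with the first two dims spatial (H x W x ...).
#' @param size target side length (default 128).
#' @return cropped stack, warning if a nonempty mask centroid falls outside.
#' @export
center_crop <- function(stack, size = 128) {
  d <- dim(stack)
  if (d[1] < size || d[2] < size)
    stop(sprintf("input %dx%d is smaller than the %dx%d crop; refusing to pad",
                 d[1], d[2], size, size))
  r0 <- floor((d[1] - size) / 2)
  c0 <- floor((d[2] - size) / 2)
  idx_r <- r0 + seq_len(size)
  idx_c <- c0 + seq_len(size)
  out <- if (length(d) == 2L) stack[idx_r, idx_c, drop = FALSE]
  else if (length(d) == 3L) stack[idx_r, idx_c, , drop = FALSE]
  else if (length(d) == 4L) stack[idx_r, idx_c, , , drop = FALSE]
  else stop("center_crop supports 2-4 dimensional stacks")
  if (any(stack != 0)) {
    w <- which(stack != 0, arr.ind = TRUE)
    cen <- colMeans(w)[1:2]
    if (cen[1] < r0 + 1 || cen[1] > r0 + size || cen[2] < c0 + 1 || cen[2] > c0 + size)
      warning("mask centroid falls outside the centered crop")
  }
  out
}
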
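# ---------------------------------------------------------------------------
# Synthetic deforming-annulus phantom
#
# Stands in for a short-axis cine acquisition with a tagging-derived
# reference displacement field: an annular left-ventricular wall contracts
# radially and twists rigidly over the cycle, with every quantity (motion
# map, displacement field, circumferential/radial strain) available in
# closed form.
#
# Motion model. In polar coordinates about the annulus center, material
# points move as
#     phi_t(r, theta) = ( r'(r, t), theta + beta(t) ),
#     r'(r, t) = r - a(t) * g(r),   g(r) = Ri * w((r - Ri) / (Ro - Ri)),
#     w(s) = (1 + cos(pi * s)) / 2,
# so the endocardium (r = Ri) contracts by the fraction a(t) while the
# epicardium (r = Ro) stays fixed, mimicking systolic wall thickening; the
# rigid twist beta(t) adds no strain. Both amplitudes follow a raised-cosine
# temporal ramp 0 -> peak -> 0 with its maximum at `peak_frame`
# (systole/diastole with smooth derivatives). Displacements are Lagrangian:
# stored on the frame-0 reference grid, identically zero at frame 0.
#
# Closed-form strain. Circumferential stretch lambda_c = r'/r and radial
# stretch lambda_r = dr'/dr give the Green-Lagrange components
#     Ecc = 0.5 * (lambda_c^2 - 1),   Err = 0.5 * (lambda_r^2 - 1).
# ---------------------------------------------------------------------------

#' Specification of the synthetic annulus phantom
#'
#' @param grid_size image side length in pixels.
#' @param n_frames number of cine timeframes.
#' @param center annulus center `(row, col)` in 0-based pixel coordinates;
#'   default is the image center.
#' @param inner_radius,outer_radius endocardial/epicardial radii in mm.
#' @param pixel_spacing mm per pixel.
#' @param contraction_amplitude peak fractional endocardial contraction
#'   (dimensionless, in \[0, 1)); the endocardial radius at peak is
#'   `inner_radius * (1 - contraction_amplitude)`.
#' @param twist_amplitude peak rigid rotation in radians.
#' @param peak_frame 0-based frame index of maximal deformation.
#' @param seed integer seed (reserved for randomized cohort generation; a
#'   single phantom is fully deterministic).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_size = 128, n_frames = 20,
                         center = c((grid_size - 1) / 2, (grid_size - 1) / 2),
                         inner_radius = 6, outer_radius = 12,
                         pixel_spacing = 0.25,
                         contraction_amplitude = 0.25,
                         twist_amplitude = 0.1,
                         peak_frame = 9, seed = 1L) {
  stopifnot(grid_size >= 8, n_frames >= 2)
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("need 0 < inner_radius < outer_radius")
  if (!(peak_frame >= 0 && peak_frame < n_frames))
    stop("peak_frame must lie in [0, n_frames)")
  if (contraction_amplitude < 0 || contraction_amplitude >= 1)
    stop("contraction_amplitude must be in [0, 1) so the endocardium keeps a positive radius")
  wall_px <- (outer_radius - inner_radius) / pixel_spacing
  if (wall_px < 2)
    stop(sprintf("degenerate annulus: wall is %.2f px across (< 2); increase radii or resolution",
                 wall_px))
  structure(list(grid_size = as.integer(grid_size), n_frames = as.integer(n_frames),
                 center = as.numeric(center),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 pixel_spacing = pixel_spacing,
                 contraction_amplitude = contraction_amplitude,
                 twist_amplitude = twist_amplitude,
                 peak_frame = as.integer(peak_frame), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %dpx, %d frames, annulus [%.3g, %.3g] mm @ %.3g mm/px,\n",
                     "  contraction %.3g, twist %.3g rad, peak frame %d, seed %d\n"),
              x$grid_size, x$n_frames, x$inner_radius, x$outer_radius, x$pixel_spacing,
              x$contraction_amplitude, x$twist_amplitude, x$peak_frame, x$seed))
  invisible(x)
}

# raised-cosine temporal ramp: 0 at frame 0, 1 at peak_frame, back to 0 at
# the last frame (or held if peak_frame is terminal)
phantom_ramp <- function(frame, peak_frame, n_frames) {
  f <- as.numeric(frame)
  p <- as.numeric(peak_frame)
  last <- n_frames - 1
  up <- if (p > 0) 0.5 * (1 - cos(pi * f / p)) else rep(1, length(f))
  down <- if (p < last) 0.5 * (1 - cos(pi * (last - f) / (last - p))) else rep(1, length(f))
  ifelse(f <= p, up, down)
}

# radial profile g(r) and derivative g'(r); zero outside [Ri, Ro]
phantom_g <- function(r, Ri, Ro) {
  s <- (r - Ri) / (Ro - Ri)
  out <- Ri * 0.5 * (1 + cos(pi * pmin(pmax(s, 0), 1)))
  out[r < Ri | r > Ro] <- 0
  out
}

phantom_gprime <- function(r, Ri, Ro) {
  s <- (r - Ri) / (Ro - Ri)
  out <- -Ri * 0.5 * pi * sin(pi * s) / (Ro - Ri)
  out[s < 0 | s > 1] <- 0
  out
}

# deformed radius and the two stretches at reference radius r, amplitude a
phantom_rprime <- function(r, a, Ri, Ro) r - a * phantom_g(r, Ri, Ro)
phantom_lambda_c <- function(r, a, Ri, Ro) phantom_rprime(r, a, Ri, Ro) / r
phantom_lambda_r <- function(r, a, Ri, Ro) 1 - a * phantom_gprime(r, Ri, Ro)

#' Generate one synthetic cine scan with analytic ground truth
#'
#' Renders the deforming annulus as a binary mask per frame, evaluates the
#' analytic Lagrangian displacement field on the frame-0 reference grid, and
#' returns closed-form per-segment strain for every frame.
#'
#' @param spec a [phantom_spec].
#' @param reference_angle anterior-insertion angle in degrees used for the
#'   analytic segment table (same convention as [aha_segment_labels()]).
#' @return list with elements `cine` ([cine_sequence]), `displacement`
#'   ([displacement_sequence], signed mm, Lagrangian from frame 0) and
#'   `truth` (list: `segment_strain` tibble with per-frame per-segment
#'   analytic Ecc/Err as fraction and percent; `ramp`, the temporal
#'   amplitude profile).
#' @export
make_phantom <- function(spec, reference_angle = 90) {
  stopifnot(inherits(spec, "phantom_spec"))
  G <- spec$grid_size
  n <- spec$n_frames
  sp <- spec$pixel_spacing
  Ri <- spec$inner_radius; Ro <- spec$outer_radius

  # pixel-center coordinates in mm relative to the annulus center
  rows <- (seq_len(G) - 1) - spec$center[1]
  cols <- (seq_len(G) - 1) - spec$center[2]
  ymm <- matrix(rows, G, G) * sp          # row direction
  xmm <- matrix(cols, G, G, byrow = TRUE) * sp  # column direction
  rmm <- sqrt(xmm^2 + ymm^2)
  theta <- atan2(ymm, xmm)

  ramp <- phantom_ramp(seq_len(n) - 1, spec$peak_frame, n)
  masks <- array(0, dim = c(G, G, n))
  ux <- array(0, dim = c(G, G, n))
  uy <- array(0, dim = c(G, G, n))
  ref_mask <- rmm >= Ri & rmm <= Ro
  if (sum(ref_mask) < 8)
    stop("degenerate annulus: fewer than 8 pixels in the rendered wall")

  for (t in seq_len(n)) {
    a <- spec$contraction_amplitude * ramp[t]
    b <- spec$twist_amplitude * ramp[t]
    # deformed annulus occupies [r'(Ri), r'(Ro)] = [Ri(1-a), Ro]; the radial
    # map is monotone for admissible a, so thresholding the signed distance
    # of the deformed boundary circles is radius thresholding
    ri_t <- phantom_rprime(Ri, a, Ri, Ro)
    masks[, , t] <- as.numeric(rmm >= ri_t & rmm <= Ro)
    # Lagrangian displacement at reference pixels; frames with zero
    # amplitude (in particular frame 0) are exactly zero by construction
    if (a != 0 || b != 0) {
      rp <- phantom_rprime(rmm, a, Ri, Ro)
      thp <- theta + b
      dx <- rp * cos(thp) - xmm
      dy <- rp * sin(thp) - ymm
      dx[!ref_mask] <- 0
      dy[!ref_mask] <- 0
      ux[, , t] <- dx
      uy[, , t] <- dy
    }
  }

  scan_id <- sprintf("phantom-%04d", spec$seed)
  cine <- cine_sequence(masks, sp, scan_id = scan_id)
  disp <- displacement_sequence(ux, uy, ref_mask, sp, scan_id = scan_id)

  seg <- do.call(rbind, lapply(seq_len(n) - 1, function(fr)
    analytic_segment_strain(spec, fr, reference_angle = reference_angle)))
  list(cine = cine, displacement = disp,
       truth = list(segment_strain = seg, ramp = ramp),
       spec = spec)
}

#' Closed-form wall-averaged segment strain of the phantom motion
#'
#' Computes the analytic circumferential and radial Green-Lagrange strains
#' `Ecc = (lambda_c^2 - 1)/2`, `Err = (lambda_r^2 - 1)/2` of the phantom's
#' radial contraction (the rigid twist contributes nothing), averaged over
#' the wall by area-weighted radial quadrature. The motion is axisymmetric,
#' so all six segments share the same value; the segment column is kept for
#' interface parity with [segment_strain_table()].
#'
#' @param spec a [phantom_spec].
#' @param frame 0-based frame index.
#' @param n_quad quadrature points across the wall.
#' @param reference_angle kept for interface symmetry (axisymmetric motion
#'   makes the value independent of it).
#' @return tibble with columns `frame`, `segment` (1..6), `Ecc`, `Err`
#'   (fractions) and `Ecc_percent`, `Err_percent`.
#' @export
analytic_segment_strain <- function(spec, frame, n_quad = 2048, reference_angle = 90) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (frame < 0 || frame >= spec$n_frames)
    stop("frame must lie in [0, n_frames)")
  a <- spec$contraction_amplitude *
    phantom_ramp(frame, spec$peak_frame, spec$n_frames)
  Ri <- spec$inner_radius; Ro <- spec$outer_radius
  # area-weighted wall average: integral f(r) r dr / integral r dr (midpoint rule)
  r <- Ri + (seq_len(n_quad) - 0.5) * (Ro - Ri) / n_quad
  w <- r / sum(r)
  ecc <- sum(w * 0.5 * (phantom_lambda_c(r, a, Ri, Ro)^2 - 1))
  err <- sum(w * 0.5 * (phantom_lambda_r(r, a, Ri, Ro)^2 - 1))
  tibble::tibble(frame = as.integer(frame), segment = 1:6,
                 Ecc = ecc, Err = err,
                 Ecc_percent = 100 * ecc, Err_percent = 100 * err)
}

#' Evaluate the analytic phantom displacement on an arbitrary point set
#'
#' Used by convergence tests: returns the exact Lagrangian displacement (mm)
#' of the phantom motion at reference positions given in mm relative to the
#' annulus center.
#'
#' @param spec a [phantom_spec].
#' @param frame 0-based frame index.
#' @param xmm,ymm numeric arrays of reference coordinates (mm from center).
#' @return list of arrays `ux`, `uy` (mm; 0 outside the wall).
#' @export
phantom_displacement_at <- function(spec, frame, xmm, ymm) {
  ramp <- phantom_ramp(frame, spec$peak_frame, spec$n_frames)
  a <- spec$contraction_amplitude * ramp
  b <- spec$twist_amplitude * ramp
  if (a == 0 && b == 0)
    return(list(ux = xmm * 0, uy = ymm * 0))
  r <- sqrt(xmm^2 + ymm^2)
  th <- atan2(ymm, xmm)
  rp <- phantom_rprime(r, a, spec$inner_radius, spec$outer_radius)
  ux <- rp * cos(th + b) - xmm
  uy <- rp * sin(th + b) - ymm
  out <- r >= spec$inner_radius & r <= spec$outer_radius
  ux[!out] <- 0; uy[!out] <- 0
  list(ux = ux, uy = uy)
}

#' Generate a cohort of phantom scans with per-scan variability
#'
#' Scan-to-scan variability emulates a small-animal cohort: contraction and
#' twist amplitudes, wall radii and the annulus center are jittered around
#' the base specification with seeded uniform perturbations.
#'
#' @param n_scans number of scans.
#' @param base a [phantom_spec] providing the cohort means.
#' @param seed cohort seed; scan k uses deterministic sub-seed `seed + k`.
#' @param jitter relative jitter half-width for amplitudes/radii (default
#'   0.15) ; centers move up to 1.5 px.
#' @return list of [make_phantom()] results, one per scan.
#' @export
make_phantom_cohort <- function(n_scans, base = phantom_spec(), seed = 1L,
                                jitter = 0.15) {
  stopifnot(n_scans >= 1)
  lapply(seq_len(n_scans), function(k) {
    rng <- local({ set.seed(seed * 1000L + k); runif(7, -1, 1) })
    sp <- phantom_spec(
      grid_size = base$grid_size, n_frames = base$n_frames,
      center = base$center + 1.5 * rng[1:2],
      inner_radius = base$inner_radius * (1 + jitter * rng[3]),
      outer_radius = base$outer_radius * (1 + jitter * rng[4]),
      pixel_spacing = base$pixel_spacing,
      contraction_amplitude = base$contraction_amplitude * (1 + jitter * rng[5]),
      twist_amplitude = base$twist_amplitude * (1 + jitter * rng[6]),
      peak_frame = base$peak_frame,
      seed = seed * 1000L + k)
    make_phantom(sp)
  })
}
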
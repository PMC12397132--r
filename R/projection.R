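#' Parallel-beam projection geometry with a precomputed system matrix
#'
#' Builds a 2D parallel-beam geometry for square slices: `n_angles` views
#' uniformly spaced over `[0, pi)` and radial bins spaced one pixel apart.
#' Each detector bin's line integral is discretized ray-driven: sample
#' points every `step` pixels along the ray, bilinear interpolation of
#' the image at each sample, weights scaled by the step so values are
#' line integrals in pixel-length units. The whole operator is stored as
#' one sparse system matrix, so forward projection and backprojection are
#' exact adjoints of each other - which makes OSEM's fixed-point property
#' hold by construction.
#'
#' @param n_pixels side of the square slice.
#' @param n_angles number of views, default 48.
#' @param n_radial number of radial bins; default the smallest odd count
#'   covering the image diagonal plus a margin.
#' @param step ray sampling step in pixels (default 0.5).
#' @return Object of class `projection_geometry` with the sparse matrix
#'   `A` (`n_radial * n_angles` rows, `n_pixels^2` columns), `angles`,
#'   `n_radial`, `n_angles`, `n_pixels`.
#' @export
projection_geometry <- function(n_pixels, n_angles = 48, n_radial = NULL,
                                step = 0.5) {
  if (n_pixels < 2) stop("n_pixels must be at least 2")
  if (is.null(n_radial)) {
    n_radial <- ceiling(n_pixels * sqrt(2)) + 3L
    if (n_radial %% 2L == 0L) n_radial <- n_radial + 1L
  }
  angles <- (seq_len(n_angles) - 1L) / n_angles * pi
  ctr <- (n_pixels + 1) / 2
  half_diag <- n_pixels / sqrt(2) + 1
  tgrid <- seq(-half_diag, half_diag, by = step)
  sgrid <- seq_len(n_radial) - (n_radial + 1) / 2
  # all (radial bin, ray sample) pairs for one view
  sv <- rep(sgrid, times = length(tgrid))
  tv <- rep(tgrid, each = length(sgrid))
  bin <- rep(seq_len(n_radial), times = length(tgrid))
  ii <- jj <- xx <- vector("list", n_angles)
  for (a in seq_len(n_angles)) {
    co <- cos(angles[a]); si <- sin(angles[a])
    # ray point: s * (cos, sin) + t * (-sin, cos), in pixel index space
    px <- sv * co - tv * si + ctr
    py <- sv * si + tv * co + ctr
    i0 <- floor(px); j0 <- floor(py)
    fx <- px - i0; fy <- py - j0
    keep <- i0 >= 1L & i0 + 1L <= n_pixels & j0 >= 1L & j0 + 1L <= n_pixels
    i0 <- i0[keep]; j0 <- j0[keep]; fx <- fx[keep]; fy <- fy[keep]
    row <- (a - 1L) * n_radial + bin[keep]
    base <- i0 + (j0 - 1L) * n_pixels
    ii[[a]] <- rep(row, 4L)
    jj[[a]] <- c(base, base + 1L, base + n_pixels, base + n_pixels + 1L)
    xx[[a]] <- step * c((1 - fx) * (1 - fy), fx * (1 - fy),
                        (1 - fx) * fy, fx * fy)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_radial * n_angles, n_pixels^2))
  structure(list(A = A, angles = angles, n_radial = n_radial,
                 n_angles = n_angles, n_pixels = n_pixels, step = step),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection_geometry: %d px, %d angles x %d radial bins\n",
              x$n_pixels, x$n_angles, x$n_radial))
  invisible(x)
}

#' Forward-project an image slice
#'
#' Discrete parallel-beam radon transform of a square slice; if an
#' attenuation map is supplied, each line integral is multiplied by
#' \eqn{e^{-\int \mu}} along the same ray.
#'
#' @param image_slice square numeric matrix.
#' @param geom a [projection_geometry()] of matching `n_pixels`.
#' @param mu_slice optional attenuation map, 1/cm, same shape.
#' @param px_cm pixel size in cm (used only for the attenuation integral).
#' @return Sinogram matrix, `n_radial` x `n_angles`.
#' @export
forward_project <- function(image_slice, geom, mu_slice = NULL, px_cm = 0.1) {
  stopifnot(inherits(geom, "projection_geometry"))
  d <- dim(image_slice)
  if (is.null(d) || d[1L] != d[2L]) stop("image slice must be square")
  if (d[1L] != geom$n_pixels)
    stop("slice size ", d[1L], " != geometry n_pixels ", geom$n_pixels)
  p <- as.numeric(geom$A %*% as.vector(image_slice))
  if (!is.null(mu_slice))
    p <- p * attenuation_factors(geom, mu_slice, px_cm)
  matrix(p, geom$n_radial, geom$n_angles)
}

#' Per-ray attenuation survival factors
#'
#' @inheritParams forward_project
#' @return Vector of factors `exp(-int mu)` in sinogram order
#'   (radial fastest), length `n_radial * n_angles`.
#' @export
attenuation_factors <- function(geom, mu_slice, px_cm = 0.1) {
  stopifnot(inherits(geom, "projection_geometry"))
  exp(-as.numeric(geom$A %*% as.vector(mu_slice)) * px_cm)
}

#' Expected coincidence counts for one frame
#'
#' Scales a line-integral sinogram of decay-corrected activity to expected
#' true counts: `trues = proj * dur_s * 2^(-t_mid/T) * trues_scale`
#' (physical decay is applied here because the ground-truth curves are
#' generated decay-corrected), plus spatially uniform expected randoms at
#' `randoms_fraction` of the mean trues.
#'
#' @param proj attenuated line-integral sinogram (matrix or vector).
#' @param frame frame index.
#' @param schedule the [frame_schedule()].
#' @param trues_scale detector sensitivity factor (counts per
#'   line-integral-second); see [calibrate_trues_scale()].
#' @param randoms_fraction expected randoms as a fraction of mean trues.
#' @param half_life tracer half-life, minutes.
#' @return list with `trues`, `randoms` (scalar expected randoms per bin)
#'   and `cal`, the scalar mapping line integrals to expected trues.
#' @export
frame_counts <- function(proj, frame, schedule, trues_scale,
                         randoms_fraction = 0.3, half_life = 110) {
  stopifnot(inherits(schedule, "frame_schedule"), trues_scale > 0)
  t_mid <- frame_mid_times(schedule)[frame]
  cal <- schedule$dur_s[frame] * 2^(-t_mid / half_life) * trues_scale
  trues <- proj * cal
  list(trues = trues, randoms = randoms_fraction * mean(trues), cal = cal)
}

#' Calibrate the detector sensitivity factor
#'
#' Chooses `trues_scale` so that the mean expected trues per non-empty
#' sinogram bin of the last (300 s) frame equals `target_mean_trues` for
#' the reference configuration; higher-sensitivity systems multiply this
#' baseline.
#'
#' @param proj_last attenuated line-integral sinogram of the last frame.
#' @param schedule the [frame_schedule()].
#' @param target_mean_trues desired mean trues per non-empty bin.
#' @param half_life tracer half-life, minutes.
#' @return Scalar `trues_scale`.
#' @export
calibrate_trues_scale <- function(proj_last, schedule, target_mean_trues = 20,
                                  half_life = 110) {
  f <- schedule$n_frames
  t_mid <- frame_mid_times(schedule)[f]
  m <- mean(proj_last[proj_last > 0])
  target_mean_trues / (m * schedule$dur_s[f] * 2^(-t_mid / half_life))
}

#' Deterministic seed derivation for noise replicates
#'
#' Mixes the master seed with replicate, frame and slice indices through a
#' chained multiplicative-congruential rule (multiplier 69069 modulo
#' 2^31 - 1), so every `(replicate, frame, slice)` cell gets its own
#' reproducible, order-insensitive RNG stream.
#'
#' @param master_seed integer master seed.
#' @param replicate,frame,slice non-negative integer indices.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, replicate = 0, frame = 0, slice = 0) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (k in c(replicate, frame, slice)) h <- (h * 69069 + 1 + k) %% m
  as.integer(h %% (m - 2)) + 1L
}

#' Poisson noise realization of an expected-counts sinogram
#'
#' Independent Poisson draw per bin with mean `expected`; the supplied
#' seed makes the draw reproducible (same seed, same counts).
#'
#' @param expected non-negative expected counts (any shape).
#' @param seed integer RNG seed, e.g. from [derive_seed()].
#' @return Integer-valued array of observed counts, same shape.
#' @export
add_poisson_noise <- function(expected, seed) {
  if (any(expected < 0)) stop("expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- stats::rpois(length(expected), as.numeric(expected))
  if (!is.null(dim(expected))) dim(out) <- dim(expected)
  out
}
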
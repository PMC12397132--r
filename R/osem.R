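#' OSEM reconstruction of one sinogram
#'
#' Ordered-subsets expectation maximization with the standard
#' multiplicative update. The forward model for subset \eqn{S} is
#' \deqn{\bar y_S = c \, a_S \odot (A_S x) + r_S}
#' with calibration scalar \eqn{c} (duration x decay x sensitivity),
#' per-ray attenuation factors \eqn{a}, and expected randoms \eqn{r} as an
#' additive background; the update is
#' \deqn{x \leftarrow \frac{x}{A_S^T (c\, a_S)} \; A_S^T\!\left(c\, a_S
#'   \frac{y_S}{\bar y_S}\right).}
#' Angles are assigned to subsets by stride (angle `i` to subset
#' `i mod n_subsets`) and processed in fixed order, so uneven subset sizes
#' are distributed deterministically. With `n_subsets = 1` this is MLEM.
#' The output is non-negative by construction; voxels with zero
#' sensitivity are set to zero and reported.
#'
#' Dividing the calibration (which includes the frame's physical decay
#' factor) back out means the returned image is decay-corrected activity
#' concentration whenever the counts were produced by [frame_counts()].
#'
#' @param counts observed sinogram (matrix `n_radial x n_angles` or
#'   vector), non-negative.
#' @param geom a [projection_geometry()].
#' @param n_iterations full OSEM iterations (each visits every subset).
#' @param n_subsets number of angle subsets.
#' @param randoms expected randoms per bin (scalar or vector).
#' @param atten per-ray attenuation factors from [attenuation_factors()],
#'   or `NULL` for none.
#' @param cal calibration scalar `c` (default 1).
#' @param init initial image value (uniform, positive).
#' @return list: `image` (square matrix, same units as the ground truth
#'   when `cal` matches the simulation), `zero_sensitivity` (logical
#'   matrix of masked voxels).
#' @export
osem_reconstruct <- function(counts, geom, n_iterations, n_subsets,
                             randoms = 0, atten = NULL, cal = 1, init = 1) {
  stopifnot(inherits(geom, "projection_geometry"),
            n_iterations >= 1, n_subsets >= 1,
            n_subsets <= geom$n_angles, cal > 0, init > 0)
  y <- as.numeric(counts)
  nb <- geom$n_radial * geom$n_angles
  if (length(y) != nb) stop("counts length does not match geometry")
  if (any(y < 0)) stop("counts must be non-negative")
  r <- rep_len(as.numeric(randoms), nb)
  a <- if (is.null(atten)) rep(1, nb) else as.numeric(atten)

  pre <- osem_precompute(geom, n_subsets, atten = a)
  x <- osem_run(pre, y, randoms = r, cal = cal,
                n_iterations = n_iterations, init = init)
  list(image = matrix(x, geom$n_pixels, geom$n_pixels),
       zero_sensitivity = matrix(pre$dead, geom$n_pixels, geom$n_pixels))
}

#' Precompute the OSEM subset decomposition
#'
#' Splits the system matrix into angle-stride subsets and precomputes the
#' unit-calibration sensitivity images, so many sinograms sharing one
#' geometry and attenuation map (e.g. all frames of a dynamic study) can
#' be reconstructed cheaply with [osem_run()].
#'
#' @inheritParams osem_reconstruct
#' @return Opaque list consumed by [osem_run()]; its `dead` field flags
#'   zero-sensitivity voxels.
#' @export
osem_precompute <- function(geom, n_subsets, atten = NULL) {
  stopifnot(inherits(geom, "projection_geometry"),
            n_subsets >= 1, n_subsets <= geom$n_angles)
  nb <- geom$n_radial * geom$n_angles
  a <- if (is.null(atten)) rep(1, nb) else as.numeric(atten)
  # angle i -> subset ((i-1) %% n_subsets) + 1, fixed processing order
  rows_of <- lapply(seq_len(n_subsets), function(s) {
    ang <- seq(s, geom$n_angles, by = n_subsets)
    as.vector(outer(seq_len(geom$n_radial), (ang - 1L) * geom$n_radial, `+`))
  })
  As <- lapply(rows_of, function(rs) geom$A[rs, , drop = FALSE])
  Ats <- lapply(As, Matrix::t)
  sens1 <- lapply(seq_len(n_subsets), function(s)
    as.numeric(Ats[[s]] %*% a[rows_of[[s]]]))
  dead <- Reduce(`+`, sens1) <= 0
  list(geom = geom, n_subsets = n_subsets, a = a, rows_of = rows_of,
       As = As, Ats = Ats, sens1 = sens1, dead = dead)
}

#' @rdname osem_precompute
#' @param pre result of [osem_precompute()].
#' @param y observed counts vector.
#' @return `osem_run` returns the reconstructed image as a vector.
#' @export
osem_run <- function(pre, y, randoms = 0, cal = 1, n_iterations = 2,
                     init = 1) {
  nb <- length(pre$a)
  y <- as.numeric(y)
  if (length(y) != nb) stop("counts length does not match geometry")
  r <- rep_len(as.numeric(randoms), nb)
  x <- rep(init, pre$geom$n_pixels^2)
  x[pre$dead] <- 0
  for (it in seq_len(n_iterations)) {
    for (s in seq_len(pre$n_subsets)) {
      rs <- pre$rows_of[[s]]
      ybar <- cal * pre$a[rs] * as.numeric(pre$As[[s]] %*% x) + r[rs]
      ratio <- ifelse(ybar > 0, y[rs] / ybar, 0)
      back <- as.numeric(pre$Ats[[s]] %*% (pre$a[rs] * ratio))
      pos <- pre$sens1[[s]] > 0
      # calibration cancels between numerator and sensitivity
      x[pos] <- x[pos] * back[pos] / pre$sens1[[s]][pos]
    }
  }
  x
}
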
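#' 4D dynamic PET image container
#'
#' @param data 4D numeric array `(x, y, z, frame)`, kBq/mL.
#' @param schedule the [frame_schedule()]; its frame count must match the
#'   4th dimension.
#' @param voxel_size mm triplet.
#' @param decay_corrected logical; reconstructed PET is decay-corrected.
#' @return Object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_size = c(1, 1, 1),
                          decay_corrected = TRUE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(data)
  if (length(d) != 4L)
    stop("data must be a 4D array, got ", length(d), " dimensions")
  if (d[4L] != schedule$n_frames)
    stop("frame axis length (", d[4L], ") != schedule n_frames (",
         schedule$n_frames, ")")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be a positive mm triplet")
  structure(list(data = data, schedule = schedule,
                 voxel_size = as.numeric(voxel_size),
                 decay_corrected = isTRUE(decay_corrected)),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic_image: %d x %d x %d voxels, %d frames, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Extract the mean TAC over a voxel mask
#'
#' @param dyn a [dynamic_image()].
#' @param mask logical/0-1 3D array on the same grid.
#' @return A [tissue_tac()] of per-frame means over the mask.
#' @export
mask_tac <- function(dyn, mask) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  if (!all(dim(mask) == d[1:3])) stop("mask grid does not match image grid")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("empty mask")
  nvox <- prod(d[1:3])
  flat <- matrix(dyn$data, nvox, d[4L])
  tissue_tac(colMeans(flat[idx, , drop = FALSE]), dyn$schedule)
}
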
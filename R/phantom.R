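#' Labeled geometric thorax phantom
#'
#' Builds a deterministic voxelized thorax on a regular grid: an elliptical
#' body (muscle) with a subcutaneous fat rim, two lung ellipsoids, a heart,
#' a liver, a spleen, a simplified spine-plus-ribs bone compartment, a
#' descending-aorta cylinder (arterial blood pool), a superior-vena-cava
#' cylinder (venous blood pool) and two spherical lung tumors, each split
#' into a center core and a border shell. Geometry is defined in
#' grid-normalized coordinates, so structure volumes scale with grid
#' resolution (about 8x more voxels when every dimension is doubled).
#'
#' Each non-air label carries the kinetic parameters of its tissue class
#' from the bundled reference set ([load_reference_kinetics()]); the two
#' blood-pool labels carry the input function directly (vb = 1 semantics).
#'
#' @param grid_shape integer triplet, default `c(128, 128, 16)`.
#' @param voxel_size mm triplet; default scales a ~400 mm transaxial and
#'   ~200 mm axial field of view to the grid.
#' @param kinetics reference kinetic parameter table; defaults to the
#'   bundled one.
#' @return Object of class `phantom_spec`: `labels` (3D integer array, 0 =
#'   air), `label_table` (label, name, class, K1, k2, k3, vb), `voxel_size`.
#' @examples
#' ph <- build_thorax_phantom(c(48, 48, 6))
#' table(ph$labels)[-1]      # voxels per structure
#' @export
build_thorax_phantom <- function(grid_shape = c(128, 128, 16),
                                 voxel_size = NULL,
                                 kinetics = load_reference_kinetics()) {
  if (length(grid_shape) != 3L || any(grid_shape < c(24, 24, 2)))
    stop("grid too small: need at least 24 x 24 x 2 voxels")
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  if (is.null(voxel_size))
    voxel_size <- c(400 / nx, 400 / ny, 200 / nz)

  X <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  Y <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  Z <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  XY <- expand.grid(X = X, Y = Y)
  lab <- array(0L, grid_shape)

  paint_xy <- function(test_xy, zmask, value) {
    m <- which(test_xy)
    m3 <- as.vector(outer(m, (which(zmask) - 1L) * nx * ny, `+`))
    lab[m3] <- value
    lab
  }
  ell_xy <- function(x0, y0, a, b)
    ((XY$X - x0) / a)^2 + ((XY$Y - y0) / b)^2 <= 1

  # body: fat rim around muscle interior
  lab <- paint_xy(ell_xy(0, 0, 0.92, 0.78), rep(TRUE, nz), 2L)   # fat
  lab <- paint_xy(ell_xy(0, 0, 0.84, 0.70), rep(TRUE, nz), 1L)   # muscle
  # bone: posterior spine + two lateral rib rods, full z
  lab <- paint_xy(ell_xy(0, 0.55, 0.10, 0.10), rep(TRUE, nz), 7L)
  lab <- paint_xy(ell_xy(-0.78, 0, 0.06, 0.06) | ell_xy(0.78, 0, 0.06, 0.06),
                  rep(TRUE, nz), 7L)

  ellipsoid <- function(x0, y0, z0, a, b, cz, value) {
    for (k in seq_len(nz)) {
      rz <- ((Z[k] - z0) / cz)^2
      if (rz > 1) next
      sc <- sqrt(1 - rz)
      m <- which(ell_xy(x0, y0, a * sc, b * sc))
      lab[m + (k - 1L) * nx * ny] <- value
    }
    lab
  }
  # lungs, then mediastinal / abdominal organs painted over them
  lab <- ellipsoid(-0.40, -0.10, 0.15, 0.26, 0.42, 0.95, 3L)
  lab <- ellipsoid(0.40, -0.10, 0.15, 0.26, 0.42, 0.95, 3L)
  lab <- ellipsoid(-0.10, -0.05, 0.00, 0.20, 0.18, 0.70, 4L)   # heart
  lab <- ellipsoid(0.30, 0.15, -0.75, 0.36, 0.36, 0.55, 5L)    # liver
  lab <- ellipsoid(-0.44, 0.18, -0.70, 0.14, 0.16, 0.45, 6L)   # spleen
  # blood pools: full-length cylinders
  lab <- paint_xy(ell_xy(-0.13, 0.40, 0.075, 0.075), rep(TRUE, nz), 12L)
  lab <- paint_xy(ell_xy(0.16, 0.12, 0.065, 0.065), rep(TRUE, nz), 13L)

  sphere_pair <- function(x0, y0, z_target, r_border, r_core, border, core) {
    k0 <- which.min(abs(Z - z_target))      # snap center to a slice
    z0 <- Z[k0]
    for (k in seq_len(nz)) {
      dz2 <- (Z[k] - z0)^2
      r2 <- (XY$X - x0)^2 + (XY$Y - y0)^2 + dz2
      m <- which(r2 <= r_border^2)
      if (length(m)) lab[m + (k - 1L) * nx * ny] <- border
      m <- which(r2 <= r_core^2)
      if (length(m)) lab[m + (k - 1L) * nx * ny] <- core
    }
    lab
  }
  lab <- sphere_pair(-0.42, -0.24, 0.05, 0.22, 0.12, 10L, 11L)  # tumor L
  lab <- sphere_pair(0.42, -0.08, 0.35, 0.18, 0.10, 8L, 9L)     # tumor R

  row_of <- function(s) which(kinetics$structure == s)
  map <- data.frame(
    label = c(1:13),
    name = c("muscle", "fat", "lungs", "heart", "liver", "spleen", "bone",
             "tumor_r_border", "tumor_r_center", "tumor_l_border",
             "tumor_l_center", "aorta", "cava"),
    class = c(rep("tissue", 11L), "arterial", "venous"),
    source = c("muscle", "fat", "lungs", "heart", "liver", "spleen", "bone",
               "tumor_border", "tumor_center", "tumor_border", "tumor_center",
               NA, NA),
    stringsAsFactors = FALSE
  )
  for (col in c("K1", "k2", "k3", "vb")) {
    map[[col]] <- NA_real_
    tis <- !is.na(map$source)
    map[[col]][tis] <- kinetics[[col]][vapply(map$source[tis], row_of, 1L)]
  }
  map$source <- NULL

  counts <- tabulate(lab, nbins = 13L)
  if (any(counts == 0L))
    stop("grid too small: empty structure(s) ",
         paste(map$name[counts == 0L], collapse = ", "))
  map$n_voxels <- counts

  structure(list(labels = lab, label_table = map,
                 voxel_size = as.numeric(voxel_size)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", paste(dim(x$labels), collapse = " x "), "voxels,",
      nrow(x$label_table), "structures\n")
  print(x$label_table, row.names = FALSE)
  invisible(x)
}

#' 511 keV attenuation map of a phantom
#'
#' Piecewise-constant linear attenuation coefficients by tissue class:
#' air 0, lung 0.03, soft tissue 0.096, bone 0.17 (all 1/cm).
#'
#' @param phantom a [phantom_spec()].
#' @return 3D array of mu values, 1/cm.
#' @export
phantom_mu_map <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  mu_of <- rep(0.096, 13)          # soft tissue default
  mu_of[3] <- 0.03                 # lungs
  mu_of[7] <- 0.17                 # bone
  mu <- array(0, dim(phantom$labels))
  nz <- phantom$labels != 0L
  mu[nz] <- mu_of[phantom$labels[nz]]
  mu
}

#' Noise-free ground-truth 4D activity from a phantom
#'
#' Every voxel of a tissue label carries the frame-averaged irreversible
#' 2TCM curve of its kinetic parameters; arterial and venous blood-pool
#' voxels carry the whole-blood input curve directly; air is zero. Curves
#' are generated decay-corrected (physical decay is applied later, at the
#' count level, by the simulator).
#'
#' @param phantom a [phantom_spec()].
#' @param schedule a [frame_schedule()].
#' @param inp an [input_function()].
#' @param fine_step_s internal model grid step, seconds (default 1).
#' @return A noise-free [dynamic_image()].
#' @export
synthesize_ground_truth <- function(phantom, schedule = make_default_schedule(),
                                    inp = default_input_function(),
                                    fine_step_s = 1) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(schedule, "frame_schedule"),
            inherits(inp, "input_function"))
  t_fine <- seq(0, schedule_end_s(schedule), by = fine_step_s) / 60
  tacs <- phantom_label_tacs(phantom, schedule, inp, t_fine)
  gs <- dim(phantom$labels)
  out <- array(0, c(gs, schedule$n_frames))
  flat <- matrix(0, prod(gs), schedule$n_frames)
  for (i in seq_len(nrow(phantom$label_table))) {
    lb <- phantom$label_table$label[i]
    idx <- which(phantom$labels == lb)
    flat[idx, ] <- rep(tacs[[i]]$values, each = length(idx))
  }
  dynamic_image(array(flat, c(gs, schedule$n_frames)), schedule,
                voxel_size = phantom$voxel_size, decay_corrected = TRUE)
}

#' Per-label noise-free TACs of a phantom
#'
#' @inheritParams synthesize_ground_truth
#' @param t_fine internal fine time grid, minutes.
#' @return Named list of [tissue_tac()], one per label-table row.
#' @export
phantom_label_tacs <- function(phantom, schedule = make_default_schedule(),
                               inp = default_input_function(),
                               t_fine = seq(0, schedule_end_s(schedule)) / 60) {
  tt <- phantom$label_table
  tacs <- vector("list", nrow(tt))
  names(tacs) <- tt$name
  for (i in seq_len(nrow(tt))) {
    if (tt$class[i] %in% c("arterial", "venous")) {
      curve <- if (tt$class[i] == "arterial") inp$cp(t_fine)
               else inp$cb(t_fine)
    } else {
      p <- kinetic_params(tt$K1[i], tt$k2[i], tt$k3[i], tt$vb[i])
      if (p$K1 > 0 && p$k2 + p$k3 == 0)
        warning("label '", tt$name[i], "': degenerate parameters ",
                "(k2 + k3 = 0), using pure-trapping limit")
      curve <- suppressWarnings(tcm2_tissue_concentration(p, inp, t_fine))
    }
    tacs[[i]] <- frame_average(t_fine, curve, schedule)
  }
  tacs
}
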
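#' Scanner configuration for the simulation harness
#'
#' Bundles the reconstruction and count-level settings that distinguish
#' the two emulated systems: a conventional short-axial-FOV scanner
#' (28 OSEM subsets) and a high-sensitivity long-axial-FOV scanner
#' (19 subsets, trues and randoms scaled by 3.5). Time-of-flight is not
#' modeled; `sensitivity_multiplier` is an optional effective stand-in
#' (default 1).
#'
#' @param name configuration tag, e.g. `"SAFOV"`.
#' @param osem_subsets number of OSEM angle subsets.
#' @param trues_scale detector sensitivity (counts per
#'   line-integral-second), or `NA` to auto-calibrate at simulation time.
#' @param trues_multiplier multiplier applied to the calibrated baseline
#'   (3.5 for the long-axial-FOV system).
#' @param randoms_fraction expected randoms as a fraction of mean trues.
#' @param n_angles projection views per slice.
#' @param attenuation_on model photon attenuation (and correct for it in
#'   reconstruction).
#' @param recon_voxel_size informational mm triplet.
#' @param sensitivity_multiplier extra effective-sensitivity factor.
#' @return Object of class `scanner_config`.
#' @export
scanner_config <- function(name, osem_subsets, trues_scale = NA_real_,
                           trues_multiplier = 1, randoms_fraction = 0.3,
                           n_angles = 48, attenuation_on = TRUE,
                           recon_voxel_size = NULL,
                           sensitivity_multiplier = 1) {
  stopifnot(osem_subsets >= 1, trues_multiplier > 0, randoms_fraction >= 0,
            n_angles >= osem_subsets, sensitivity_multiplier > 0)
  structure(list(name = name, osem_subsets = as.integer(osem_subsets),
                 trues_scale = trues_scale,
                 trues_multiplier = trues_multiplier,
                 randoms_fraction = randoms_fraction,
                 n_angles = as.integer(n_angles),
                 attenuation_on = isTRUE(attenuation_on),
                 recon_voxel_size = recon_voxel_size,
                 sensitivity_multiplier = sensitivity_multiplier),
            class = "scanner_config")
}

#' Default SAFOV-like and LAFOV-like configurations
#'
#' @param n_angles projection views per slice (desk-scale default 48).
#' @return Named list of two [scanner_config()] objects; the LAFOV-like
#'   system uses 19 subsets and 3.5x the calibrated SAFOV count level.
#' @export
default_scanner_configs <- function(n_angles = 48) {
  list(
    SAFOV = scanner_config("SAFOV", osem_subsets = 28, trues_multiplier = 1,
                           n_angles = n_angles,
                           recon_voxel_size = c(2.34, 2.34, 2.78)),
    LAFOV = scanner_config("LAFOV", osem_subsets = 19, trues_multiplier = 3.5,
                           n_angles = n_angles,
                           recon_voxel_size = c(1.65, 1.65, 1.645))
  )
}

#' Simulate a complete dynamic PET validation study
#'
#' End-to-end harness: synthesizes the noise-free ground truth from a
#' labeled phantom, forward-projects every frame and slice with
#' attenuation, scales to expected trues and randoms for each scanner
#' configuration, draws Poisson noise replicates with per-cell derived
#' seeds, and reconstructs each replicate (and the noise-free data) with
#' OSEM at the requested iteration counts. Slices are treated as
#' independent 2D problems.
#'
#' The SAFOV-like count level is auto-calibrated so the last (300 s)
#' frame averages `target_mean_trues` expected trues per non-empty bin;
#' other configurations scale that baseline by their `trues_multiplier`.
#'
#' @param phantom a [phantom_spec()].
#' @param schedule a [frame_schedule()].
#' @param inp an [input_function()].
#' @param configs named list of [scanner_config()]s.
#' @param iterations OSEM iteration counts to reconstruct at.
#' @param n_replicates Poisson noise realizations per configuration.
#' @param master_seed integer master seed (see [derive_seed()]).
#' @param frames frame indices to simulate (default all; a subset is
#'   useful for last-frame-only SUV studies).
#' @param target_mean_trues calibration target, mean trues/bin in the
#'   last frame of the baseline configuration.
#' @param out_dir optional directory; when given, ground truth, label
#'   map, schedule, reconstructions and a JSON manifest are written.
#' @param overwrite allow overwriting an existing manifest.
#' @return Object of class `sim_study`: `ground_truth` (noise-free
#'   [dynamic_image()]), `phantom`, `schedule`, `configs`,
#'   `trues_scale` (per config), and `recons[[config]][[paste0("it", k)]]`
#'   containing `noisefree` (a [dynamic_image()]) and `replicates` (list
#'   of [dynamic_image()]). Frames not simulated are zero-filled.
#' @export
simulate_study <- function(phantom, schedule = make_default_schedule(),
                           inp = default_input_function(),
                           configs = default_scanner_configs(),
                           iterations = c(2, 6), n_replicates = 3,
                           master_seed = 1, frames = NULL,
                           target_mean_trues = 20,
                           out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"), n_replicates >= 1)
  gs <- dim(phantom$labels)
  nx <- gs[1L]; nz <- gs[3L]
  if (gs[1L] != gs[2L]) stop("simulation requires square slices")
  if (is.null(frames)) frames <- seq_len(schedule$n_frames)

  gt <- synthesize_ground_truth(phantom, schedule, inp)
  mu <- phantom_mu_map(phantom)
  px_cm <- phantom$voxel_size[1L] / 10

  # geometries keyed by angle count (configs usually share one)
  geoms <- list()
  for (cf in configs) {
    key <- as.character(cf$n_angles)
    if (is.null(geoms[[key]]))
      geoms[[key]] <- projection_geometry(nx, n_angles = cf$n_angles)
  }

  decay_mid <- 2^(-frame_mid_times(schedule) / 110)

  study <- list(ground_truth = gt, phantom = phantom, schedule = schedule,
                configs = configs, master_seed = master_seed,
                frames = frames, trues_scale = list(), recons = list())
  class(study) <- "sim_study"

  for (cname in names(configs)) {
    cf <- configs[[cname]]
    geom <- geoms[[as.character(cf$n_angles)]]
    atten <- if (cf$attenuation_on) {
      lapply(seq_len(nz), function(k)
        attenuation_factors(geom, mu[, , k], px_cm))
    } else NULL

    # noise-free attenuated line integrals per (slice, frame)
    proj <- array(0, c(geom$n_radial * geom$n_angles, nz, length(frames)))
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      for (k in seq_len(nz)) {
        p <- as.numeric(geom$A %*% as.vector(gt$data[, , k, f]))
        if (!is.null(atten)) p <- p * atten[[k]]
        proj[, k, fi] <- p
      }
    }

    scale <- cf$trues_scale
    if (is.na(scale)) {
      last <- proj[, , length(frames)]
      scale <- calibrate_trues_scale(last, schedule, target_mean_trues) *
        cf$trues_multiplier * cf$sensitivity_multiplier
    }
    study$trues_scale[[cname]] <- scale

    pre <- lapply(seq_len(nz), function(k)
      osem_precompute(geom, cf$osem_subsets,
                      atten = if (is.null(atten)) NULL else atten[[k]]))

    recon_one <- function(counts_fun) {
      # counts_fun(fi, k, trues, randoms) -> observed vector
      vols <- lapply(iterations, function(i) array(0, c(gs, schedule$n_frames)))
      names(vols) <- paste0("it", iterations)
      for (fi in seq_along(frames)) {
        f <- frames[fi]
        cal <- schedule$dur_s[f] * decay_mid[f] * scale
        for (k in seq_len(nz)) {
          trues <- proj[, k, fi] * cal
          rnd <- cf$randoms_fraction * mean(trues)
          yobs <- counts_fun(fi, k, trues, rnd)
          for (i in seq_along(iterations)) {
            img <- osem_run(pre[[k]], yobs, randoms = rnd, cal = cal,
                            n_iterations = iterations[i])
            vols[[i]][, , k, f] <- img
          }
        }
      }
      lapply(vols, dynamic_image, schedule = schedule,
             voxel_size = phantom$voxel_size)
    }

    nf <- recon_one(function(fi, k, trues, rnd) trues + rnd)
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      reps[[r]] <- recon_one(function(fi, k, trues, rnd)
        add_poisson_noise(trues + rnd,
                          derive_seed(master_seed, r, frames[fi], k)))
    }
    study$recons[[cname]] <- lapply(paste0("it", iterations), function(tag)
      list(noisefree = nf[[tag]],
           replicates = lapply(reps, `[[`, tag)))
    names(study$recons[[cname]]) <- paste0("it", iterations)
  }

  if (!is.null(out_dir))
    write_sim_study(study, out_dir, overwrite = overwrite)
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", paste(dim(x$phantom$labels), collapse = " x "),
      "grid,", length(x$frames), "frames simulated\n")
  for (cn in names(x$recons))
    cat(sprintf("  %s: trues_scale %.4g, %s, %d replicates\n", cn,
                x$trues_scale[[cn]], paste(names(x$recons[[cn]]),
                                           collapse = "/"),
                length(x$recons[[cn]][[1]]$replicates)))
  invisible(x)
}
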
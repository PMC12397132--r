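#' Read a 4D dynamic PET volume with its frame schedule
#'
#' @param path 4D NIfTI file, kBq/mL.
#' @param schedule_path frame schedule text file
#'   (see [read_frame_schedule()]), or a [frame_schedule()] object.
#' @return A [dynamic_image()]; voxel sizes are taken from the header.
#' @export
read_dynamic_nifti <- function(path, schedule_path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D volume, got ", length(d), " dimensions: ", path)
  schedule <- if (inherits(schedule_path, "frame_schedule")) schedule_path
              else read_frame_schedule(schedule_path)
  if (d[4L] != schedule$n_frames)
    stop("schedule has ", schedule$n_frames, " frames but volume has ",
         d[4L], " frames: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  dynamic_image(unclass(img)[, , , , drop = FALSE], schedule,
                voxel_size = vox, decay_corrected = TRUE)
}

#' Write a dynamic image (or any array) as NIfTI
#'
#' @param dyn a [dynamic_image()] or plain array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size mm triplet for plain arrays.
#' @return `path`, invisibly.
#' @export
write_dynamic_nifti <- function(dyn, path, voxel_size = c(1, 1, 1)) {
  if (inherits(dyn, "dynamic_image")) {
    arr <- dyn$data
    voxel_size <- dyn$voxel_size
  } else arr <- dyn
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, max(0L, nd - 3L)))[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Persist a simulated study to disk
#'
#' Writes the noise-free ground truth, the label map, the schedule, every
#' reconstruction (noise-free and replicates, per configuration and
#' iteration count) as NIfTI, plus a JSON manifest recording the master
#' seed, per-replicate derived seeds, calibrated count levels, and an MD5
#' checksum for every file.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @param overwrite allow replacing an existing manifest.
#' @return The manifest, invisibly.
#' @export
write_sim_study <- function(study, out_dir, overwrite = FALSE) {
  stopifnot(inherits(study, "sim_study"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists (use overwrite = TRUE): ", manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character()
  put <- function(obj, name, vox = c(1, 1, 1)) {
    p <- file.path(out_dir, name)
    write_dynamic_nifti(obj, p, voxel_size = vox)
    files <<- c(files, name)
    p
  }
  put(study$ground_truth, "ground_truth.nii.gz")
  put(array(as.numeric(study$phantom$labels), dim(study$phantom$labels)),
      "labels.nii.gz", vox = study$phantom$voxel_size)
  write_frame_schedule(study$schedule, file.path(out_dir, "schedule.txt"))
  utils::write.csv(study$phantom$label_table,
                   file.path(out_dir, "label_table.csv"), row.names = FALSE)
  files <- c(files, "schedule.txt", "label_table.csv")

  seeds <- list()
  for (cn in names(study$recons)) {
    for (tag in names(study$recons[[cn]])) {
      node <- study$recons[[cn]][[tag]]
      put(node$noisefree, sprintf("recon_%s_%s_noisefree.nii.gz", cn, tag))
      for (r in seq_along(node$replicates))
        put(node$replicates[[r]],
            sprintf("recon_%s_%s_rep%03d.nii.gz", cn, tag, r))
    }
    seeds[[cn]] <- vapply(seq_along(study$recons[[cn]][[1]]$replicates),
                          function(r) derive_seed(study$master_seed, r,
                                                  study$frames[1L], 1L), 1L)
  }

  manifest <- list(
    tool = paste0("dynpet ", as.character(utils::packageVersion("dynpet"))),
    master_seed = study$master_seed,
    frames = study$frames,
    trues_scale = study$trues_scale,
    first_cell_seeds = seeds,
    configs = lapply(study$configs, unclass),
    files = lapply(files, function(f)
      list(name = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a simulated study back from disk
#'
#' Rebuilds a `sim_study` object from a directory written by
#' [write_sim_study()]: manifest, label map plus label table, schedule,
#' ground truth and all reconstructions.
#'
#' @param study_dir directory containing `manifest.json`.
#' @return A `sim_study` list as returned by [simulate_study()].
#' @export
read_sim_study <- function(study_dir) {
  manifest_path <- file.path(study_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", study_dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  schedule <- read_frame_schedule(file.path(study_dir, "schedule.txt"))
  lab_img <- RNifti::readNifti(file.path(study_dir, "labels.nii.gz"))
  labels <- array(as.integer(round(lab_img)), dim(lab_img))
  label_table <- utils::read.csv(file.path(study_dir, "label_table.csv"),
                                 stringsAsFactors = FALSE)
  phantom <- structure(list(labels = labels, label_table = label_table,
                            voxel_size = RNifti::pixdim(lab_img)[1:3]),
                       class = "phantom_spec")
  gt <- read_dynamic_nifti(file.path(study_dir, "ground_truth.nii.gz"),
                           schedule)
  recs <- list.files(study_dir,
                     pattern = "^recon_.*_rep[0-9]+\\.nii\\.gz$")
  info <- regmatches(recs, regexec(
    "^recon_(.+)_(it[0-9]+)_rep([0-9]+)\\.nii\\.gz$", recs))
  recons <- list()
  for (m in info) {
    cn <- m[2L]; tag <- m[3L]
    if (is.null(recons[[cn]][[tag]])) {
      nf <- read_dynamic_nifti(
        file.path(study_dir, sprintf("recon_%s_%s_noisefree.nii.gz", cn, tag)),
        schedule)
      recons[[cn]][[tag]] <- list(noisefree = nf, replicates = list())
    }
    r <- as.integer(m[4L])
    recons[[cn]][[tag]]$replicates[[r]] <-
      read_dynamic_nifti(file.path(study_dir, m[1L]), schedule)
  }
  structure(list(ground_truth = gt, phantom = phantom, schedule = schedule,
                 configs = man$configs, master_seed = man$master_seed,
                 frames = man$frames, trues_scale = man$trues_scale,
                 recons = recons),
            class = "sim_study")
}

#' Write parametric maps as one NIfTI per parameter plus a JSON sidecar
#'
#' @param maps a `parametric_maps` object.
#' @param out_dir output directory.
#' @param prefix file name prefix (defaults to the model tag).
#' @return Character vector of written paths, invisibly.
#' @export
write_parametric_maps <- function(maps, out_dir, prefix = maps$model) {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (pn in names(maps$volumes)) {
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, pn))
    write_dynamic_nifti(maps$volumes[[pn]], p, voxel_size = maps$voxel_size)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, sprintf("%s_status.nii.gz", prefix))
  write_dynamic_nifti(array(as.numeric(maps$status), dim(maps$status)), p,
                      voxel_size = maps$voxel_size)
  paths <- c(paths, p)
  side <- file.path(out_dir, sprintf("%s_maps.json", prefix))
  jsonlite::write_json(
    list(model = maps$model, units = "kBq/mL inputs, parameters in native units",
         parameters = names(maps$volumes), settings = unclass(maps$settings),
         n_failed = sum(maps$status == 1L),
         n_masked = sum(maps$status == 2L)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, side))
}
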
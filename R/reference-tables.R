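#' Bundled reference kinetic parameters for thoracic FDG tissues
#'
#' Published reference values of irreversible-2TCM and Patlak parameters
#' for nine thoracic tissue classes (tumor border/center, liver, lungs,
#' bone, heart, spleen, muscle, soft-tissue fat), estimated from one-hour
#' dynamic FDG PET/MR patient data. These drive the phantom simulator's
#' ground-truth time-activity curves.
#'
#' The file is shipped under `extdata` and verified against a frozen MD5
#' checksum on load so transcription drift is impossible.
#'
#' @return data.frame with columns `structure`, `K1`, `k2`, `k3`, `vb`
#'   (2TCM), `Ki_2tcm` (the published net-influx column), `Ki_patlak`,
#'   `vb_patlak` (published Patlak estimates of the same tissues).
#' @export
load_reference_kinetics <- function() {
  .load_checked("reference_kinetics.csv", "6ab29c8ff3dd8124bc7907487bd98623")
}

#' Bundled benchmark bias tables (SAFOV / LAFOV phantom study)
#'
#' Published per-structure percent biases (mean and replicate SD over 100
#' noise realizations) of voxel-wise Patlak and irreversible-2TCM parameter
#' maps, for a short- and a long-axial-FOV scanner configuration at 2 and 6
#' OSEM iterations. Used by [median_relative_bias_change()] to recompute
#' the study-level median bias-reduction aggregates.
#'
#' @return Long-format data.frame with columns `iterations` (2 or 6),
#'   `config` (`"SAFOV"`/`"LAFOV"`), `structure` (11 levels), `parameter`
#'   (`K1,k2,k3,vb,Ki` for 2TCM; `Ki_patlak,vb_patlak`), `bias_pct`,
#'   `sd_pct`.
#' @export
load_reference_bias_tables <- function() {
  tab <- .load_checked("reference_bias_benchmark.csv",
                       "d5001b54f4de9fedeeb2eed2c3ef7cbd")
  tab$config <- as.character(tab$config)
  tab
}

.load_checked <- function(file, md5) {
  path <- system.file("extdata", file, package = "dynpet", mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5))
    stop("checksum mismatch for bundled table ", file,
         " (got ", got, ", expected ", md5, ")")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Parameter sets used in the study-level aggregates
#'
#' Convenience constants naming the 2TCM and Patlak parameter columns of
#' the bundled bias tables.
#' @name parameter_sets
#' @export
params_2tcm <- c("K1", "k2", "k3", "vb", "Ki")

#' @rdname parameter_sets
#' @export
params_patlak <- c("Ki_patlak", "vb_patlak")
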
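#' Ground-truth parameter values per structure of a phantom
#'
#' 2TCM truths come from the phantom's label table (with `Ki` via
#' [macro_ki()]); Patlak truths are computed by applying the package's
#' own Patlak estimator to the noise-free label TACs (so estimator and
#' reference share one definition); the SUV truth is the last-frame TAC
#' value converted with [suv()].
#'
#' @param phantom a [phantom_spec()].
#' @param schedule a [frame_schedule()].
#' @param inp the true [input_function()] of the simulation.
#' @param t_star Patlak linear-phase start, minutes.
#' @return Named list of named vectors (per tissue structure): `K1`,
#'   `k2`, `k3`, `vb`, `Ki`, `Ki_patlak`, `vb_patlak`, `SUV`.
#' @export
ground_truth_parameters <- function(phantom,
                                    schedule = make_default_schedule(),
                                    inp = default_input_function(),
                                    t_star = 20) {
  tt <- phantom$label_table
  tis <- tt[tt$class == "tissue", ]
  tacs <- phantom_label_tacs(phantom, schedule, inp)
  truth <- list(
    K1 = stats::setNames(tis$K1, tis$name),
    k2 = stats::setNames(tis$k2, tis$name),
    k3 = stats::setNames(tis$k3, tis$name),
    vb = stats::setNames(tis$vb, tis$name),
    Ki = stats::setNames(macro_ki(tis$K1, tis$k2, tis$k3), tis$name)
  )
  pk <- vapply(tis$name, function(nm) {
    fit <- patlak_fit(patlak_transform(tacs[[nm]], inp), t_star = t_star)
    c(fit$Ki_slope, fit$v_intercept)
  }, c(0, 0))
  truth$Ki_patlak <- pk[1L, ]
  truth$vb_patlak <- pk[2L, ]
  nf <- schedule$n_frames
  truth$SUV <- vapply(tis$name, function(nm)
    suv(tacs[[nm]]$values[nf], t = frame_mid_times(schedule)[nf]), 1.0)
  truth
}

#' Evaluate a simulated study: bias, trade-off and CNR readouts
#'
#' Runs the full parametric-imaging analysis on every reconstruction of a
#' [simulate_study()] result: extracts an image-derived input function
#' from the arterial blood-pool label of each replicate, fits Patlak (and
#' optionally 2TCM) maps voxel-wise, computes SUV maps, and aggregates
#' per-structure percent biases, noise-bias trade-off points and
#' kinetic-to-SUV CNR ratios (on the replicate-mean maps, venous
#' blood-pool background).
#'
#' @param study a `sim_study`.
#' @param models character subset of `c("patlak", "2tcm")`.
#' @param settings a [fit_settings()].
#' @param use_idif extract the input function from the reconstructed
#'   aorta (the method's own pipeline); if `FALSE`, the true simulation
#'   input function is used instead.
#' @param inp true input function (for ground-truth references, and for
#'   fitting when `use_idif = FALSE`).
#' @param erosion_radius ROI erosion for CNR tables (voxels).
#' @param idif_erosion erosion radius for the image-derived input
#'   function mask.
#' @return list with data.frames `bias` (columns `config`, `iterations`,
#'   `structure`, `parameter`, `bias_pct`, `sd_pct`), `tradeoff`, and
#'   `cnr` (per-map-type CNRs with kinetic-to-SUV ratios), plus the
#'   `truth` list used.
#' @export
evaluate_study <- function(study, models = c("patlak", "2tcm"),
                           settings = fit_settings(), use_idif = TRUE,
                           inp = default_input_function(),
                           erosion_radius = 1, idif_erosion = 1) {
  stopifnot(inherits(study, "sim_study"))
  models <- match.arg(models, several.ok = TRUE)
  phantom <- study$phantom
  labels <- phantom$labels
  tt <- phantom$label_table
  tis <- tt[tt$class == "tissue", ]
  aorta <- labels == tt$label[tt$class == "arterial"]
  truth <- ground_truth_parameters(phantom, study$schedule, inp,
                                   t_star = settings$t_star)

  bias_rows <- list(); tradeoff_rows <- list(); cnr_rows <- list()
  param_of_model <- list(patlak = c("Ki", "vb"),
                         `2tcm` = c("K1", "k2", "k3", "vb", "Ki"))
  truth_key <- list(patlak = c(Ki = "Ki_patlak", vb = "vb_patlak"),
                    `2tcm` = c(K1 = "K1", k2 = "k2", k3 = "k3", vb = "vb",
                               Ki = "Ki"))

  for (cname in names(study$recons)) for (tag in names(study$recons[[cname]])) {
    node <- study$recons[[cname]][[tag]]
    iters <- as.integer(sub("^it", "", tag))
    reps <- node$replicates
    nrep <- length(reps)

    fit_one <- function(dyn) {
      fi <- if (use_idif) extract_idif(dyn, aorta, idif_erosion) else inp
      out <- list()
      if ("patlak" %in% models)
        out$patlak <- fit_patlak_voxelwise(dyn, fi, settings)
      if ("2tcm" %in% models)
        out$`2tcm` <- fit_2tcm_voxelwise(dyn, fi, settings)
      out$suv_map <- compute_suv_map(dyn)
      out
    }
    fits <- lapply(reps, fit_one)

    # per-replicate label means, per map type and parameter
    collect <- function(getter) {
      t(vapply(fits, function(f)
        label_means(getter(f), labels, tis$label), numeric(nrow(tis))))
    }
    map_sets <- list()
    for (m in models) for (pn in param_of_model[[m]]) {
      key <- paste0(m, ".", pn)
      rm_ <- collect(function(f) f[[m]]$volumes[[pn]])
      colnames(rm_) <- tis$name
      map_sets[[key]] <- list(rep_means = rm_, model = m, param = pn,
                              truth = truth[[truth_key[[m]][[pn]]]])
    }
    suv_rm <- collect(function(f) f$suv_map)
    colnames(suv_rm) <- tis$name
    map_sets[["suv.SUV"]] <- list(rep_means = suv_rm, model = "suv",
                                  param = "SUV", truth = truth$SUV)

    for (key in names(map_sets)) {
      ms <- map_sets[[key]]
      b <- bias_per_label(ms$rep_means, ms$truth)
      b <- cbind(config = cname, iterations = iters, model = ms$model,
                 parameter = ms$param, b)
      bias_rows[[length(bias_rows) + 1L]] <- b
      if (nrep >= 2L) {
        tr <- noise_bias_tradeoff(ms$rep_means, ms$truth,
                                  iterations = iters, config = cname)
        tr <- cbind(model = ms$model, parameter = ms$param, tr)
        tradeoff_rows[[length(tradeoff_rows) + 1L]] <- tr
      }
    }

    # CNR on replicate-mean maps, ratio against the matching mean SUV map
    mean_suv <- label_mean_map(lapply(fits, function(f) f$suv_map))$mean
    suv_cnr <- cnr_table(mean_suv, labels, tt, erosion_radius)
    for (m in models) for (pn in param_of_model[[m]]) {
      mean_map <- label_mean_map(
        lapply(fits, function(f) f[[m]]$volumes[[pn]]))$mean
      kc <- cnr_table(mean_map, labels, tt, erosion_radius)
      rc <- kinetic_to_suv_cnr_ratio(kc, suv_cnr)
      rc <- cbind(config = cname, iterations = iters, model = m,
                  parameter = pn, rc)
      cnr_rows[[length(cnr_rows) + 1L]] <- rc
    }
  }

  list(bias = do.call(rbind, bias_rows),
       tradeoff = do.call(rbind, tradeoff_rows),
       cnr = do.call(rbind, cnr_rows),
       truth = truth)
}
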
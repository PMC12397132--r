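#' Voxel-wise mean and SD across noise replicates
#'
#' @param maps list of numeric arrays (>= 2) on a common grid — typically
#'   one parameter volume per noise replicate.
#' @return list with `mean` and `sd` arrays. The SD is the population SD
#'   (divide by N), matching the voxel-wise map statistics convention;
#'   replicate statistics of scalar label means use the sample SD instead
#'   (see [noise_bias_tradeoff()]).
#' @export
label_mean_map <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 replicates")
  d <- dim(maps[[1L]])
  for (m in maps) if (!all(dim(m) == d)) stop("replicate grids differ")
  n <- length(maps)
  s <- Reduce(`+`, maps)
  s2 <- Reduce(`+`, lapply(maps, function(m) m^2))
  mean <- s / n
  var <- pmax(s2 / n - mean^2, 0)
  list(mean = mean, sd = sqrt(var))
}

#' Mean of a map over each label
#'
#' @param map 3D array.
#' @param labels integer 3D label array.
#' @param ids label ids to evaluate.
#' @param na.rm drop failed/masked (`NA`) voxels from the mean.
#' @return Named numeric vector of label means.
#' @export
label_means <- function(map, labels, ids, na.rm = TRUE) {
  vapply(ids, function(l) mean(map[labels == l], na.rm = na.rm), 1.0)
}

#' Percent bias of replicate-mean label estimates against ground truth
#'
#' Implements the label-wise bias readout
#' \deqn{Bias(\%) = |(\langle est \rangle - truth) / truth| \times 100}
#' where \eqn{\langle est \rangle} is the mean over noise replicates of
#' the label-mean estimate (bias of the replicate mean). The reported
#' spread is the sample SD across replicates of the per-replicate signed
#' percent deviation. The same machinery applies unchanged to SUV maps.
#'
#' @param rep_means matrix of label means, replicates in rows, one column
#'   per structure (column names = structure names).
#' @param truth named numeric vector of ground-truth values per structure.
#' @return data.frame with `structure`, `bias_pct`, `sd_pct`,
#'   `n_replicates`; structures with zero truth are excluded and listed
#'   in `attr(, "excluded")`.
#' @export
bias_per_label <- function(rep_means, truth) {
  truth <- truth[colnames(rep_means)]
  ok <- is.finite(truth) & truth != 0
  dev <- sweep(sweep(rep_means[, ok, drop = FALSE], 2L, truth[ok], `-`),
               2L, truth[ok], `/`) * 100
  out <- data.frame(
    structure = colnames(rep_means)[ok],
    bias_pct = abs(colMeans(dev)),
    sd_pct = apply(dev, 2L, stats::sd),
    n_replicates = nrow(rep_means),
    row.names = NULL
  )
  attr(out, "excluded") <- colnames(rep_means)[!ok]
  out
}

#' Noise-bias trade-off points
#'
#' For each structure: `NBias` is the percent bias of the replicate-mean
#' label estimate (as in [bias_per_label()]) and `NSD` is the sample SD
#' across replicates of the label mean, normalized by the ground truth,
#' in percent. One `(NBias, NSD)` point per structure; points from
#' different iteration counts and scanner configurations assemble into
#' trade-off lines.
#'
#' @inheritParams bias_per_label
#' @param iterations,config optional tags copied into the output.
#' @return data.frame with `structure`, `nbias_pct`, `nsd_pct` and tags.
#' @export
noise_bias_tradeoff <- function(rep_means, truth, iterations = NA,
                                config = NA) {
  if (nrow(rep_means) < 2L) stop("need at least 2 replicates")
  truth <- truth[colnames(rep_means)]
  ok <- is.finite(truth) & truth != 0
  m <- colMeans(rep_means[, ok, drop = FALSE])
  s <- apply(rep_means[, ok, drop = FALSE], 2L, stats::sd)
  data.frame(structure = colnames(rep_means)[ok],
             nbias_pct = abs((m - truth[ok]) / truth[ok]) * 100,
             nsd_pct = s / abs(truth[ok]) * 100,
             iterations = iterations, config = config, row.names = NULL)
}

#' Absolute contrast-to-noise ratio of a map
#'
#' \deqn{CNR = |mean(ROI_{tissue}) - mean(ROI_{bck})| / SD(ROI_{bck})}
#' computed on a (replicate-mean) map with the venous blood pool as the
#' canonical background region.
#'
#' @param map 3D array.
#' @param tissue_roi,background_roi logical/0-1 3D masks; must be
#'   disjoint, background at least 10 voxels.
#' @return Scalar CNR (>= 0). Signals an error of class
#'   `dynpet_undefined_cnr` when the background SD is zero.
#' @export
cnr <- function(map, tissue_roi, background_roi) {
  tr <- tissue_roi != 0; br <- background_roi != 0
  if (sum(br) < 10L) stop("background ROI must contain at least 10 voxels")
  if (any(tr & br)) stop("tissue and background ROIs must be disjoint")
  mt <- mean(map[tr], na.rm = TRUE)
  mb <- mean(map[br], na.rm = TRUE)
  sb <- stats::sd(map[br][is.finite(map[br])])
  if (!is.finite(sb) || sb == 0)
    stop(structure(class = c("dynpet_undefined_cnr", "error", "condition"),
                   list(message = "undefined CNR: constant background ROI",
                        call = sys.call())))
  abs(mt - mb) / sb
}

#' CNR of every structure of a labeled map
#'
#' Applies [cnr()] to each tissue structure of a label volume, using the
#' (eroded) venous blood-pool label as the common background.
#'
#' @param map 3D (replicate-mean) parameter or SUV map.
#' @param labels integer 3D label array.
#' @param label_table data.frame with `label`, `name`, `class` columns
#'   (as in a [build_thorax_phantom()] result).
#' @param erosion_radius voxels eroded off each ROI (0 disables; the
#'   erosion is skipped for any ROI it would empty).
#' @return data.frame with `structure` and `cnr`.
#' @export
cnr_table <- function(map, labels, label_table, erosion_radius = 0) {
  roi_of <- function(l) {
    m <- labels == l
    if (erosion_radius > 0) {
      e <- erode_mask(m, erosion_radius)
      if (any(e)) m <- e
    }
    m
  }
  ven <- label_table$label[label_table$class == "venous"]
  if (length(ven) != 1L) stop("label table must have exactly one venous label")
  bck <- roi_of(ven)
  tis <- label_table[label_table$class == "tissue", ]
  data.frame(structure = tis$name,
             cnr = vapply(tis$label, function(l) cnr(map, roi_of(l), bck), 1.0),
             row.names = NULL)
}

#' Kinetic-to-SUV CNR ratios
#'
#' @param kinetic_tbl,suv_tbl data.frames from [cnr_table()] on a kinetic
#'   parameter map and on the matching SUV map.
#' @return `kinetic_tbl` with added columns `cnr_suv` and `ratio`
#'   (`cnr / cnr_suv`); rows with zero SUV CNR keep an `NA` ratio and are
#'   listed in `attr(, "undefined")`.
#' @export
kinetic_to_suv_cnr_ratio <- function(kinetic_tbl, suv_tbl) {
  i <- match(kinetic_tbl$structure, suv_tbl$structure)
  if (anyNA(i)) stop("structure sets differ between the two CNR tables")
  out <- kinetic_tbl
  out$cnr_suv <- suv_tbl$cnr[i]
  out$ratio <- ifelse(out$cnr_suv > 0, out$cnr / out$cnr_suv, NA_real_)
  attr(out, "undefined") <- out$structure[!is.na(out$cnr_suv) &
                                            out$cnr_suv == 0]
  out
}

#' Median relative change in per-cell bias between two configurations
#'
#' For every (structure, parameter) cell present in both bias tables,
#' computes \eqn{100 (bias_{LAFOV} - bias_{SAFOV}) / bias_{SAFOV}} and
#' returns the median over the chosen parameter set (the 2TCM set spans
#' 5 parameters x 11 structures = 55 cells; the Patlak set 2 x 11 = 22).
#' The median of an even cell count is the mean of the central pair;
#' cells with zero baseline bias are excluded and reported.
#'
#' @param bias_safov,bias_lafov data.frames with `structure`,
#'   `parameter`, `bias_pct` columns (e.g. slices of
#'   [load_reference_bias_tables()], or [bias_per_label()] outputs with a
#'   `parameter` column added).
#' @param parameter_set parameters defining the cell set, e.g.
#'   [params_2tcm] or [params_patlak].
#' @return list: `median_pct` (raw), `median_pct_rounded` (nearest
#'   integer, the reporting convention), `n_cells`, `excluded`.
#' @export
median_relative_bias_change <- function(bias_safov, bias_lafov,
                                        parameter_set) {
  s <- bias_safov[bias_safov$parameter %in% parameter_set, ]
  l <- bias_lafov[bias_lafov$parameter %in% parameter_set, ]
  key_s <- paste(s$structure, s$parameter)
  key_l <- paste(l$structure, l$parameter)
  if (!setequal(key_s, key_l) || anyDuplicated(key_s))
    stop("the two tables must cover the same structure x parameter cells")
  l <- l[match(key_s, key_l), ]
  zero <- s$bias_pct == 0
  chg <- 100 * (l$bias_pct[!zero] - s$bias_pct[!zero]) / s$bias_pct[!zero]
  med <- stats::median(chg)
  list(median_pct = med, median_pct_rounded = round(med),
       n_cells = sum(!zero), excluded = key_s[zero])
}

#' Plot noise-bias trade-off lines
#'
#' @param points data.frame rows from [noise_bias_tradeoff()], possibly
#'   several iteration counts and configurations bound together.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `points`.
#' @export
plot_tradeoff <- function(points, ...) {
  cfgs <- unique(points$config)
  cols <- grDevices::hcl.colors(max(2L, length(cfgs)), "Dark 3")
  graphics::plot(points$nsd_pct, points$nbias_pct, type = "n",
                 xlab = "NSD (%)", ylab = "NBias (%)", ...)
  for (i in seq_along(cfgs)) {
    p <- points[points$config == cfgs[i], ]
    for (st in unique(p$structure)) {
      q <- p[p$structure == st, ]
      q <- q[order(q$iterations), ]
      graphics::lines(q$nsd_pct, q$nbias_pct, col = cols[i],
                      lty = if (i == 1L) 2L else 1L)
      graphics::points(q$nsd_pct, q$nbias_pct, col = cols[i],
                       pch = c(1L, 15L)[seq_len(nrow(q))])
    }
  }
  graphics::legend("topright", legend = cfgs, col = cols[seq_along(cfgs)],
                   lty = seq_along(cfgs), bty = "n")
  invisible(points)
}

#' Bar plot of kinetic-to-SUV CNR ratios
#'
#' @param ratio_tbl data.frame from [kinetic_to_suv_cnr_ratio()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_cnr_ratios <- function(ratio_tbl, ...) {
  mids <- graphics::barplot(ratio_tbl$ratio, names.arg = ratio_tbl$structure,
                            las = 2L, ylab = "kinetic / SUV CNR", ...)
  graphics::abline(h = 1, col = "red")
  invisible(mids)
}
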
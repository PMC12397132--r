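#' Settings for voxel-wise kinetic fitting
#'
#' @param t_star start of the Patlak linear phase, minutes. The default
#'   20 min leaves more than five equilibration time constants for all
#'   bundled tissue classes (k2 + k3 >= 0.25/min).
#' @param lower,upper bounds for the 2TCM parameters `(K1, k2, k3, vb)`.
#' @param init deterministic initial point; `init_fallback` is tried once
#'   when the first fit does not converge.
#' @param weights `"uniform"` or `"duration"` (frame-duration weights).
#' @param foreground_fraction voxels whose time-integrated activity falls
#'   below this fraction of the volume maximum are masked, not fitted.
#' @param fine_step_s internal model grid step for the 2TCM forward
#'   model, seconds.
#' @param max_nfev maximum residual evaluations per voxel fit.
#' @param ftol relative convergence tolerance of the least-squares fit.
#' @return Object of class `fit_settings`.
#' @export
fit_settings <- function(t_star = 20,
                         lower = c(K1 = 0, k2 = 0, k3 = 0, vb = 0),
                         upper = c(K1 = 2, k2 = 5, k3 = 5, vb = 1),
                         init = c(K1 = 0.05, k2 = 0.2, k3 = 0.03, vb = 0.05),
                         init_fallback = c(K1 = 0.2, k2 = 0.5, k3 = 0.1,
                                           vb = 0.2),
                         weights = c("uniform", "duration"),
                         foreground_fraction = 0.01,
                         fine_step_s = 1, max_nfev = 200, ftol = 1e-8) {
  weights <- match.arg(weights)
  stopifnot(all(lower <= init), all(init <= upper),
            all(lower <= init_fallback), all(init_fallback <= upper),
            t_star >= 0, fine_step_s > 0)
  structure(list(t_star = t_star, lower = lower, upper = upper, init = init,
                 init_fallback = init_fallback, weights = weights,
                 foreground_fraction = foreground_fraction,
                 fine_step_s = fine_step_s, max_nfev = max_nfev,
                 ftol = ftol),
            class = "fit_settings")
}

# fit-status codes shared by all map producers
STATUS_OK <- 0L
STATUS_FAILED <- 1L
STATUS_MASKED <- 2L

#' Parametric map container
#'
#' One 3D volume per kinetic parameter plus a fit-status volume
#' (0 = ok, 1 = failed, 2 = masked); failed and masked voxels carry `NA`
#' in the parameter volumes, distinct from a genuine 0 estimate.
#'
#' @param volumes named list of 3D arrays on a common grid.
#' @param status integer 3D array of fit-status codes.
#' @param model model tag, `"patlak"` or `"2tcm"`.
#' @param settings the [fit_settings()] used.
#' @param voxel_size mm triplet.
#' @param diagnostics optional named list of extra volumes (residual
#'   norm, iteration count, ...).
#' @return Object of class `parametric_maps`.
#' @export
parametric_maps <- function(volumes, status, model, settings,
                            voxel_size = c(1, 1, 1), diagnostics = list()) {
  d <- dim(volumes[[1L]])
  for (v in volumes) stopifnot(all(dim(v) == d))
  stopifnot(all(dim(status) == d))
  structure(list(volumes = volumes, status = status, model = model,
                 settings = settings, voxel_size = voxel_size,
                 diagnostics = diagnostics),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("parametric_maps (%s): %s; %d ok, %d failed, %d masked\n",
              x$model, paste(names(x$volumes), collapse = ", "),
              sum(x$status == STATUS_OK), sum(x$status == STATUS_FAILED),
              sum(x$status == STATUS_MASKED)))
  invisible(x)
}

#' Binary erosion of a voxel mask
#'
#' Box erosion: a voxel survives if the whole `(2r+1)^3` neighborhood
#' (clipped at the volume edge in z only) lies inside the mask.
#'
#' @param mask logical/0-1 3D array.
#' @param radius integer erosion radius in voxels; 0 returns the mask.
#' @return Logical 3D array.
#' @export
erode_mask <- function(mask, radius = 1) {
  m <- mask != 0
  if (radius < 1) return(m)
  d <- dim(m)
  out <- m
  shift <- function(a, dx, dy, dz) {
    r <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xv <- xs + dx; yv <- ys + dy; zv <- zs + dz
    okx <- xv >= 1 & xv <= d[1]; oky <- yv >= 1 & yv <= d[2]
    okz <- zv >= 1 & zv <= d[3]
    r[xs[okx], ys[oky], zs[okz]] <- a[xv[okx], yv[oky], zv[okz]]
    r
  }
  for (dx in -radius:radius) for (dy in -radius:radius)
    for (dz in -radius:radius) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (abs(dz) >= d[3]) next     # z shift beyond the stack: edge-clipped away
      # clip z shifts at the edges so thin stacks are not eroded away axially
      sh <- shift(m, dx, dy, dz)
      if (dz != 0) {
        zedge <- if (dz > 0) seq(d[3] - dz + 1, d[3]) else seq_len(-dz)
        sh[, , zedge] <- m[, , zedge]
      }
      out <- out & sh
    }
  out
}

#' Image-derived input function from a blood-pool mask
#'
#' Extracts the mean TAC over an eroded blood-pool label (the thoracic
#' aorta in the bundled phantom) and returns it as a tabulated input
#' function on the frame mid-times, with whole blood equal to plasma. If
#' erosion empties the mask, the un-eroded mask is used and a warning is
#' recorded in the result's `warnings` attribute.
#'
#' @param dyn a [dynamic_image()].
#' @param blood_mask logical/0-1 3D array marking the blood pool.
#' @param erosion_radius voxels eroded off the mask boundary to limit
#'   partial-volume contamination.
#' @return An [input_function()] (tabulated) with attributes `n_voxels`
#'   and `warnings`.
#' @export
extract_idif <- function(dyn, blood_mask, erosion_radius = 1) {
  stopifnot(inherits(dyn, "dynamic_image"))
  if (!all(dim(blood_mask) == dim(dyn$data)[1:3]))
    stop("blood mask grid does not match image grid")
  if (!any(blood_mask != 0)) stop("blood mask is empty")
  warnings <- character()
  em <- erode_mask(blood_mask, erosion_radius)
  if (!any(em)) {
    warnings <- c(warnings, sprintf(
      "erosion radius %d emptied the blood mask; falling back to uneroded mask",
      erosion_radius))
    em <- blood_mask != 0
  }
  tac <- mask_tac(dyn, em)
  tab <- data.frame(t_min = c(0, tac$mid_min), Cp = c(0, tac$values))
  inp <- input_function(tab)
  attr(inp, "n_voxels") <- sum(em)
  attr(inp, "warnings") <- warnings
  inp
}

# shared preamble for the voxel-wise fitters
.fit_prep <- function(dyn, inp, settings) {
  d <- dim(dyn$data)
  nvox <- prod(d[1:3])
  Y <- matrix(dyn$data, nvox, d[4L])
  integ <- as.numeric(Y %*% (dyn$schedule$dur_s / 60))
  if (settings$foreground_fraction <= 0) {
    fg <- rep(TRUE, nvox)    # masking disabled: fit every voxel
  } else {
    fg <- integ > settings$foreground_fraction * max(integ, 0)
    if (max(integ) <= 0) fg <- rep(FALSE, nvox)
  }
  w <- if (settings$weights == "duration") dyn$schedule$dur_s / 60
       else rep(1, dyn$schedule$n_frames)
  list(d = d, nvox = nvox, Y = Y, fg = fg, w = w)
}

#' Voxel-wise Patlak parametric maps
#'
#' Computes the Patlak transform once (the abscissa is common to all
#' voxels) and fits the weighted least-squares line through the points
#' with mid-time `>= t_star` in closed form, fully vectorized over the
#' volume. Background voxels (below the foreground threshold) are masked;
#' voxels with fewer than 3 usable frames are flagged failed.
#'
#' @param dyn a [dynamic_image()].
#' @param inp an [input_function()] (e.g. from [extract_idif()]).
#' @param settings a [fit_settings()].
#' @return A [parametric_maps()] with volumes `Ki` (slope, mL/min/cm^3)
#'   and `vb` (intercept, dimensionless).
#' @export
fit_patlak_voxelwise <- function(dyn, inp, settings = fit_settings()) {
  stopifnot(inherits(dyn, "dynamic_image"), inherits(inp, "input_function"))
  pr <- .fit_prep(dyn, inp, settings)
  mids <- frame_mid_times(dyn$schedule)

  ref <- patlak_transform(tissue_tac(rep(0, dyn$schedule$n_frames),
                                     dyn$schedule), inp)
  usable <- ref$frame[ref$t_min >= settings$t_star]
  status <- array(STATUS_OK, pr$d[1:3])
  status[!pr$fg] <- STATUS_MASKED
  ki <- vb <- array(NA_real_, pr$d[1:3])
  if (length(usable) < 3L) {
    status[pr$fg] <- STATUS_FAILED
    warning("fewer than 3 usable Patlak frames beyond t_star")
    return(parametric_maps(list(Ki = ki, vb = vb), status, "patlak",
                           settings, dyn$voxel_size))
  }
  cp <- inp$cp(mids[usable])
  x <- ref$x_min[match(usable, ref$frame)]
  w <- pr$w[usable]
  Yv <- pr$Y[pr$fg, usable, drop = FALSE]
  yv <- sweep(Yv, 2L, cp, `/`)
  sw <- sum(w); mx <- sum(w * x) / sw
  my <- as.numeric(yv %*% w) / sw
  sxx <- sum(w * (x - mx)^2)
  slope <- as.numeric(yv %*% (w * (x - mx))) / sxx
  ki[pr$fg] <- slope
  vb[pr$fg] <- my - slope * mx
  parametric_maps(list(Ki = ki, vb = vb), status, "patlak", settings,
                  dyn$voxel_size)
}

#' Voxel-wise irreversible-2TCM parametric maps
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the frame-averaged irreversible 2TCM forward
#' model against every foreground voxel's TAC, with an analytic Jacobian.
#' Each voxel starts from the same deterministic initial point; one
#' fallback restart is attempted on non-convergence, after which the
#' voxel is flagged failed (`NA` parameters) without aborting the volume.
#' The net-influx volume `Ki` is [macro_ki()] applied voxel-wise to the
#' fitted rate constants.
#'
#' @inheritParams fit_patlak_voxelwise
#' @param voxel_subset optional logical 3D array restricting which
#'   foreground voxels are fitted (others are masked).
#' @return A [parametric_maps()] with volumes `K1`, `k2`, `k3`, `vb`,
#'   `Ki` and diagnostics `rss` (residual sum of squares) and `niter`.
#' @export
fit_2tcm_voxelwise <- function(dyn, inp, settings = fit_settings(),
                               voxel_subset = NULL) {
  stopifnot(inherits(dyn, "dynamic_image"), inherits(inp, "input_function"))
  pr <- .fit_prep(dyn, inp, settings)
  fit_mask <- pr$fg
  if (!is.null(voxel_subset)) fit_mask <- fit_mask & as.vector(voxel_subset != 0)

  model <- tcm2_frame_model(inp, dyn$schedule, settings$fine_step_s)
  sqw <- sqrt(pr$w)

  status <- array(STATUS_MASKED, pr$d[1:3])
  vols <- lapply(1:5, function(i) array(NA_real_, pr$d[1:3]))
  names(vols) <- c("K1", "k2", "k3", "vb", "Ki")
  rss <- niter <- array(NA_real_, pr$d[1:3])

  idx <- which(fit_mask)
  ctrl <- minpack.lm::nls.lm.control(maxfev = settings$max_nfev,
                                     maxiter = settings$max_nfev,
                                     ftol = settings$ftol,
                                     ptol = settings$ftol)
  for (v in idx) {
    yv <- pr$Y[v, ]
    resid_fn <- function(p) sqw * (model$predict(p) - yv)
    jac_fn <- function(p) sqw * model$jacobian(p)
    fit <- try(minpack.lm::nls.lm(par = settings$init, fn = resid_fn,
                                  jac = jac_fn, lower = settings$lower,
                                  upper = settings$upper, control = ctrl),
               silent = TRUE)
    ok <- !inherits(fit, "try-error") && fit$info %in% 1:4
    if (!ok) {
      fit2 <- try(minpack.lm::nls.lm(par = settings$init_fallback,
                                     fn = resid_fn, jac = jac_fn,
                                     lower = settings$lower,
                                     upper = settings$upper, control = ctrl),
                  silent = TRUE)
      if (!inherits(fit2, "try-error") && fit2$info %in% 1:4) {
        fit <- fit2; ok <- TRUE
      }
    }
    if (ok) {
      p <- fit$par
      vols$K1[v] <- p[1]; vols$k2[v] <- p[2]; vols$k3[v] <- p[3]
      vols$vb[v] <- p[4]
      vols$Ki[v] <- if (p[2] + p[3] > 0) p[1] * p[3] / (p[2] + p[3]) else NA_real_
      rss[v] <- fit$deviance; niter[v] <- fit$niter
      status[v] <- STATUS_OK
    } else {
      status[v] <- STATUS_FAILED
    }
  }
  parametric_maps(vols, status, "2tcm", settings, dyn$voxel_size,
                  diagnostics = list(rss = rss, niter = niter))
}

#' Frame-averaged irreversible-2TCM forward model factory
#'
#' Precomputes the fine time grid, the input-function integrals and the
#' frame-averaging operator for a schedule, and returns fast
#' `predict(par)` / `jacobian(par)` closures over the parameter vector
#' `(K1, k2, k3, vb)`. Used by [fit_2tcm_voxelwise()]; exposed for tests
#' and custom fitting loops.
#'
#' @inheritParams fit_patlak_voxelwise
#' @param schedule a [frame_schedule()].
#' @param fine_step_s internal grid step, seconds.
#' @return list with `predict`, `jacobian`, and the precomputed pieces.
#' @export
tcm2_frame_model <- function(inp, schedule, fine_step_s = 1) {
  t_fine <- seq(0, schedule_end_s(schedule), by = fine_step_s) / 60
  dt <- t_fine[2L] - t_fine[1L]
  cp <- inp$cp(t_fine)
  cb <- inp$cb(t_fine)
  W <- Matrix::Matrix(.frame_average_matrix(t_fine, schedule), sparse = TRUE)
  icp_f <- as.numeric(W %*% .cumtrapz_uniform(cp, dt))
  cb_f <- as.numeric(W %*% cb)

  predict <- function(par) {
    K1 <- par[1]; k2 <- par[2]; k3 <- par[3]; vb <- par[4]
    beta <- k2 + k3
    ct_f <- if (K1 == 0) 0 else if (beta == 0) {
      K1 * icp_f
    } else {
      e_f <- as.numeric(W %*% .exp_conv(cp, beta, dt))
      (K1 / beta) * (k3 * icp_f + k2 * e_f)
    }
    (1 - vb) * ct_f + vb * cb_f
  }
  jacobian <- function(par) {
    K1 <- par[1]; k2 <- par[2]; k3 <- par[3]; vb <- par[4]
    beta <- k2 + k3
    if (beta == 0) {
      ct_f <- K1 * icp_f
      return(cbind((1 - vb) * icp_f, 0, 0, cb_f - ct_f))
    }
    e <- .exp_conv(cp, beta, dt)
    # dE/dbeta = -G with G(t) = int (t-s) exp(-beta(t-s)) Cp ds,
    # integrated as dG/dt = E - beta G (trapezoidal update)
    n <- length(e)
    gfac <- (1 - beta * dt / 2) / (1 + beta * dt / 2)
    ginp <- (dt / 2) * (e[-n] + e[-1L]) / (1 + beta * dt / 2)
    g <- c(0, .rec_filter(ginp, gfac))
    eg_f <- as.matrix(W %*% cbind(e, g))
    e_f <- eg_f[, 1L]; g_f <- eg_f[, 2L]
    base_f <- (k3 * icp_f + k2 * e_f) / beta
    ct_f <- K1 * base_f
    common <- -ct_f / beta
    d_k2 <- common + (K1 / beta) * (e_f - k2 * g_f)
    d_k3 <- common + (K1 / beta) * (icp_f - k2 * g_f)
    cbind((1 - vb) * base_f,
          (1 - vb) * d_k2,
          (1 - vb) * d_k3,
          cb_f - ct_f)
  }
  list(predict = predict, jacobian = jacobian, t_fine = t_fine, W = W,
       icp_frames = icp_f, cb_frames = cb_f, cp_fine = cp)
}

#' SUV map from the last frame of a dynamic image
#'
#' Applies [suv()] voxel-wise to the last frame at its mid-time, with the
#' standardized defaults (60 kg body weight, 4 MBq/kg injected dose).
#'
#' @param dyn a [dynamic_image()].
#' @param injected_dose MBq.
#' @param weight kg.
#' @return 3D SUV array.
#' @export
compute_suv_map <- function(dyn, injected_dose = 240, weight = 60) {
  stopifnot(inherits(dyn, "dynamic_image"))
  nf <- dyn$schedule$n_frames
  t_mid <- frame_mid_times(dyn$schedule)[nf]
  last <- dyn$data[, , , nf, drop = FALSE]
  dim(last) <- dim(dyn$data)[1:3]
  suv(last, injected_dose, weight, t_mid)
}
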
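test_that("IDIF from homogeneous blood voxels recovers the blood TAC", {
  lab <- array(0L, c(8, 8, 2)); lab[3:6, 3:6, ] <- 12L
  tt <- data.frame(label = 12L, name = "aorta", class = "arterial",
                   K1 = NA, k2 = NA, k3 = NA, vb = NA)
  gt <- synthesize_ground_truth(tiny_phantom(lab, tt), default_sched,
                                default_inp)
  idif <- extract_idif(gt, lab == 12L, erosion_radius = 1)
  ref <- frame_average(seq(0, 3600) / 60,
                       default_inp$cp(seq(0, 3600) / 60),
                       default_sched)$values
  expect_equal(idif$cp(frame_mid_times(default_sched)), ref)
  expect_length(attr(idif, "warnings"), 0L)
  expect_equal(attr(idif, "n_voxels"), sum(erode_mask(lab == 12L, 1)))

  # erosion larger than the mask: fallback with a recorded warning
  idif2 <- extract_idif(gt, lab == 12L, erosion_radius = 5)
  expect_length(attr(idif2, "warnings"), 1L)
  expect_match(attr(idif2, "warnings"), "falling back")
  expect_equal(idif2$cp(frame_mid_times(default_sched)), ref)
  expect_error(extract_idif(gt, lab == 99L), "empty")
})

test_that("mean IDIF over noisy replicates stays within 2 SEM of truth", {
  set.seed(21)
  lab <- array(0L, c(6, 6, 1)); lab[2:5, 2:5, ] <- 12L
  tt <- data.frame(label = 12L, name = "aorta", class = "arterial",
                   K1 = NA, k2 = NA, k3 = NA, vb = NA)
  gt <- synthesize_ground_truth(tiny_phantom(lab, tt), default_sched,
                                default_inp)
  truth <- mask_tac(gt, lab == 12L)$values
  n <- 20
  curves <- matrix(0, n, 41)
  for (r in 1:n) {
    noisy <- gt
    noisy$data <- gt$data + array(rnorm(length(gt$data), 0, 2),
                                  dim(gt$data))
    curves[r, ] <- extract_idif(noisy, lab == 12L,
                                erosion_radius = 0)$cp(
                     frame_mid_times(default_sched))
  }
  sem <- apply(curves, 2, stats::sd) / sqrt(n)
  late <- 5:41   # skip near-zero early frames where SEM bounds are trivial
  expect_true(all(abs(colMeans(curves)[late] - truth[late]) <=
                    3 * sem[late] + 1e-9))
})

test_that("voxel-wise Patlak solves constructed voxels exactly", {
  # voxel sampled at frame mid-times with C = 0.02 int(Cp) + 0.1 Cp:
  # an exact line in Patlak coordinates
  tg <- seq(0, 3600) / 60
  cp <- default_inp$cp(tg)
  icp_f <- stats::approx(tg, cumsum(c(0, (cp[-length(cp)] + cp[-1]) / 2 *
                                        diff(tg))),
                         xout = frame_mid_times(default_sched))$y
  v1 <- 0.02 * icp_f + 0.1 * default_inp$cp(frame_mid_times(default_sched))
  v0 <- rep(0, 41)                                  # all-zero voxel
  curves <- rbind(matrix(rep(v1, 3), 3, byrow = TRUE), v0)
  dyn <- dyn_from_curves(curves, grid = c(2, 2, 1))
  st <- fit_settings(t_star = 20, foreground_fraction = 0)
  maps <- fit_patlak_voxelwise(dyn, default_inp, st)
  expect_equal(maps$volumes$Ki[1, 1, 1], 0.02, tolerance = 1e-4)
  expect_equal(maps$volumes$vb[1, 1, 1], 0.1, tolerance = 1e-4)
  expect_equal(maps$volumes$Ki[2, 2, 1], 0)
  expect_equal(maps$volumes$vb[2, 2, 1], 0)
  expect_true(all(maps$status == 0L))

  # background masking: with the default threshold the zero voxel is masked
  maps2 <- fit_patlak_voxelwise(dyn, default_inp, fit_settings(t_star = 20))
  expect_equal(maps2$status[2, 2, 1], 2L)
  expect_true(is.na(maps2$volumes$Ki[2, 2, 1]))
})

test_that("voxel-wise 2TCM recovers noise-free parameters within 1%", {
  heart <- c(0.11, 0.38, 0.066, 0.17)
  v_heart <- model_tac(heart[1], heart[2], heart[3], heart[4])$values
  v_blood <- frame_average(seq(0, 3600) / 60,
                           0.3 * default_inp$cb(seq(0, 3600) / 60),
                           default_sched)$values
  dyn <- dyn_from_curves(rbind(v_heart, v_blood), grid = c(2, 1, 1))
  st <- fit_settings(foreground_fraction = 0)
  maps <- fit_2tcm_voxelwise(dyn, default_inp, st)
  est <- c(maps$volumes$K1[1, 1, 1], maps$volumes$k2[1, 1, 1],
           maps$volumes$k3[1, 1, 1], maps$volumes$vb[1, 1, 1])
  expect_lt(max(abs(est - heart) / heart), 0.01)
  # blood-only voxel: no extraction, vb recovered
  expect_lt(maps$volumes$K1[2, 1, 1], 1e-4)
  expect_equal(maps$volumes$vb[2, 1, 1], 0.3, tolerance = 0.01)
  # the Ki volume is the macro formula applied voxel-wise, exactly
  ki_expected <- maps$volumes$K1 * maps$volumes$k3 /
    (maps$volumes$k2 + maps$volumes$k3)
  expect_equal(maps$volumes$Ki, ki_expected)
  expect_true(all(maps$status == 0L))
  expect_true(all(is.finite(maps$diagnostics$rss[maps$status == 0L])))
})

test_that("2TCM fitting is deterministic and never aborts the volume", {
  set.seed(9)
  v <- model_tac(0.05, 0.19, 0.06, 0.05)$values
  curves <- sweep(matrix(rnorm(4 * 41, 0, 0.5), 4), 2, v, `+`)
  dyn <- dyn_from_curves(curves, grid = c(2, 2, 1))
  st <- fit_settings(foreground_fraction = 0)
  m1 <- fit_2tcm_voxelwise(dyn, default_inp, st)
  m2 <- fit_2tcm_voxelwise(dyn, default_inp, st)
  expect_identical(m1$volumes, m2$volumes)
  expect_identical(m1$status, m2$status)
  # voxel_subset restricts fitting
  sub <- array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1))
  m3 <- fit_2tcm_voxelwise(dyn, default_inp, st, voxel_subset = sub)
  expect_equal(sum(m3$status == 0L), 1L)
  expect_equal(sum(m3$status == 2L), 3L)
})

test_that("noisy replicate estimates of a tumor voxel cover the truth", {
  set.seed(31)
  truth <- c(0.08, 0.18, 0.08, 0.07)
  v <- model_tac(truth[1], truth[2], truth[3], truth[4])$values
  n <- 60
  est <- matrix(NA_real_, n, 4)
  st <- fit_settings(foreground_fraction = 0)
  model <- tcm2_frame_model(default_inp, default_sched)
  for (r in 1:n) {
    yv <- v * (1 + rnorm(41, 0, 0.1))
    fit <- minpack.lm::nls.lm(
      par = st$init, fn = function(q) model$predict(q) - yv,
      jac = function(q) model$jacobian(q),
      lower = st$lower, upper = st$upper,
      control = minpack.lm::nls.lm.control(maxfev = 200, maxiter = 200))
    est[r, ] <- fit$par
  }
  # truth lies within the central 95% of the K1 estimate distribution
  q <- stats::quantile(est[, 1], c(0.025, 0.975))
  expect_gt(truth[1], q[1]); expect_lt(truth[1], q[2])
  expect_lt(abs(median(est[, 1]) - truth[1]) / truth[1], 0.2)
})

test_that("SUV maps follow the last frame and the dosing linearly", {
  arr <- array(2, c(3, 3, 1, 41))
  dyn <- dynamic_image(arr, default_sched)
  m <- compute_suv_map(dyn)
  expect_equal(dim(m), c(3, 3, 1))
  expect_equal(max(m) - min(m), 0)                 # uniform in, uniform out
  # doubling body weight at fixed dose doubles SUV
  expect_equal(compute_suv_map(dyn, weight = 120), 2 * m)
  # tumor border outranks muscle on the noise-free phantom
  ph <- build_thorax_phantom(c(48, 48, 6))
  gt <- synthesize_ground_truth(ph, default_sched, default_inp)
  sm <- compute_suv_map(gt)
  expect_gt(mean(sm[ph$labels == 8L]), mean(sm[ph$labels == 1L]))
})
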
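geom32 <- projection_geometry(32, n_angles = 36)

test_that("projector maps zero to zero and conserves mass across angles", {
  z <- matrix(0, 32, 32)
  expect_true(all(forward_project(z, geom32) == 0))
  set.seed(5)
  # activity restricted to the scanner field of view (inscribed disc), as
  # for any physical object; corner pixels graze the ray-sampling support
  xy <- expand.grid(x = 1:32 - 16.5, y = 1:32 - 16.5)
  img <- matrix(runif(32 * 32) * (xy$x^2 + xy$y^2 <= 14^2), 32, 32)
  sg <- forward_project(img, geom32)
  # per-angle total mass equals image mass (pixel weights sum to one)
  per_angle <- colSums(sg)
  expect_lt(max(abs(per_angle - sum(img))) / sum(img), 0.01)
  expect_error(forward_project(matrix(0, 16, 32), geom32), "square")
  expect_error(forward_project(matrix(0, 16, 16), geom32), "n_pixels")
})

test_that("centered disc projects identically at every angle", {
  # band-limited edge (3 px ramp) so the *discretized* object is itself
  # rotationally symmetric; a hard binary edge aliases on the pixel grid
  xy <- expand.grid(x = 1:32 - 16.5, y = 1:32 - 16.5)
  r <- sqrt(xy$x^2 + xy$y^2)
  disc <- matrix(pmin(pmax((10 - r) / 3, 0), 1), 32, 32)
  sg <- forward_project(disc, geom32)
  ref <- sg[, 1]
  dev <- apply(sg, 2, function(col) max(abs(col - ref)))
  expect_lt(max(dev) / max(ref), 0.01)
})

test_that("attenuation only ever reduces line integrals", {
  xy <- expand.grid(x = 1:32 - 16.5, y = 1:32 - 16.5)
  disc <- matrix(as.numeric(xy$x^2 + xy$y^2 <= 100), 32, 32)
  mu <- disc * 0.096
  sg0 <- forward_project(disc, geom32)
  sg1 <- forward_project(disc, geom32, mu_slice = mu, px_cm = 0.4)
  expect_true(all(sg1 <= sg0 + 1e-12))
  expect_lt(sum(sg1), sum(sg0))
  af <- attenuation_factors(geom32, mu, px_cm = 0.4)
  expect_true(all(af > 0 & af <= 1))
})

test_that("expected counts scale with duration, decay and sensitivity", {
  s <- make_default_schedule()
  proj <- matrix(2, 47, 36)
  a <- frame_counts(proj, 1, s, trues_scale = 1)
  # frame 13 lasts 20 s vs frame 1 at 10 s: trues double modulo decay
  b <- frame_counts(proj, 13, s, trues_scale = 1)
  dec_a <- 2^(-frame_mid_times(s)[1] / 110)
  dec_b <- 2^(-frame_mid_times(s)[13] / 110)
  expect_equal(b$trues / a$trues,
               matrix(2 * dec_b / dec_a, 47, 36))
  # a 3.5x sensitivity multiplies trues exactly 3.5x
  c35 <- frame_counts(proj, 1, s, trues_scale = 3.5)
  expect_equal(c35$trues, 3.5 * a$trues)
  # a frame centered one half-life after injection halves the decay factor
  s2 <- frame_schedule(c(0, 6450), c(6450, 300))     # mid-time 110 min
  f2 <- frame_counts(proj, 2, s2, trues_scale = 1)
  expect_equal(unname(f2$cal / 300), 0.5, tolerance = 1e-12)
  # randoms are a uniform fraction of mean trues
  expect_equal(a$randoms, 0.3 * mean(a$trues))
})

test_that("count calibration hits the requested mean trues per bin", {
  s <- make_default_schedule()
  proj <- matrix(c(rep(0, 100), runif(47 * 36 - 100, 0.5, 2)), 47, 36)
  sc <- calibrate_trues_scale(proj, s, target_mean_trues = 20)
  fc <- frame_counts(proj, 41, s, trues_scale = sc)
  expect_equal(mean(fc$trues[proj > 0]), 20, tolerance = 1e-10)
})

test_that("seed derivation is deterministic and index-sensitive", {
  expect_identical(derive_seed(42, 1, 2, 3), derive_seed(42, 1, 2, 3))
  cells <- expand.grid(r = 0:3, f = 0:3, s = 0:3)
  seeds <- mapply(derive_seed, 42, cells$r, cells$f, cells$s)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_false(derive_seed(42, 1, 2, 3) == derive_seed(43, 1, 2, 3))
})

test_that("Poisson noise respects zero means, seeds and the CLT", {
  expect_true(all(add_poisson_noise(matrix(0, 10, 10), 1) == 0))
  e <- matrix(100, 100, 100)
  a <- add_poisson_noise(e, 99); b <- add_poisson_noise(e, 99)
  expect_identical(a, b)                       # same seed, same counts
  expect_false(identical(a, add_poisson_noise(e, 100)))
  # sample mean of 1e4 bins at mean 100 within ~4 sigma of truth
  expect_gt(mean(a), 99.6); expect_lt(mean(a), 100.4)
  expect_true(all(a >= 0 & a == round(a)))
  expect_error(add_poisson_noise(matrix(-1, 2, 2), 1), "non-negative")
})
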
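test_that("replicate mean/SD maps use the population convention", {
  a <- array(1, c(4, 4, 2)); b <- array(3, c(4, 4, 2))
  mm <- label_mean_map(list(a, b))
  expect_equal(mm$mean, array(2, c(4, 4, 2)))
  expect_equal(mm$sd, array(1, c(4, 4, 2)))    # population SD of {1, 3}
  mm2 <- label_mean_map(list(a, a, a))
  expect_true(all(mm2$sd == 0))
  expect_error(label_mean_map(list(a)), "at least 2")
  expect_error(label_mean_map(list(a, array(0, c(2, 2, 2)))), "grids")
})

test_that("SD map of unit-variance noise concentrates near 1", {
  set.seed(17)
  reps <- lapply(1:50, function(i) array(rnorm(500), c(10, 10, 5)))
  mm <- label_mean_map(reps)
  # 50 * sd^2 ~ chi-square(49): P(0.8 <= sd <= 1.2) is about 0.954, and a
  # 4-sigma binomial band around that for 500 voxels reaches down to 0.92
  expect_gt(mean(mm$sd >= 0.8 & mm$sd <= 1.2), 0.92)
  expect_lt(abs(mean(mm$sd) - 1), 0.05)
})

test_that("percent bias implements the absolute replicate-mean deviation", {
  truth <- c(liver = 2, lungs = 4)
  exact <- rbind(truth, truth)
  colnames(exact) <- names(truth)
  b <- bias_per_label(exact, truth)
  expect_equal(b$bias_pct, c(0, 0))
  over <- exact * 1.2; under <- exact * 0.8
  expect_equal(bias_per_label(over, truth)$bias_pct, c(20, 20))
  expect_equal(bias_per_label(under, truth)$bias_pct, c(20, 20))
  # zero-truth structures are excluded and reported
  b0 <- bias_per_label(cbind(exact, air = c(1, 1)),
                       c(truth, air = 0))
  expect_equal(attr(b0, "excluded"), "air")
  expect_equal(nrow(b0), 2L)
})

test_that("bias is invariant under joint scaling of estimate and truth", {
  set.seed(4)
  truth <- c(a = 0.5, b = 2)
  reps <- cbind(a = runif(5, 0.4, 0.6), b = runif(5, 1.5, 2.5))
  b1 <- bias_per_label(reps, truth)
  b2 <- bias_per_label(reps * 7, truth * 7)
  expect_equal(b1$bias_pct, b2$bias_pct)
  expect_equal(b1$sd_pct, b2$sd_pct)
})

test_that("noise-bias trade-off points separate bias from spread", {
  truth <- c(liver = 2)
  # unbiased, noise-free replicates sit at the origin
  tr0 <- noise_bias_tradeoff(cbind(liver = c(2, 2, 2)), truth)
  expect_equal(tr0$nbias_pct, 0)
  expect_equal(tr0$nsd_pct, 0)
  # symmetric +-10% replicates: zero bias, sample-SD spread
  tr <- noise_bias_tradeoff(cbind(liver = c(2.2, 1.8)), truth,
                            iterations = 2, config = "SAFOV")
  expect_equal(tr$nbias_pct, 0)
  expect_equal(tr$nsd_pct, 100 * stats::sd(c(2.2, 1.8)) / 2)  # 14.14%
  expect_equal(tr$iterations, 2)
  expect_error(noise_bias_tradeoff(cbind(liver = 2), truth), "2 replicates")
})

test_that("CNR follows the background-normalized contrast definition", {
  map <- array(1, c(6, 6, 1))
  tis <- array(FALSE, c(6, 6, 1)); tis[1:2, 1:2, 1] <- TRUE
  bck <- array(FALSE, c(6, 6, 1)); bck[4:6, 1:6, 1] <- TRUE
  set.seed(8)
  map[bck] <- rnorm(sum(bck), 1, 1)
  map[tis] <- 3
  expect_equal(cnr(map, tis, bck),
               abs(3 - mean(map[bck])) / stats::sd(map[bck]))
  # constructed arithmetic: contrast 2 over unit background SD gives 2
  map2 <- map
  map2[bck] <- rep(c(0, 2), length.out = sum(bck))   # mean 1, SD ~1
  expect_equal(cnr(map2, tis, bck),
               2 / stats::sd(map2[bck]))
  # zero-contrast ROIs: two disjoint constant-equal regions give 0
  map3 <- array(5, c(6, 6, 1)); map3[bck] <- rnorm(sum(bck), 5, 0.5)
  tis2 <- array(FALSE, c(6, 6, 1)); tis2[1:2, 4:6, 1] <- TRUE
  map3[tis2] <- mean(map3[bck])
  expect_equal(cnr(map3, tis2, bck), 0)
  # error paths
  expect_error(cnr(array(1, c(6, 6, 1)), tis, bck),
               class = "dynpet_undefined_cnr")
  expect_error(cnr(map, bck, bck), "disjoint")
  small <- array(FALSE, c(6, 6, 1)); small[1, 1, 1] <- TRUE
  expect_error(cnr(map, tis, small), "10 voxels")
})

test_that("CNR is invariant under positive affine rescaling", {
  set.seed(12)
  map <- array(rnorm(216, 10, 2), c(6, 6, 6))
  tis <- array(FALSE, c(6, 6, 6)); tis[1:2, 1:2, ] <- TRUE
  bck <- array(FALSE, c(6, 6, 6)); bck[5:6, 5:6, ] <- TRUE
  expect_equal(cnr(3.2 * map + 11, tis, bck), cnr(map, tis, bck))
})

test_that("kinetic-to-SUV ratios divide matching structures", {
  k <- data.frame(structure = c("liver", "lungs"), cnr = c(4, 3))
  s <- data.frame(structure = c("lungs", "liver"), cnr = c(2, 4))
  r <- kinetic_to_suv_cnr_ratio(k, s)
  expect_equal(r$ratio, c(1, 1.5))
  s0 <- data.frame(structure = c("liver", "lungs"), cnr = c(0, 2))
  r0 <- kinetic_to_suv_cnr_ratio(k, s0)
  expect_true(is.na(r0$ratio[1]))
  expect_equal(attr(r0, "undefined"), "liver")
  expect_equal(r0$ratio[2], 1.5)
  expect_error(kinetic_to_suv_cnr_ratio(
    k, data.frame(structure = "bone", cnr = 1)), "differ")
})

test_that("median bias change handles degenerate and exact cases", {
  tbl <- data.frame(structure = rep(c("a", "b"), each = 2),
                    parameter = rep(c("Ki", "vb"), 2),
                    bias_pct = c(10, 20, 30, 40))
  same <- median_relative_bias_change(tbl, tbl, c("Ki", "vb"))
  expect_equal(same$median_pct, 0)
  half <- tbl; half$bias_pct <- half$bias_pct / 2
  expect_equal(median_relative_bias_change(tbl, half,
                                           c("Ki", "vb"))$median_pct, -50)
  # even cell count: median is the mean of the central pair
  l <- tbl; l$bias_pct <- tbl$bias_pct * c(0.5, 0.8, 1.2, 2)
  res <- median_relative_bias_change(tbl, l, c("Ki", "vb"))
  expect_equal(res$median_pct, mean(c(-20, 20)))
  # zero-baseline cells are dropped and reported
  z <- tbl; z$bias_pct[1] <- 0
  res0 <- median_relative_bias_change(z, l, c("Ki", "vb"))
  expect_equal(res0$n_cells, 3L)
  expect_match(res0$excluded, "a Ki")
  expect_error(median_relative_bias_change(
    tbl, tbl[-1, ], c("Ki", "vb")), "same structure")
})
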
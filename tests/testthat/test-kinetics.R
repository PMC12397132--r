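test_that("macro Ki reproduces the bundled reference influx values", {
  # printed net-influx column, after rounding to the printed precision
  expect_equal(round(macro_ki(0.10, 0.34, 0.04), 3), 0.011)   # liver
  expect_equal(round(macro_ki(0.11, 0.38, 0.066), 3), 0.016)  # heart
  expect_equal(round(macro_ki(0.037, 0.22, 0.044), 3), 0.006) # bone
  expect_equal(round(macro_ki(0.055, 0.28, 0.030), 3), 0.005) # spleen
  expect_equal(macro_ki(0.1, 0.3, 0), 0)      # no trapping
  expect_equal(macro_ki(0.1, 0, 0.3), 0.1)    # all extracted tracer trapped
  expect_error(macro_ki(0.1, 0, 0), class = "dynpet_degenerate")
})

test_that("macro Ki scales linearly in K1 and is scale-free in (k2, k3)", {
  set.seed(11)
  for (i in 1:20) {
    K1 <- runif(1, 0.01, 0.5); k2 <- runif(1, 0.01, 1); k3 <- runif(1, 0.01, 1)
    a <- runif(1, 0.1, 10)
    expect_equal(macro_ki(a * K1, k2, k3), a * macro_ki(K1, k2, k3))
    expect_equal(macro_ki(K1, a * k2, a * k3), macro_ki(K1, k2, k3))
  }
})

test_that("2TCM limiting cases are exact", {
  tg <- seq(0, 30, by = 1 / 60)
  # no extraction: pure blood signal
  p <- kinetic_params(0, 0.3, 0.1, 0.1)
  expect_equal(tcm2_tissue_concentration(p, default_inp, tg),
               0.1 * default_inp$cb(tg))
  # pure trapping with k2 = 0: running integral of Cp
  p <- kinetic_params(0.1, 0, 0.05, 0)
  ct <- tcm2_tissue_concentration(p, default_inp, tg)
  icp <- cumsum(c(0, (default_inp$cp(tg)[-length(tg)] +
                        default_inp$cp(tg)[-1]) / 2 * diff(tg)))
  # kernel (k3 + k2 e^-bt)/b reduces to the constant K1 when k2 = 0
  expect_equal(ct, 0.1 * icp, tolerance = 1e-6)
  # degenerate k2 + k3 = 0 signals and falls back to the trapping limit
  p <- kinetic_params(0.1, 0, 0, 0)
  expect_warning(ct0 <- tcm2_tissue_concentration(p, default_inp, tg),
                 class = "dynpet_degenerate")
  expect_equal(ct0, 0.1 * icp, tolerance = 1e-6)
})

test_that("2TCM solution matches a stiff ODE integrator to < 1e-4", {
  skip_if_not_installed("deSolve")
  tg <- seq(0, 60, by = 1 / 60)
  cpf <- default_inp$cp
  # tolerance is tighter for liver (higher blood fraction damps the
  # bolus-peak discretization error of the 1 s grid)
  for (case in list(list(p = c(0.10, 0.34, 0.04, 0.33), tol = 1e-4),
                    list(p = c(0.08, 0.18, 0.08, 0.07), tol = 5e-4))) {
    pars <- case$p
    p <- kinetic_params(pars[1], pars[2], pars[3], pars[4])
    ct <- tcm2_tissue_concentration(p, default_inp, tg)
    sol <- deSolve::ode(
      c(C1 = 0, C2 = 0), tg,
      function(t, y, q) list(c(q[1] * cpf(t) - (q[2] + q[3]) * y[1],
                               q[3] * y[1])),
      pars[1:3], method = "lsoda", rtol = 1e-9, atol = 1e-9)
    ct_ode <- (1 - pars[4]) * (sol[, 2] + sol[, 3]) +
      pars[4] * default_inp$cb(tg)
    expect_lt(max(abs(ct - ct_ode) / pmax(ct_ode, 1e-6)), case$tol)
  }
})

test_that("mass conservation: tissue tracer equals K1*int(Cp) - k2*int(C1)", {
  skip_if_not_installed("deSolve")
  tg <- seq(0, 40, by = 1 / 60)
  cpf <- default_inp$cp
  pars <- c(0.08, 0.18, 0.08)
  p <- kinetic_params(pars[1], pars[2], pars[3], 0)
  ct <- tcm2_tissue_concentration(p, default_inp, tg)
  sol <- deSolve::ode(
    c(C1 = 0, C2 = 0), tg,
    function(t, y, q) list(c(q[1] * cpf(t) - (q[2] + q[3]) * y[1],
                             q[3] * y[1])),
    pars, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(tg))
  rhs <- pars[1] * trapz(cpf(tg)) - pars[2] * trapz(sol[, 2])
  expect_lt(abs(ct[length(tg)] - rhs) / rhs, 1e-4)
})

test_that("2TCM output is non-negative for in-bound parameters", {
  set.seed(7)
  tg <- seq(0, 60, by = 1 / 30)
  for (i in 1:25) {
    p <- kinetic_params(runif(1, 0, 0.5), runif(1, 0.01, 2),
                        runif(1, 0, 1), runif(1, 0, 1))
    expect_true(all(tcm2_tissue_concentration(p, default_inp, tg) >= 0))
  }
})

test_that("frame averaging is exact for constant and linear curves", {
  s <- make_default_schedule()
  tg <- seq(0, 3600) / 60
  expect_equal(frame_average(tg, rep(3.7, length(tg)), s)$values,
               rep(3.7, 41))
  a <- 0.42
  expect_equal(frame_average(tg, a * tg, s)$values, a * frame_mid_times(s))
  expect_error(frame_average(seq(0, 30, by = 1 / 60), rep(1, 1801), s),
               "cover")
  expect_error(frame_average(seq(0, 60, by = 0.1), rep(1, 601), s),
               "at most 1 s")
})

test_that("frame averages agree with adaptive quadrature to < 0.1%", {
  skip_if_not_installed("pracma")
  s <- make_default_schedule()
  tg <- seq(0, 3600, by = 0.25) / 60   # fine grid resolves the bolus peak
  fa <- frame_average(tg, default_inp$cp(tg), s)
  for (f in c(1, 3, 12, 13, 25, 41)) {
    a <- s$start_s[f] / 60; b <- a + s$dur_s[f] / 60
    q <- pracma::integral(default_inp$cp, a, b, reltol = 1e-10) / (b - a)
    expect_lt(abs(fa$values[f] - q) / q, 1e-3)
  }
})

test_that("SUV arithmetic follows the decay-corrected dose definition", {
  # uniformly diluted dose: 240 MBq in 60 kg is 4 kBq/mL, SUV exactly 1
  expect_equal(suv(4, injected_dose = 240, weight = 60, t = 0), 1)
  # one half-life of decay doubles SUV relative to the uncorrected ratio
  expect_equal(suv(4, 240, 60, t = 110), 2 * suv(4, 240, 60, t = 0))
  expect_equal(suv(2, 240, 60, t = 0), 0.5)
  expect_error(suv(1, injected_dose = 0), "dose")
  expect_error(suv(1, weight = -1), "weight")
})

test_that("TAC container validates length and finiteness", {
  s <- make_default_schedule()
  expect_error(tissue_tac(rep(1, 40), s), "41")
  expect_error(tissue_tac(c(rep(1, 40), NA), s), "finite")
})
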
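#' Kinetic parameter set for the irreversible two-tissue compartment model
#'
#' @param K1 plasma-to-tissue transport rate, mL/min/cm^3.
#' @param k2 tissue-to-plasma washout rate, 1/min.
#' @param k3 trapping (phosphorylation) rate, 1/min.
#' @param vb fractional blood volume, dimensionless in `[0, 1]`.
#' @return An object of class `kinetic_params`; the net influx macro
#'   parameter `Ki = K1 k3 / (k2 + k3)` is attached when `k2 + k3 > 0`.
#' @export
kinetic_params <- function(K1, k2, k3, vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, vb = vb)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  if (vb > 1) stop("vb must lie in [0, 1]")
  p <- list(K1 = K1, k2 = k2, k3 = k3, vb = vb,
            Ki = if (k2 + k3 > 0) K1 * k3 / (k2 + k3) else NA_real_)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: K1=%.4g k2=%.4g k3=%.4g vb=%.4g (Ki=%.4g)\n",
              x$K1, x$k2, x$k3, x$vb, x$Ki))
  invisible(x)
}

#' Net influx macro parameter Ki
#'
#' Computes \eqn{K_i = K_1 k_3 / (k_2 + k_3)}, the net trapping rate of an
#' irreversible tracer, in mL/min/cm^3. Vectorized over its arguments.
#'
#' @param K1,k2,k3 rate constants (see [kinetic_params()]).
#' @return Ki, mL/min/cm^3.
#' @examples
#' macro_ki(0.10, 0.34, 0.04)   # 0.01053, prints as 0.011
#' @export
macro_ki <- function(K1, k2, k3) {
  if (any(c(K1, k2, k3) < 0, na.rm = TRUE))
    stop("rate constants must be non-negative")
  beta <- k2 + k3
  if (any(beta == 0, na.rm = TRUE))
    stop(.degenerate_condition("macro_ki undefined for k2 + k3 = 0"))
  K1 * k3 / beta
}

# condition object signalling a degenerate kinetic parameter combination
.degenerate_condition <- function(msg, type = "error") {
  structure(class = c("dynpet_degenerate", type, "condition"),
            list(message = msg, call = sys.call(-1)))
}

# exponential-integrator convolution E(t) = int_0^t exp(-beta (t-s)) f(s) ds
# on a uniform grid, exact for piecewise-linear f; beta >= 0.
.exp_conv <- function(f, beta, dt) {
  n <- length(f)
  if (n < 2L) return(rep(0, n))
  if (beta * dt < 1e-8) # series limit: plain cumulative trapezoid
    return(.cumtrapz_uniform(f, dt))
  g <- exp(-beta * dt)
  phi1 <- (1 - g) / beta
  cs <- phi1 - (phi1 - dt * g) / (beta * dt)
  w <- f[-n] * (phi1 - cs) + f[-1L] * cs
  c(0, .rec_filter(w, g))
}

.cumtrapz_uniform <- function(f, dt) {
  n <- length(f)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((f[-n] + f[-1L]) / 2 * dt))
}

#' Tissue concentration under the irreversible two-tissue compartment model
#'
#' Solves the standard irreversible 2TCM
#' \deqn{\dot C_1 = K_1 C_p - (k_2 + k_3) C_1,\qquad \dot C_2 = k_3 C_1}
#' equivalently
#' \deqn{C_T(t) = \frac{K_1}{k_2+k_3}\left(k_3 + k_2
#'   e^{-(k_2+k_3)t}\right) \otimes C_p(t)}
#' and returns the measured voxel signal
#' \eqn{C(t) = (1-v_b) C_T(t) + v_b C_b(t)}. The convolution is evaluated
#' with an exponential-integrator update on the (uniform) time grid, exact
#' for piecewise-linear \eqn{C_p}; the default internal grid step used
#' throughout the package is one second.
#'
#' In the degenerate pure-trapping limit `k2 + k3 = 0` with `K1 > 0` a
#' condition of class `dynpet_degenerate` is signalled as a warning and the
#' limit \eqn{C_T = K_1 \int_0^t C_p} is returned.
#'
#' @param p a [kinetic_params()].
#' @param inp an [input_function()].
#' @param t_grid uniform increasing time grid starting at 0, minutes.
#' @param tissue_only if `TRUE`, return \eqn{C_T} (no blood-volume mixing).
#' @return Concentration on `t_grid`, kBq/mL.
#' @export
tcm2_tissue_concentration <- function(p, inp, t_grid, tissue_only = FALSE) {
  stopifnot(inherits(p, "kinetic_params"), inherits(inp, "input_function"))
  n <- length(t_grid)
  if (n < 2L || t_grid[1L] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be increasing and start at 0")
  dt <- t_grid[2L] - t_grid[1L]
  if (max(abs(diff(t_grid) - dt)) > 1e-9 * dt)
    stop("t_grid must be uniform")
  cp <- inp$cp(t_grid)
  beta <- p$k2 + p$k3
  if (p$K1 == 0) {
    ct <- rep(0, n)
  } else if (beta == 0) {
    warning(.degenerate_condition(
      "k2 + k3 = 0 with K1 > 0: using pure-trapping limit C_T = K1 * int Cp",
      type = "warning"))
    ct <- p$K1 * .cumtrapz_uniform(cp, dt)
  } else {
    icp <- .cumtrapz_uniform(cp, dt)
    ect <- .exp_conv(cp, beta, dt)
    ct <- (p$K1 / beta) * (p$k3 * icp + p$k2 * ect)
  }
  if (tissue_only) return(ct)
  (1 - p$vb) * ct + p$vb * inp$cb(t_grid)
}

#' Time-activity curve of a region or voxel on a frame schedule
#'
#' @param values frame values, kBq/mL, one per frame.
#' @param schedule the [frame_schedule()] the values were measured on.
#' @return Object of class `tissue_tac` with `values`, `mid_min` and
#'   `schedule`.
#' @export
tissue_tac <- function(values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != schedule$n_frames)
    stop("values length (", length(values), ") != n_frames (",
         schedule$n_frames, ")")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(values = as.numeric(values),
                 mid_min = frame_mid_times(schedule),
                 schedule = schedule),
            class = "tissue_tac")
}

#' Average a continuous curve over the frames of a schedule
#'
#' Emulates histogrammed acquisition: each frame value is the time-average
#' of the curve over `[start, start + dur)`. The curve must be sampled on a
#' fine grid (step at most 1 s) covering the whole schedule; integration is
#' by trapezoid with linear interpolation at frame boundaries.
#'
#' @param t_min fine time grid, minutes.
#' @param values curve values on `t_min`.
#' @param schedule a [frame_schedule()].
#' @return A [tissue_tac()].
#' @export
frame_average <- function(t_min, values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(t_min) != length(values)) stop("grid/value length mismatch")
  end_min <- schedule_end_s(schedule) / 60
  if (t_min[1L] > 0 || t_min[length(t_min)] < end_min - 1e-9)
    stop("fine grid must cover the full schedule [0, ", end_min, "] min")
  if (max(diff(t_min)) > 1 / 60 + 1e-9)
    stop("fine grid step must be at most 1 s")
  Fi <- cumsum(c(0, (values[-length(values)] + values[-1L]) / 2 * diff(t_min)))
  Fat <- stats::approxfun(t_min, Fi, rule = 2)
  a <- schedule$start_s / 60
  b <- (schedule$start_s + schedule$dur_s) / 60
  tissue_tac((Fat(b) - Fat(a)) / (b - a), schedule)
}

# dense frame-averaging operator: W %*% curve_on_grid gives frame averages.
# Requires the uniform grid to contain every frame boundary exactly.
.frame_average_matrix <- function(t_min, schedule) {
  n <- length(t_min)
  dt <- t_min[2L] - t_min[1L]
  W <- matrix(0, schedule$n_frames, n)
  for (f in seq_len(schedule$n_frames)) {
    a <- schedule$start_s[f] / 60
    b <- (schedule$start_s[f] + schedule$dur_s[f]) / 60
    i0 <- round((a - t_min[1L]) / dt) + 1L
    i1 <- round((b - t_min[1L]) / dt) + 1L
    if (abs(t_min[i0] - a) > 1e-7 || abs(t_min[i1] - b) > 1e-7)
      stop("grid does not align with frame boundaries")
    w <- rep(dt, i1 - i0 + 1L)
    w[1L] <- dt / 2; w[length(w)] <- dt / 2
    W[f, i0:i1] <- w / (b - a)
  }
  W
}

#' Patlak transform of a time-activity curve
#'
#' Maps a TAC and an input function to Patlak coordinates
#' \deqn{x(t) = \int_0^t C_p \, ds / C_p(t), \qquad y(t) = C(t) / C_p(t)}
#' evaluated at the frame mid-times. The running integral is computed by
#' trapezoid on the input function's own time base (its tabulated grid, or
#' a one-second grid for analytic input). Frames where \eqn{C_p \le 0} are
#' excluded and reported in the `excluded` attribute.
#'
#' For an irreversibly trapped tracer the late-time points fall on a line
#' with slope \eqn{K_i} (of the curve's tissue component) and intercept
#' related to the reversible distribution volume plus blood fraction.
#'
#' @param tac a [tissue_tac()].
#' @param inp an [input_function()].
#' @return data.frame with columns `frame`, `t_min`, `x_min`, `y`; excluded
#'   frame indices in `attr(, "excluded")`.
#' @export
patlak_transform <- function(tac, inp) {
  stopifnot(inherits(tac, "tissue_tac"), inherits(inp, "input_function"))
  mids <- tac$mid_min
  if (!is.null(inp$table)) {
    tb <- inp$table$t_min
    base <- sort(unique(c(0, tb[tb <= max(mids) + 1e-9], mids)))
  } else {
    base <- sort(unique(c(seq(0, max(mids), by = 1 / 60), mids)))
  }
  cp_base <- inp$cp(base)
  icp <- cumsum(c(0, (cp_base[-length(cp_base)] + cp_base[-1L]) / 2 *
                    diff(base)))
  icp_mid <- stats::approx(base, icp, xout = mids)$y
  cp_mid <- inp$cp(mids)
  ok <- cp_mid > 0
  out <- data.frame(frame = which(ok), t_min = mids[ok],
                    x_min = icp_mid[ok] / cp_mid[ok],
                    y = tac$values[ok] / cp_mid[ok])
  attr(out, "excluded") <- which(!ok)
  out
}

#' Weighted least-squares line through Patlak points
#'
#' Closed-form slope/intercept of `y ~ x` restricted to points with
#' `t_min >= t_star`.
#'
#' @param pts data.frame from [patlak_transform()].
#' @param t_star start of the linear (equilibrated) phase, minutes.
#' @param weights optional per-point weights (recycled after restriction).
#' @return list with `Ki_slope`, `v_intercept`, `n_points`.
#' @export
patlak_fit <- function(pts, t_star = 20, weights = NULL) {
  use <- pts$t_min >= t_star
  if (sum(use) < 2L) stop("need at least 2 Patlak points beyond t_star")
  x <- pts$x_min[use]; y <- pts$y[use]
  w <- if (is.null(weights)) rep(1, length(x)) else rep_len(weights, length(x))
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx == 0) stop("degenerate Patlak abscissa (all x equal)")
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  list(Ki_slope = slope, v_intercept = my - slope * mx, n_points = sum(use))
}

#' Standardized uptake value
#'
#' \deqn{SUV = \frac{C \cdot W}{D \cdot 2^{-t/T}}}
#' with concentration \eqn{C} in kBq/mL, injected dose \eqn{D} in MBq,
#' body weight \eqn{W} in kg (1 g/mL tissue density assumed) and the
#' physical decay factor \eqn{2^{-t/T}} with half-life \eqn{T = 110} min
#' (FDG). Decay-correcting the dose to the acquisition time makes SUV of a
#' uniformly distributed tracer equal 1 regardless of `t`.
#'
#' @param activity_conc activity concentration, kBq/mL (already
#'   decay-corrected to `t`, as reconstructed PET images are).
#' @param injected_dose MBq; default 240 (4 MBq/kg at 60 kg).
#' @param weight kg; default 60.
#' @param t minutes between injection and acquisition.
#' @param half_life tracer half-life, minutes.
#' @return SUV, dimensionless; vectorized over `activity_conc`.
#' @export
suv <- function(activity_conc, injected_dose = 240, weight = 60, t = 0,
                half_life = 110) {
  if (injected_dose <= 0) stop("injected dose must be positive")
  if (weight <= 0) stop("weight must be positive")
  if (t < 0) stop("time must be non-negative")
  activity_conc * weight / (injected_dose * 2^(-t / half_life))
}
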
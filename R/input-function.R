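#' Tri-exponential bolus plasma input function
#'
#' Evaluates the classic tri-exponential arterial plasma model
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' clipped at zero. By construction \eqn{C_p(0) = 0} and the curve decays to
#' zero. Default parameters describe a typical FDG bolus: a sharp peak of
#' roughly 100 kBq/mL shortly after injection and a 60-minute tail at about
#' 10--15% of the peak.
#'
#' @param t time(s) post injection, minutes; must be `>= 0`.
#' @param A1 amplitude of the bolus term, kBq/mL/min.
#' @param A2,A3 amplitudes of the two washout exponentials, kBq/mL.
#' @param l1,l2,l3 rate constants, 1/min; must satisfy `l1 > l2 > l3 >= 0`.
#' @return Plasma concentration(s), kBq/mL.
#' @examples
#' feng_input_function(0)         # 0 by construction
#' feng_input_function(c(1, 60))
#' @export
feng_input_function <- function(t, A1 = 851.1, A2 = 21.9, A3 = 20.8,
                                l1 = 4.1339, l2 = 0.1191, l3 = 0.0104) {
  if (any(t < 0)) stop("negative time not allowed in the input function")
  if (!(l1 > l2 && l2 > l3 && l3 >= 0))
    stop("rate constants must satisfy l1 > l2 > l3 >= 0")
  cp <- (A1 * t - A2 - A3) * exp(-l1 * t) +
    A2 * exp(-l2 * t) + A3 * exp(-l3 * t)
  pmax(cp, 0)
}

#' Arterial input function container
#'
#' Wraps plasma (`Cp`) and whole-blood (`Cb`) concentration curves as
#' functions of time in minutes. Accepts either vectorized functions
#' (analytic form) or a data frame with columns `t_min`, `Cp` and optionally
#' `Cb` (tabulated form, interpolated linearly and held at the last value
#' beyond the tabulated range; zero before the first sample). For FDG,
#' whole blood and plasma concentrations are nearly equal, so `Cb` defaults
#' to `Cp`.
#'
#' @param Cp a function of minutes, or a data frame (tabulated form).
#' @param Cb optional whole-blood curve (function); defaults to `Cp`.
#' @return An object of class `input_function` with callable fields
#'   `cp(t)` and `cb(t)` and, for tabulated input, the source `table`.
#' @export
input_function <- function(Cp, Cb = NULL) {
  if (is.data.frame(Cp)) {
    tab <- Cp
    if (!all(c("t_min", "Cp") %in% names(tab)))
      stop("tabulated input function needs columns t_min and Cp")
    if (is.unsorted(tab$t_min, strictly = TRUE))
      stop("t_min must be strictly increasing")
    cp_fun <- .tab_fun(tab$t_min, tab$Cp)
    cb_fun <- if ("Cb" %in% names(tab)) .tab_fun(tab$t_min, tab$Cb) else cp_fun
    out <- list(cp = cp_fun, cb = cb_fun, table = tab, form = "tabulated")
  } else if (is.function(Cp)) {
    cb_fun <- if (is.null(Cb)) Cp else Cb
    if (!is.function(cb_fun)) stop("Cb must be a function when Cp is")
    out <- list(cp = Cp, cb = cb_fun, table = NULL, form = "analytic")
  } else {
    stop("Cp must be a function or a data frame")
  }
  structure(out, class = "input_function")
}

# linear interpolation, 0 before first sample, flat after last
.tab_fun <- function(t, v) {
  force(t); force(v)
  function(tt) {
    out <- stats::approx(t, v, xout = tt, rule = 2)$y
    out[tt < t[1L]] <- if (t[1L] <= 0) v[1L] else 0
    out
  }
}

#' Default analytic input function
#'
#' The package default: a tri-exponential bolus ([feng_input_function()])
#' with whole blood equal to plasma (FDG assumption).
#'
#' @param ... overrides passed to [feng_input_function()].
#' @return An [input_function()].
#' @export
default_input_function <- function(...) {
  input_function(function(t) feng_input_function(t, ...))
}

#' @export
print.input_function <- function(x, ...) {
  cat("input_function (", x$form, " form)\n", sep = "")
  if (!is.null(x$table))
    cat("  ", nrow(x$table), "samples over",
        format(range(x$table$t_min), digits = 4), "min\n")
  invisible(x)
}

#' Read / write a tabulated input function as CSV
#'
#' Columns: `t_min`, `Cp`, and optionally `Cb` (all kBq/mL, minutes).
#'
#' @param inp an [input_function()]; analytic forms are tabulated on
#'   `t_grid` before writing.
#' @param path file path.
#' @param t_grid minutes; grid used to tabulate analytic input functions.
#' @return `read_input_function` returns a tabulated [input_function()].
#' @export
write_input_function <- function(inp, path, t_grid = seq(0, 60, by = 1 / 60)) {
  stopifnot(inherits(inp, "input_function"))
  tab <- inp$table
  if (is.null(tab))
    tab <- data.frame(t_min = t_grid, Cp = inp$cp(t_grid), Cb = inp$cb(t_grid))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_input_function
#' @export
read_input_function <- function(path) {
  input_function(utils::read.csv(path))
}
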
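#' Continuous periodic waveform
#'
#' A `circ_waveform` wraps an evaluator f(t) defined for all real t with
#' f(t) = f(t + T), together with its derivative f'(t) and the period T.
#' Downstream operations (R(t), costs, phase analysis) consume this contract
#' rather than raw samples, so derivatives are analytic properties of the
#' fitted curve, never finite differences of noisy data.
#'
#' @param fun vectorized evaluator of f(t).
#' @param deriv vectorized evaluator of f'(t).
#' @param period period T in hours.
#' @param method character tag describing how the waveform was built.
#' @param label free-text label.
#' @return an object of class `circ_waveform`.
#' @export
circ_waveform <- function(fun, deriv, period, method = "custom", label = "") {
  stopifnot(is.function(fun), is.function(deriv),
            is.numeric(period), period > 0)
  structure(
    list(fun = fun, deriv = deriv, period = period,
         method = method, label = as.character(label)[1L]),
    class = "circ_waveform"
  )
}

#' @export
print.circ_waveform <- function(x, ...) {
  cat(sprintf("<circ_waveform> %s (T = %g h, %s fit)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$period, x$method))
  invisible(x)
}

is_circ_waveform <- function(x) inherits(x, "circ_waveform")

assert_waveform <- function(w) {
  if (!is_circ_waveform(w)) {
    stop("expected a 'circ_waveform' object", call. = FALSE)
  }
  invisible(w)
}

#' Fit a continuous periodic waveform through sampled data
#'
#' Builds a periodic interpolant through the samples of a series: a periodic
#' cubic spline (the default, with smooth analytic derivatives) or a periodic
#' piecewise-linear interpolant (preferred for coarse, e.g. 4-h, sampling
#' where spline overshoot between samples is not trustworthy).  Periodicity
#' is enforced by wrapping the first sample at t + T.
#'
#' @param series a [circ_series()].
#' @param method `"spline"` (periodic cubic interpolation) or `"linear"`.
#' @return a [circ_waveform()] interpolating the samples.
#' @examples
#' s <- circ_series(seq(2, 24, 2), 2 + sin(seq(2, 24, 2) * pi / 12), 24)
#' w <- fit_periodic_waveform(s)
#' w$fun(c(1, 25))   # periodic extension
#' @export
fit_periodic_waveform <- function(series, method = c("spline", "linear")) {
  assert_series(series)
  method <- match.arg(method)
  T <- series$period
  t <- series$times
  v <- series$values
  # wrap the first sample at t + T so the interpolant closes the period
  tw <- c(t, t[1L] + T)
  vw <- c(v, v[1L])
  if (method == "spline") {
    sf <- stats::splinefun(tw, vw, method = "periodic")
    fun <- function(x) sf(x)
    der <- function(x) sf(x, deriv = 1)
  } else {
    af <- stats::approxfun(tw, vw, method = "linear", rule = 2)
    t0 <- t[1L]
    wrapin <- function(x) ((x - t0) %% T) + t0
    fun <- function(x) af(wrapin(x))
    # one-sided slope; at the sample knots the right-hand slope is reported
    der <- function(x) {
      xs <- wrapin(x)
      idx <- findInterval(xs, tw, rightmost.closed = TRUE)
      idx[idx < 1L] <- 1L
      idx[idx >= length(tw)] <- length(tw) - 1L
      (vw[idx + 1L] - vw[idx]) / (tw[idx + 1L] - tw[idx])
    }
  }
  circ_waveform(fun, der, T, method = method, label = series$label)
}

#' Time average of a periodic waveform
#'
#' Computes (1/T) * integral of w over one period by trapezoidal quadrature
#' on a dense uniform grid.
#'
#' @param w a [circ_waveform()] (or a plain function, with `period` given).
#' @param grid_h quadrature grid spacing in hours (default 0.01 h).
#' @param period required when `w` is a plain function.
#' @return the scalar time average.
#' @examples
#' w <- sinusoid_waveform(L = 3, h0 = 2, period = 24)
#' time_average(w)  # L/omega + h0
#' @export
time_average <- function(w, grid_h = .circwave_defaults$grid_quad_h,
                         period = NULL) {
  if (is_circ_waveform(w)) {
    f <- w$fun
    T <- w$period
  } else if (is.function(w)) {
    if (is.null(period)) stop("period must be given for a plain function")
    f <- w
    T <- period
  } else {
    stop("w must be a circ_waveform or a function", call. = FALSE)
  }
  grid <- seq(0, T, by = grid_h)
  if (grid[length(grid)] < T) grid <- c(grid, T)
  pracma::trapz(grid, f(grid)) / T
}

#' Sinusoidal reference waveform
#'
#' The analytic benchmark waveform x(t) = -(L/omega) cos(omega t) + L/omega
#' + h0, with omega = 2 pi / T: its derivative is the pure sinusoid
#' x'(t) = L sin(omega t), it is strictly positive for h0 > 0, peaks at
#' t = T/2 and troughs at t = T.  Used throughout the feedback-phase module,
#' where the closed-form phase solutions are derived for this shape.
#'
#' @param L derivative amplitude in 1/h (L > 0).
#' @param h0 trough level (dimensionless, >= 0).
#' @param period period T in hours.
#' @return a [circ_waveform()] carrying `L`, `h0` and `C = h0*omega + L` as
#'   attributes (class `sinusoid_waveform` in addition to `circ_waveform`).
#' @export
sinusoid_waveform <- function(L, h0, period = 24) {
  stopifnot(L > 0, h0 >= 0, period > 0)
  omega <- 2 * pi / period
  w <- circ_waveform(
    fun = function(t) -(L / omega) * cos(omega * t) + L / omega + h0,
    deriv = function(t) L * sin(omega * t),
    period = period, method = "analytic",
    label = sprintf("sinusoid(L=%g, h0=%g)", L, h0)
  )
  w$L <- L
  w$h0 <- h0
  w$omega <- omega
  w$C <- h0 * omega + L
  class(w) <- c("sinusoid_waveform", class(w))
  w
}

#' Locate the maximum of a periodic function on (0, T]
#'
#' Coarse grid scan followed by local refinement with [stats::optimize()];
#' ties on the grid are broken by the earliest time in (0, T].
#'
#' @param f vectorized function of time.
#' @param period period T in hours.
#' @param grid_h scan resolution in hours.
#' @return list with `t` (argmax in (0, T]) and `value`.
#' @keywords internal
periodic_argmax <- function(f, period, grid_h = .circwave_defaults$grid_extremum_h) {
  grid <- seq(grid_h, period, by = grid_h)
  vals <- f(grid)
  i <- which.max(vals)   # which.max returns the first (earliest) maximum
  lo <- grid[i] - grid_h
  hi <- grid[i] + grid_h
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  if (opt$objective >= vals[i]) {
    list(t = fold_time(opt$maximum, period), value = opt$objective)
  } else {
    list(t = grid[i], value = vals[i])
  }
}

periodic_argmin <- function(f, period, grid_h = .circwave_defaults$grid_extremum_h) {
  res <- periodic_argmax(function(t) -f(t), period, grid_h)
  list(t = res$t, value = -res$value)
}
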
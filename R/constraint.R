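#' Waveform-imposed lower bound on the degradation rate
#'
#' For a periodic abundance waveform x(t) obeying dx/dt = g(t) - r(t) x(t)
#' with nonnegative synthesis g(t) and degradation r(t), the degradation rate
#' is bounded below by
#' \deqn{R(t) = \max\{-x'(t)/x(t),\, 0\}}
#' regardless of the synthesis profile.  The maximum of R over the period,
#' r_min, is the smallest *constant* degradation rate compatible with the
#' waveform, attained at a single "hotspot" t_R located between the steepest
#' decline (t_a) and the trough (t_b) of x.
#'
#' @param x a [circ_waveform()] for the protein abundance; must stay above a
#'   small floor (`eps_x_rel` times its peak) everywhere.
#' @param smooth_window_h optional moving-window width (hours) applied to
#'   R(t) on the grid before locating r_min; used for noisy profiles
#'   (1-h window for PER2-style data).  Default `NULL` (no smoothing).
#' @param grid_h grid spacing for the reported R(t) curve.
#' @param eps_x_rel relative floor below which x is considered degenerate.
#' @return a `constraint_profile`: list with `times`, `R`, `r_min`, `t_R`
#'   (hotspot), `t_a` (steepest decline), `t_b` (trough), `period`,
#'   `smooth_window_h`.
#' @examples
#' w <- sinusoid_waveform(L = 3, h0 = 2, period = 24)
#' p <- lower_bound_profile(w)
#' p$r_min
#' @export
lower_bound_profile <- function(x, smooth_window_h = NULL,
                                grid_h = .circwave_defaults$grid_extremum_h,
                                eps_x_rel = .circwave_defaults$eps_x_rel) {
  assert_waveform(x)
  T <- x$period
  grid <- seq(grid_h, T, by = grid_h)
  xv <- x$fun(grid)
  peak <- max(xv)
  eps_x <- eps_x_rel * peak
  if (any(xv <= eps_x)) {
    bad <- grid[which(xv <= eps_x)[1L]]
    stop(sprintf(
      "waveform is degenerate: x(t) <= %.3g at t = %.2f h; R(t) unbounded",
      eps_x, bad), call. = FALSE)
  }
  Rfun_raw <- function(t) pmax(-x$deriv(t) / x$fun(t), 0)
  Rv <- Rfun_raw(grid)
  if (!is.null(smooth_window_h)) {
    Rv <- smooth_on_grid(grid, Rv, T, smooth_window_h)
    Rg <- stats::approxfun(c(grid[1L] - grid_h, grid),
                           c(Rv[length(Rv)], Rv), rule = 2)
    Rfun <- function(t) Rg(fold_time(t, T))
  } else {
    Rfun <- Rfun_raw
  }
  # hotspot: refine off-grid only for the unsmoothed profile
  if (is.null(smooth_window_h)) {
    hot <- periodic_argmax(Rfun, T, grid_h)
  } else {
    i <- which.max(Rv)
    hot <- list(t = grid[i], value = Rv[i])
  }
  ta <- periodic_argmax(function(t) -x$deriv(t), T, grid_h)$t
  tb <- periodic_argmin(x$fun, T, grid_h)$t
  structure(
    list(times = grid, R = Rv, r_min = hot$value, t_R = hot$t,
         t_a = ta, t_b = tb, period = T,
         smooth_window_h = smooth_window_h, R_fun = Rfun,
         waveform = x),
    class = "constraint_profile"
  )
}

# centered periodic moving average of values sampled on a uniform grid
smooth_on_grid <- function(grid, values, period, window_h) {
  dt <- grid[2L] - grid[1L]
  halfn <- floor(window_h / 2 / dt)
  if (halfn < 1L) return(values)
  n <- length(values)
  idx <- -halfn:halfn
  vapply(seq_len(n), function(i) {
    mean(values[((i - 1L + idx) %% n) + 1L])
  }, numeric(1))
}

#' @export
print.constraint_profile <- function(x, ...) {
  cat(sprintf(
    "<constraint_profile> r_min = %.4g 1/h at hotspot t_R = %.2f h (T = %g h)\n",
    x$r_min, x$t_R, x$period))
  cat(sprintf("  steepest decline t_a = %.2f h, trough t_b = %.2f h%s\n",
              x$t_a, x$t_b,
              if (is.null(x$smooth_window_h)) "" else
                sprintf(", R smoothed with %g-h window", x$smooth_window_h)))
  invisible(x)
}

#' Consequences of a constant degradation rate
#'
#' If the degradation rate were constant it could not be smaller than r_min,
#' so the half-life at *any* time of day could not exceed ln(2)/r_min, and
#' over one period at least r_min * T times the mean abundance would have to
#' be synthesized (the fold excess, from c*T >= r_min * T * <x>).
#'
#' @param r_min minimal constant degradation rate in 1/h.
#' @param period period T in hours.
#' @return list with `half_life_bound_min` (minutes; `Inf` when r_min = 0)
#'   and `fold_excess` (dimensionless).
#' @examples
#' constant_rate_implications(0.88, 24)   # ~47 min, ~21-fold
#' @export
constant_rate_implications <- function(r_min, period) {
  stopifnot(r_min >= 0, period > 0)
  if (r_min == 0) {
    return(list(half_life_bound_min = Inf, fold_excess = 0))
  }
  list(half_life_bound_min = 60 * log(2) / r_min,
       fold_excess = r_min * period)
}

#' Biosynthetic cost of maintaining a waveform
#'
#' The cost c of a periodic protein profile is the average amount synthesized
#' (equivalently degraded) per unit time, c = <r(t) x(t)>.  Under a constant
#' degradation rate the cost cannot fall below c_g = r_min <x>; the fraction
#' (c_g - c)/c_g is the saving achieved by a rhythmic degradation rate.
#'
#' @param x abundance [circ_waveform()].
#' @param r degradation-rate [circ_waveform()] (1/h), nonnegative, same
#'   period as `x`.
#' @param profile optional precomputed [lower_bound_profile()] of `x` (e.g.
#'   a trough-smoothed or R-smoothed variant); computed if missing.
#' @return a `cost_summary`: list with `c`, `c_g`, `cost_reduction`,
#'   `mean_x`, `r_min`, `fold_excess`, `half_life_bound_min`, `period`.
#' @examples
#' x <- sinusoid_waveform(3, 2, 24)
#' r <- lower_bound_profile(x)$r_min
#' rconst <- circ_waveform(function(t) rep(r, length(t)),
#'                         function(t) rep(0, length(t)), 24)
#' production_cost(x, rconst)$cost_reduction   # 0 at the constant-rate floor
#' @export
production_cost <- function(x, r, profile = NULL) {
  assert_waveform(x)
  assert_waveform(r)
  if (abs(x$period - r$period) > 1e-9) {
    stop("x and r must share the same period", call. = FALSE)
  }
  grid <- seq(0, x$period, by = .circwave_defaults$grid_quad_h)
  rv <- r$fun(grid)
  if (any(rv < -1e-9)) {
    stop("degradation rate is negative on the grid", call. = FALSE)
  }
  if (is.null(profile)) profile <- lower_bound_profile(x)
  mean_x <- time_average(x)
  cost <- pracma::trapz(grid, pmax(rv, 0) * x$fun(grid)) / x$period
  c_g <- profile$r_min * mean_x
  impl <- constant_rate_implications(profile$r_min, x$period)
  structure(
    list(c = cost, c_g = c_g,
         cost_reduction = (c_g - cost) / c_g,
         mean_x = mean_x, r_min = profile$r_min,
         fold_excess = impl$fold_excess,
         half_life_bound_min = impl$half_life_bound_min,
         period = x$period),
    class = "cost_summary"
  )
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("<cost_summary> c = %.4g, c_g = %.4g (per h)\n", x$c, x$c_g))
  cat(sprintf("  cost reduction (c_g - c)/c_g = %.1f%%\n",
              100 * x$cost_reduction))
  cat(sprintf("  r_min = %.4g 1/h -> half-life <= %.3g min, fold excess %.3g\n",
              x$r_min, x$half_life_bound_min, x$fold_excess))
  invisible(x)
}

#' Check measured degradation rates against the waveform bound
#'
#' Every experimentally measured degradation rate must satisfy
#' r(t_i) >= R(t_i); a measured rate below the bound (beyond tolerance)
#' contradicts the waveform and is flagged, not raised.
#'
#' @param profile a [lower_bound_profile()] result.
#' @param anchors a data frame with columns `t` (hours) and `r` (1/h), or a
#'   list of `(t, r)` pairs.
#' @param tol violation tolerance in 1/h.
#' @return data frame with columns `t`, `r`, `R`, `margin` (= r - R) and
#'   `pass`; attribute `all_pass` gives the aggregate verdict.
#' @export
validate_anchors <- function(profile, anchors, tol = 1e-9) {
  stopifnot(inherits(profile, "constraint_profile"))
  anchors <- as_anchor_frame(anchors)
  t <- fold_time(anchors$t, profile$period)
  Rv <- profile$R_fun(t)
  margin <- anchors$r - Rv
  pass <- margin >= -tol
  out <- data.frame(t = t, r = anchors$r, R = Rv,
                    margin = margin, pass = pass)
  attr(out, "all_pass") <- all(pass)
  out
}

as_anchor_frame <- function(anchors) {
  if (is.data.frame(anchors)) {
    nm <- names(anchors)
    tcol <- intersect(c("t", "time_h", "times"), nm)[1L]
    rcol <- intersect(c("r", "rate_per_h", "rate"), nm)[1L]
    if (is.na(tcol) || is.na(rcol)) {
      stop("anchor frame needs time and rate columns", call. = FALSE)
    }
    out <- data.frame(t = anchors[[tcol]], r = anchors[[rcol]])
    out$sd <- if ("sd_per_h" %in% nm) anchors$sd_per_h else
      if ("sd" %in% nm) anchors$sd else NA_real_
    out
  } else if (is.list(anchors)) {
    do.call(rbind, lapply(anchors, function(a) {
      data.frame(t = a[[1L]], r = a[[2L]],
                 sd = if (length(a) >= 3L) a[[3L]] else NA_real_)
    }))
  } else {
    stop("anchors must be a data frame or list of (t, r) pairs",
         call. = FALSE)
  }
}

#' Conservative r_min for coarsely sampled data
#'
#' When the abundance profile is sampled too coarsely (e.g. 4-h intervals for
#' the *Ostreococcus* clock proteins) the shape of R(t) between samples is
#' not trustworthy.  With a full measured degradation-rate time series
#' available, a conservative estimate is
#' r_min = min\{ max_t r(t), max_t R(t) \}, with R computed from a *linear*
#' (not spline) fit of the abundance profile.
#'
#' @param x_series abundance [circ_series()] (need not be normalized).
#' @param r_series measured degradation-rate [circ_series()] (1/h), sharing
#'   the same period.
#' @return the estimated r_min in 1/h.
#' @export
algal_r_min <- function(x_series, r_series) {
  assert_series(x_series)
  assert_series(r_series)
  if (abs(x_series$period - r_series$period) > 1e-9) {
    stop("abundance and rate series must share the same period",
         call. = FALSE)
  }
  xw <- fit_periodic_waveform(x_series, method = "linear")
  maxR <- lower_bound_profile(xw)$r_min
  rw <- fit_periodic_waveform(r_series, method = "linear")
  maxr <- periodic_argmax(rw$fun, rw$period)$value
  min(maxr, maxR)
}
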
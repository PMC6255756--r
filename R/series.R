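#' Periodic sampled time course
#'
#' Container for a strictly periodic, discretely sampled abundance time
#' course: times within (0, T], nonnegative finite values, a period `T` in
#' hours, and free-text annotation.  All downstream waveform math consumes
#' this class.  A time of 0 (or any multiple of T) is folded to T, matching
#' the convention that t = 0 aliases t = T.
#'
#' @param times sampling times in hours; folded into (0, T].
#' @param values nonnegative abundances (dimensionless after peak
#'   normalization, or e.g. molecules per cell for unnormalized data).
#' @param period period T in hours.
#' @param label free-text label.
#' @param light_regime optional annotation such as "12L:12D"; never used in
#'   computation.
#' @return an object of class `circ_series` with fields `times`, `values`,
#'   `period`, `label`, `light_regime`.
#' @examples
#' s <- circ_series(seq(2, 24, by = 2), 5 + sin(seq(2, 24, by = 2) * pi / 12), 24)
#' s
#' @export
circ_series <- function(times, values, period, label = "",
                        light_regime = NULL) {
  if (!is.numeric(times) || !is.numeric(values) || !is.numeric(period)) {
    stop("times, values and period must be numeric", call. = FALSE)
  }
  if (length(period) != 1L || !is.finite(period) || period <= 0) {
    stop("period must be a single positive number", call. = FALSE)
  }
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("a periodic series needs at least 3 samples", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("abundance values must be nonnegative", call. = FALSE)
  }
  times <- fold_time(times, period)
  ord <- order(times)
  times <- times[ord]
  values <- values[ord]
  if (anyDuplicated(times)) {
    stop("duplicate sample times after folding into (0, T]", call. = FALSE)
  }
  structure(
    list(times = times, values = values, period = period,
         label = as.character(label)[1L], light_regime = light_regime),
    class = "circ_series"
  )
}

#' @export
print.circ_series <- function(x, ...) {
  cat(sprintf("<circ_series> %s: %d samples over (0, %g] h",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), x$period))
  if (!is.null(x$light_regime)) cat(sprintf(" [%s]", x$light_regime))
  cat(sprintf("\n  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.circ_series <- function(x) length(x$times)

is_circ_series <- function(x) inherits(x, "circ_series")

assert_series <- function(series) {
  if (!is_circ_series(series)) {
    stop("expected a 'circ_series' object", call. = FALSE)
  }
  invisible(series)
}

#' Moving-window average of a periodic series
#'
#' Replaces each sample by the mean of all samples whose times fall within
#' a centered window of width `window_h`, wrapping around the period.  Used
#' to smooth noisy high-resolution profiles (3-h window for PER2-style
#' luminescence traces) and noisy R(t) curves (1-h window).
#'
#' @param series a [circ_series()].
#' @param window_h full window width in hours; must be positive and smaller
#'   than the period.
#' @return a `circ_series` with the same times and smoothed values.  If the
#'   window is smaller than the sampling interval the input is returned
#'   unchanged with a warning.
#' @examples
#' s <- circ_series(1:24, rep(c(1, 0), 12), 24)
#' moving_window_average(s, 3)
#' @export
moving_window_average <- function(series, window_h) {
  assert_series(series)
  stopifnot(is.numeric(window_h), length(window_h) == 1L)
  if (window_h <= 0 || window_h >= series$period) {
    stop("window_h must lie in (0, period)", call. = FALSE)
  }
  dt <- min(diff(sort(series$times)))
  if (window_h < dt) {
    warning("window smaller than the sampling interval; series unchanged")
    return(series)
  }
  t <- series$times
  v <- series$values
  T <- series$period
  half <- window_h / 2
  out <- vapply(t, function(tc) {
    # periodic distance from the window center
    d <- abs(((t - tc + T / 2) %% T) - T / 2)
    mean(v[d <= half + 1e-12])
  }, numeric(1))
  circ_series(t, out, T, label = series$label,
              light_regime = series$light_regime)
}

#' Replace trough samples by a nearby reference sample
#'
#' Measurement error dominates when abundances near the trough approach the
#' detection limit; underestimated trough values inflate R(t) and hence
#' r_min.  This conservative correction replaces the values at the given
#' target times by the value at a (presumably more reliable) source time,
#' e.g. replacing x(0), x(22) and x(24) by x(2) for a T = 24 h profile.
#'
#' @param series a [circ_series()].
#' @param target_times sample times whose values are replaced; 0 and T refer
#'   to the same periodic point.  May be empty (identity).
#' @param source_time a sample time supplying the replacement value.
#' @return the corrected `circ_series`.
#' @export
smooth_trough_points <- function(series, target_times, source_time) {
  assert_series(series)
  if (length(target_times) == 0L) return(series)
  T <- series$period
  src <- fold_time(source_time, T)
  i_src <- match_time(src, series$times)
  if (is.na(i_src)) {
    stop(sprintf("source time %g h is not a sample time", source_time),
         call. = FALSE)
  }
  tgt <- unique(fold_time(target_times, T))
  v <- series$values
  for (tt in tgt) {
    i <- match_time(tt, series$times)
    if (is.na(i)) {
      stop(sprintf("target time %g h is not a sample time", tt),
           call. = FALSE)
    }
    v[i] <- series$values[i_src]
  }
  circ_series(series$times, v, T, label = series$label,
              light_regime = series$light_regime)
}

match_time <- function(t, times, tol = 1e-8) {
  i <- which(abs(times - t) <= tol)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Normalize a series by the peak of its fitted spline
#'
#' Published circadian profiles are typically reported relative to their peak
#' level; the peak is taken from the periodic spline through the samples
#' (evaluated on a dense grid), not from the raw maximum, so that samples
#' straddling the true peak still normalize consistently.
#'
#' @param series a [circ_series()].
#' @param grid_h grid spacing (hours) for locating the spline peak.
#' @return the series divided by its spline peak; the refit spline of the
#'   result has maximum 1 to within grid tolerance.
#' @export
normalize_to_spline_peak <- function(series, grid_h = .circwave_defaults$grid_extremum_h) {
  assert_series(series)
  w <- fit_periodic_waveform(series, method = "spline")
  grid <- seq(grid_h, series$period, by = grid_h)
  peak <- max(w$fun(grid))
  if (peak <= 0) {
    stop("spline peak is not positive; cannot normalize an all-zero series",
         call. = FALSE)
  }
  circ_series(series$times, series$values / peak, series$period,
              label = series$label, light_regime = series$light_regime)
}
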
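#' Exponential half-life fit to a chase decay series
#'
#' After translation is blocked (cycloheximide chase) the remaining protein
#' decays; a log-linear least-squares fit of abundance against time from a
#' stated start time (allowing for the lag before the block takes full
#' effect) yields the instantaneous degradation rate r = -slope.  When
#' replicate series are supplied, each replicate is fitted separately and the
#' standard deviation of the per-replicate slopes is reported.
#'
#' @param decay a data frame with columns `time_h` and `value` (one series),
#'   optionally a `replicate` column; or a [circ_series()]-like list with
#'   `times`/`values`.
#' @param fit_from_h only points with `time_h >= fit_from_h` enter the fit.
#' @return list with `r` (1/h), `sd` (1/h; `NA` without replicates, 0 for a
#'   single exact series), `n_points`, `fit_from_h`.
#' @examples
#' d <- data.frame(time_h = 0:7, value = exp(-0.45 * (0:7)))
#' fit_decay_rate(d, fit_from_h = 1)$r
#' @export
fit_decay_rate <- function(decay, fit_from_h = 0) {
  if (is_circ_series(decay) || (is.list(decay) && !is.data.frame(decay) &&
                                all(c("times", "values") %in% names(decay)))) {
    decay <- data.frame(time_h = decay$times, value = decay$values)
  }
  stopifnot(is.data.frame(decay),
            all(c("time_h", "value") %in% names(decay)))
  keep <- decay$time_h >= fit_from_h - 1e-12
  d <- decay[keep, , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("need at least 2 points at or after fit_from_h", call. = FALSE)
  }
  if (any(d$value <= 0)) {
    stop("decay values must be positive for a log-linear fit", call. = FALSE)
  }
  slope_of <- function(dd) {
    unname(coef(stats::lm(log(value) ~ time_h, data = dd))[2L])
  }
  if ("replicate" %in% names(d) && length(unique(d$replicate)) > 1L) {
    slopes <- vapply(split(d, d$replicate), function(dd) {
      if (nrow(dd) < 2L) {
        stop("each replicate needs at least 2 points in the fit window",
             call. = FALSE)
      }
      slope_of(dd)
    }, numeric(1))
    r <- -mean(slopes)
    s <- stats::sd(-slopes)
  } else {
    r <- -slope_of(d)
    s <- if (nrow(d) > 2L) {
      fit <- stats::lm(log(value) ~ time_h, data = d)
      res <- sum(stats::residuals(fit)^2)
      if (res < 1e-20) 0 else NA_real_
    } else NA_real_
  }
  list(r = r, sd = s, n_points = nrow(d), fit_from_h = fit_from_h)
}

#' Estimate the mRNA-to-protein translation rate constant
#'
#' Under dx/dt = k g_m(t) - r(t) x(t) with approximately constant translation
#' rate k, each time point with a measured degradation rate gives
#' \deqn{k_i = [x'(t_i) + r(t_i) x(t_i)] / g_m(t_i),}
#' and k is taken as the unweighted arithmetic mean of the per-anchor values.
#'
#' @param x protein [circ_waveform()].
#' @param g_m mRNA [circ_waveform()], positive at all anchor times.
#' @param anchors anchor measurements: data frame with `t`, `r` (and
#'   optionally `sd`) columns, or list of `(t, r)` pairs.
#' @return a `translation_model` of mode `"constant"`: list with `mode`,
#'   `k`, and the per-anchor `k_i` values.
#' @export
estimate_translation_constant <- function(x, g_m, anchors) {
  assert_waveform(x)
  assert_waveform(g_m)
  a <- as_anchor_frame(anchors)
  if (nrow(a) < 1L) stop("need at least one anchor", call. = FALSE)
  t <- fold_time(a$t, x$period)
  gm <- g_m$fun(t)
  if (any(gm <= 0)) {
    stop(sprintf("g_m(t) is not positive at anchor t = %.2f h",
                 t[which(gm <= 0)[1L]]), call. = FALSE)
  }
  k_i <- (x$deriv(t) + a$r * x$fun(t)) / gm
  structure(list(mode = "constant", k = mean(k_i),
                 k_i = stats::setNames(k_i, paste0("t", t))),
            class = "translation_model")
}

#' @export
print.translation_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<translation_model> constant k = %.4g 1/h (%d anchors)\n",
                x$k, length(x$k_i)))
  } else {
    cat(sprintf(
      "<translation_model> sinusoidal k(t) = max{a sin(2 pi t/T - phi) + b, eps_k}\n  a = %.4g, b = %.4g, phi = %.4g rad, eps_k = %.4g\n",
      x$a, x$b, x$phi, x$eps_k))
  }
  invisible(x)
}

#' Evaluate a translation model k(t)
#'
#' @param tm a `translation_model`.
#' @param t times in hours.
#' @param period period T in hours (needed in sinusoidal mode).
#' @return k(t) in 1/h.
#' @export
translation_rate <- function(tm, t, period = 24) {
  stopifnot(inherits(tm, "translation_model"))
  if (tm$mode == "constant") {
    rep(tm$k, length(t))
  } else {
    pmax(tm$a * sin(2 * pi * t / period - tm$phi) + tm$b, tm$eps_k)
  }
}

#' Sinusoidal translation-rate model fitted to anchors
#'
#' An alternative to the constant-k approximation: k(t) is modelled as
#' max\{a sin(2 pi t/T - phi) + b, eps_k\}, with a, b and phi fitted to the
#' per-anchor values k_i = [x'(t_i) + r(t_i) x(t_i)]/g_m(t_i) by least
#' squares, and the positivity floor eps_k set to the minimum of those
#' per-anchor values.  With 3 or more anchors all three parameters are
#' identified (linear in a cos(phi), a sin(phi), b); with fewer the model is
#' underdetermined and a and b are solved separately for each phase on the
#' supplied `phi_grid`, returning the whole family.
#'
#' @inheritParams estimate_translation_constant
#' @param phi_grid phases (radians) to condition on when underdetermined;
#'   default `seq(0, pi/2, length.out = 25)`.
#' @return a `translation_model` of mode `"sinusoidal"` (fields `a`, `b`,
#'   `phi`, `eps_k`, `k_i`); in the underdetermined case a list of such
#'   models (class `translation_family`), one per phase.
#' @export
fit_sinusoidal_translation <- function(x, g_m, anchors, phi_grid = NULL) {
  assert_waveform(x)
  assert_waveform(g_m)
  a_fr <- as_anchor_frame(anchors)
  if (nrow(a_fr) < 1L) stop("need at least one anchor", call. = FALSE)
  T <- x$period
  t <- fold_time(a_fr$t, T)
  gm <- g_m$fun(t)
  if (any(gm <= 0)) stop("g_m must be positive at anchor times", call. = FALSE)
  k_i <- (x$deriv(t) + a_fr$r * x$fun(t)) / gm
  eps_k <- min(k_i)
  th <- 2 * pi * t / T
  make_model <- function(a, b, phi) {
    structure(list(mode = "sinusoidal", a = a, b = b, phi = phi,
                   eps_k = eps_k, period = T,
                   k_i = stats::setNames(k_i, paste0("t", t))),
              class = "translation_model")
  }
  if (nrow(a_fr) >= 3L) {
    # a sin(th - phi) + b = p cos(th) + q sin(th) + b, linear least squares
    fit <- stats::lm(k_i ~ cos(th) + sin(th))
    cf <- coef(fit)
    p <- unname(cf[2L]); q <- unname(cf[3L]); b <- unname(cf[1L])
    a <- sqrt(p^2 + q^2)
    # p = -a sin(phi), q = a cos(phi)
    phi <- atan2(-p, q)
    make_model(a, b, phi)
  } else {
    if (is.null(phi_grid)) phi_grid <- seq(0, pi / 2, length.out = 25L)
    fam <- lapply(phi_grid, function(phi) {
      s <- sin(th - phi)
      X <- cbind(s, 1)
      cf <- qr.solve(crossprod(X), crossprod(X, k_i))
      make_model(cf[1L], cf[2L], phi)
    })
    structure(fam, class = "translation_family", phi_grid = phi_grid)
  }
}

#' Reconstruct the time-varying degradation rate
#'
#' Inverts the synthesis/turnover balance on a regular grid:
#' \deqn{r(t) = [k(t) g_m(t) - x'(t)] / x(t),}
#' with measured anchor rates overriding the formula at their (nearest) grid
#' times.  The grid spacing defaults to the 2-h sampling of the source data.
#' Each grid point carries a provenance flag.
#'
#' @param x protein [circ_waveform()].
#' @param g_m mRNA [circ_waveform()].
#' @param tm a `translation_model` from [estimate_translation_constant()] or
#'   [fit_sinusoidal_translation()].
#' @param anchors anchor measurements (data frame or list); may be `NULL`.
#' @param grid_h reconstruction grid spacing in hours (default 2).
#' @param eps_x_rel relative floor for x on the grid.
#' @return an `inferred_rate_curve`: list with `times`, `r`, `provenance`
#'   (character: `anchor`, `inferred`, `capped_high`, `floored_low`,
#'   `corrected_window`), `period`, `anchors`, `config`.
#' @export
infer_rate_curve <- function(x, g_m, tm, anchors = NULL, grid_h = 2,
                             eps_x_rel = .circwave_defaults$eps_x_rel) {
  assert_waveform(x)
  assert_waveform(g_m)
  stopifnot(inherits(tm, "translation_model"))
  T <- x$period
  grid <- seq(grid_h, T, by = grid_h)
  xv <- x$fun(grid)
  if (any(xv <= eps_x_rel * max(xv))) {
    stop("x(t) vanishes on the reconstruction grid", call. = FALSE)
  }
  kv <- translation_rate(tm, grid, period = T)
  r <- (kv * g_m$fun(grid) - x$deriv(grid)) / xv
  prov <- rep("inferred", length(grid))
  a <- if (is.null(anchors)) NULL else as_anchor_frame(anchors)
  if (!is.null(a) && nrow(a) > 0L) {
    at <- fold_time(a$t, T)
    for (j in seq_along(at)) {
      i <- which.min(abs(circ_dist(grid, at[j], T)))
      r[i] <- a$r[j]
      prov[i] <- "anchor"
    }
  }
  new_rate_curve(grid, r, prov, T, anchors = a,
                 config = list(grid_h = grid_h, k_mode = tm$mode))
}

# periodic piecewise-linear interpolation through >= 2 knots
periodic_linear_interp <- function(times, values, period) {
  tw <- c(times, times[1L] + period)
  vw <- c(values, values[1L])
  af <- stats::approxfun(tw, vw, method = "linear", rule = 2)
  t0 <- times[1L]
  function(t) af(((t - t0) %% period) + t0)
}

circ_dist <- function(a, b, period) {
  abs(((a - b + period / 2) %% period) - period / 2)
}

new_rate_curve <- function(times, r, provenance, period, anchors = NULL,
                           config = list()) {
  structure(list(times = times, r = r, provenance = provenance,
                 period = period, anchors = anchors, config = config),
            class = "inferred_rate_curve")
}

#' @export
print.inferred_rate_curve <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("<inferred_rate_curve> %d grid points over (0, %g] h; r in [%.3g, %.3g] 1/h\n",
              length(x$times), x$period, min(x$r), max(x$r)))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Continuous waveform through a reconstructed rate curve
#'
#' Periodic piecewise-linear interpolation through the grid values; the
#' natural continuous representation for cost integrals over a curve that
#' was reconstructed pointwise.
#'
#' @param curve an `inferred_rate_curve`.
#' @return a [circ_waveform()].
#' @export
rate_curve_waveform <- function(curve) {
  stopifnot(inherits(curve, "inferred_rate_curve"))
  s <- circ_series(curve$times, pmax(curve$r, 0), curve$period,
                   label = "r(t)")
  fit_periodic_waveform(s, method = "linear")
}

#' Cap and floor a reconstructed rate curve
#'
#' Reconstruction from noisy profiles can overshoot: values larger than any
#' plausible rate are capped, and values below the smallest experimentally
#' measured rate are floored (which *reduces* the difference between c and
#' c_g, keeping the cost-reduction estimate conservative).
#'
#' Cap rules: a number; `list(rule = "window_max", window = c(lo, hi))` (cap
#' at the curve's own maximum over a stated window, e.g. 20--22 h); or
#' `list(rule = "r_min", value = r_min)` (cap at the waveform's r_min).
#' Floor rules: a number, or `list(rule = "min_anchor")` (minimum measured
#' anchor rate).
#'
#' @param curve an `inferred_rate_curve`.
#' @param cap cap rule or `NULL`.
#' @param floor floor rule or `NULL`.
#' @return the bounded curve, with provenance `capped_high` / `floored_low`
#'   on altered points (anchor points are never altered).
#' @export
apply_bounds <- function(curve, cap = NULL, floor = NULL) {
  stopifnot(inherits(curve, "inferred_rate_curve"))
  cap_v <- resolve_cap(curve, cap)
  floor_v <- resolve_floor(curve, floor)
  if (!is.null(cap_v) && !is.null(floor_v) && cap_v < floor_v) {
    stop("cap is below floor", call. = FALSE)
  }
  r <- curve$r
  prov <- curve$provenance
  movable <- prov != "anchor"
  if (!is.null(cap_v)) {
    hit <- movable & r > cap_v
    r[hit] <- cap_v
    prov[hit] <- "capped_high"
  }
  if (!is.null(floor_v)) {
    hit <- movable & r < floor_v
    r[hit] <- floor_v
    prov[hit] <- "floored_low"
  }
  out <- curve
  out$r <- r
  out$provenance <- prov
  out$config <- c(curve$config, list(cap = cap_v, floor = floor_v))
  out
}

resolve_cap <- function(curve, cap) {
  if (is.null(cap)) return(NULL)
  if (is.numeric(cap)) return(cap)
  stopifnot(is.list(cap), !is.null(cap$rule))
  switch(cap$rule,
    window_max = {
      w <- cap$window
      in_w <- curve$times >= w[1L] - 1e-9 & curve$times <= w[2L] + 1e-9
      if (!any(in_w)) stop("cap window contains no grid points", call. = FALSE)
      max(curve$r[in_w])
    },
    r_min = cap$value,
    stop("unknown cap rule: ", cap$rule, call. = FALSE)
  )
}

resolve_floor <- function(curve, floor) {
  if (is.null(floor)) return(NULL)
  if (is.numeric(floor)) return(floor)
  stopifnot(is.list(floor), !is.null(floor$rule))
  switch(floor$rule,
    min_anchor = {
      if (is.null(curve$anchors) || nrow(curve$anchors) == 0L) {
        stop("min_anchor floor requires anchors on the curve", call. = FALSE)
      }
      min(curve$anchors$r)
    },
    stop("unknown floor rule: ", floor$rule, call. = FALSE)
  )
}

#' Replace an artifact window by a line through measured rates
#'
#' Reconstructed rates inside a stated window (chosen per protein after
#' visual inspection, e.g. 2--10 h for PRR7, 6--10 h for PRR5) can deviate
#' implausibly from the measured trend; grid points inside the window are
#' replaced by linear interpolation/extrapolation through the named measured
#' rates (one anchor: constant extrapolation; two: a straight line).
#'
#' @param curve an `inferred_rate_curve`.
#' @param window `c(lo, hi)` in hours; `NULL` or empty for identity.
#' @param anchors_for_line one or two `(t, r)` anchors defining the line;
#'   data frame or list of pairs.
#' @return the corrected curve with provenance `corrected_window` inside the
#'   window (anchor points are preserved).
#' @export
correct_window <- function(curve, window, anchors_for_line) {
  stopifnot(inherits(curve, "inferred_rate_curve"))
  if (is.null(window) || length(window) == 0L) return(curve)
  a <- as_anchor_frame(anchors_for_line)
  if (nrow(a) < 1L) stop("need at least one anchor for the line", call. = FALSE)
  line <- if (nrow(a) == 1L) {
    function(t) rep(a$r[1L], length(t))
  } else {
    a2 <- a[order(a$t), ][1:2, ]
    slope <- (a2$r[2L] - a2$r[1L]) / (a2$t[2L] - a2$t[1L])
    function(t) a2$r[1L] + slope * (t - a2$t[1L])
  }
  in_w <- curve$times >= window[1L] - 1e-9 & curve$times <= window[2L] + 1e-9
  movable <- in_w & curve$provenance != "anchor"
  out <- curve
  out$r[movable] <- line(curve$times[movable])
  out$provenance[movable] <- "corrected_window"
  out$config <- c(curve$config, list(artifact_window = window))
  out
}

#' Anchors-only degradation-rate estimate
#'
#' When measured degradation rates cover a wide enough span of the cycle
#' (the mammalian PER2 case) the full curve can be sketched without an mRNA
#' profile: periodic piecewise-linear interpolation through the anchors,
#' lifted pointwise to the waveform bound R(t) so the reconstruction never
#' violates r(t) >= R(t).
#'
#' @param x protein [circ_waveform()].
#' @param anchors at least two anchor measurements.
#' @param grid_h output grid spacing (hours).
#' @param profile optional precomputed [lower_bound_profile()] of `x` (e.g.
#'   with R-smoothing); computed unsmoothed if missing.
#' @return an `inferred_rate_curve`; provenance `anchor` at anchor grid
#'   times, `inferred` on interpolated points, `floored_low` where R(t)
#'   lifted the interpolant.
#' @export
infer_from_anchors_only <- function(x, anchors, grid_h = 0.5,
                                    profile = NULL) {
  assert_waveform(x)
  a <- as_anchor_frame(anchors)
  if (nrow(a) < 2L) stop("need at least two anchors", call. = FALSE)
  T <- x$period
  if (is.null(profile)) profile <- lower_bound_profile(x)
  at <- fold_time(a$t, T)
  ord <- order(at)
  interp <- periodic_linear_interp(at[ord], pmax(a$r[ord], 0), T)
  grid <- seq(grid_h, T, by = grid_h)
  base <- interp(grid)
  Rv <- profile$R_fun(grid)
  r <- pmax(base, Rv)
  prov <- ifelse(r > base + 1e-12, "floored_low", "inferred")
  for (j in seq_along(at)) {
    i <- which.min(abs(circ_dist(grid, at[j], T)))
    if (prov[i] != "floored_low") prov[i] <- "anchor"
  }
  new_rate_curve(grid, r, prov, T, anchors = a,
                 config = list(grid_h = grid_h, mode = "anchors_only"))
}
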
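#' Named periodic waveform primitives
#'
#' Builds the simple positive periodic waveforms used to specify synthetic
#' circadian scenarios:
#'
#' * `constant`: `value`;
#' * `sinusoid`: `mean + amplitude * cos(omega (t - peak_t))` (requires
#'   `mean >= amplitude` for positivity);
#' * `truncated_sinusoid`: `base + max(amplitude * cos(omega (t - peak_t)),
#'   0)` — a half-wave-rectified bump, the typical shape of high-amplitude
#'   clock transcript profiles;
#' * `double_gaussian`: `base` plus two circularly wrapped Gaussian bumps
#'   (`a1, t1, s1`, `a2, t2, s2`).
#'
#' @param spec list with `type` and the parameters above.
#' @param period period T in hours.
#' @return a [circ_waveform()] with analytic derivative.
#' @export
waveform_primitive <- function(spec, period = 24) {
  stopifnot(is.list(spec), !is.null(spec$type), period > 0)
  omega <- 2 * pi / period
  wrap <- function(t, center) ((t - center + period / 2) %% period) - period / 2
  w <- switch(spec$type,
    constant = {
      v <- spec$value
      stopifnot(v >= 0)
      circ_waveform(function(t) rep(v, length(t)),
                    function(t) rep(0, length(t)), period)
    },
    sinusoid = {
      m <- spec$mean; a <- spec$amplitude; p <- spec$peak_t
      stopifnot(m >= a, a >= 0)
      circ_waveform(function(t) m + a * cos(omega * (t - p)),
                    function(t) -a * omega * sin(omega * (t - p)), period)
    },
    truncated_sinusoid = {
      b <- spec$base; a <- spec$amplitude; p <- spec$peak_t
      stopifnot(b >= 0, a >= 0)
      circ_waveform(
        function(t) b + pmax(a * cos(omega * (t - p)), 0),
        function(t) {
          ifelse(cos(omega * (t - p)) > 0,
                 -a * omega * sin(omega * (t - p)), 0)
        }, period)
    },
    double_gaussian = {
      b <- spec$base
      stopifnot(b >= 0, spec$a1 >= 0, spec$a2 >= 0,
                spec$s1 > 0, spec$s2 > 0)
      bump <- function(t, a, c, s) a * exp(-wrap(t, c)^2 / (2 * s^2))
      dbump <- function(t, a, c, s) {
        d <- wrap(t, c)
        -a * d / s^2 * exp(-d^2 / (2 * s^2))
      }
      circ_waveform(
        function(t) b + bump(t, spec$a1, spec$t1, spec$s1) +
          bump(t, spec$a2, spec$t2, spec$s2),
        function(t) dbump(t, spec$a1, spec$t1, spec$s1) +
          dbump(t, spec$a2, spec$t2, spec$s2), period)
    },
    stop("unknown waveform primitive: ", spec$type, call. = FALSE)
  )
  w$label <- spec$type
  w
}

#' Build a ground-truth synthetic circadian scenario
#'
#' Fully specifies a synthesis/turnover system dx/dt = k(t) g_m(t) -
#' r_true(t) x(t) with known mRNA profile, translation rate and degradation
#' rate, and integrates it to its periodic steady state (burn-in of at least
#' 10 periods; consecutive-period sup-norm residual below `tol`).  The
#' default scenario mimics a PRR-type plant clock protein under a 24-h
#' light-dark cycle: transcript peaking mid-day, degradation rate peaking
#' just before the protein trough.
#'
#' @param g_m mRNA waveform: a primitive spec list (see
#'   [waveform_primitive()]) or a [circ_waveform()].
#' @param r_true degradation-rate waveform, same forms.
#' @param k translation rate: a positive constant or a `translation_model`.
#' @param period period T in hours.
#' @param seed integer seed governing all noise drawn from the scenario.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (immunoblot-style proportional error).
#' @param sampling_interval_h sampling interval for emitted datasets.
#' @param anchor_times times (hours) at which degradation-rate anchors are
#'   emitted.
#' @param tol limit-cycle residual tolerance.
#' @param horizon maximum number of periods to integrate.
#' @return a `circ_scenario`: list with waveforms `g_m`, `r_true`, `x_true`,
#'   the translation model, scenario parameters and the achieved `residual`.
#' @export
make_scenario <- function(g_m = list(type = "truncated_sinusoid", base = 0.05,
                                     amplitude = 1, peak_t = 8),
                          r_true = list(type = "truncated_sinusoid",
                                        base = 0.15, amplitude = 0.9,
                                        peak_t = 21),
                          k = 0.7, period = 24, seed = 1L,
                          noise_cv = 0.05, sampling_interval_h = 2,
                          anchor_times = c(4, 12, 18),
                          tol = 1e-8, horizon = 200) {
  gw <- if (is_circ_waveform(g_m)) g_m else waveform_primitive(g_m, period)
  rw <- if (is_circ_waveform(r_true)) r_true else
    waveform_primitive(r_true, period)
  tm <- if (inherits(k, "translation_model")) k else {
    stopifnot(is.numeric(k), k > 0)
    structure(list(mode = "constant", k = k, k_i = k),
              class = "translation_model")
  }
  grid <- seq(0, period, by = 0.05)
  deriv <- function(t, state, parms) {
    kv <- translation_rate(tm, t, period = period)
    list(kv * gw$fun(t) - rw$fun(t) * state[1L])
  }
  # start from the mean-field fixed point to shorten the burn-in
  x0 <- mean(translation_rate(tm, grid, period) * gw$fun(grid)) /
    max(mean(rw$fun(grid)), 1e-12)
  state <- c(x = x0)
  prev <- NULL
  residual <- Inf
  sol_final <- NULL
  for (p in seq_len(horizon)) {
    sol <- deSolve::ode(y = state, times = (p - 1) * period + grid,
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-13)
    traj <- sol[, "x"]
    state <- c(x = unname(traj[length(traj)]))
    if (!is.null(prev) && p > 10L) {
      residual <- max(abs(traj - prev)) / max(abs(traj), 1e-12)
      if (residual < tol) {
        sol_final <- traj
        break
      }
    }
    prev <- traj
  }
  if (is.null(sol_final)) {
    stop(sprintf(
      "no periodic solution within %d periods (residual %.3g)",
      horizon, residual), call. = FALSE)
  }
  x_true <- fit_periodic_waveform(
    circ_series(grid[-1L], pmax(sol_final[-1L], 0), period,
                label = "x_true"),
    method = "spline")
  structure(
    list(g_m = gw, r_true = rw, x_true = x_true, tm = tm,
         period = period, seed = as.integer(seed), noise_cv = noise_cv,
         sampling_interval_h = sampling_interval_h,
         anchor_times = anchor_times, residual = residual),
    class = "circ_scenario"
  )
}

#' @export
print.circ_scenario <- function(x, ...) {
  cat(sprintf(
    "<circ_scenario> T = %g h, k mode %s, noise CV %g, %g-h sampling, seed %d\n",
    x$period, x$tm$mode, x$noise_cv, x$sampling_interval_h, x$seed))
  cat(sprintf("  limit-cycle residual %.2g; anchors at t = %s h\n",
              x$residual, paste(x$anchor_times, collapse = ", ")))
  invisible(x)
}

#' Sample a noisy dataset from a scenario
#'
#' Emulates the published data regime: the protein and mRNA waveforms are
#' sampled at the scenario's interval over (0, T], multiplied by log-normal
#' noise of the stated coefficient of variation (unit mean), and normalized
#' by their spline peaks; degradation-rate anchors are read off r_true at
#' the scenario's anchor times (optionally with the same noise).  The
#' scenario seed fully determines the output.
#'
#' @param sc a [make_scenario()] result.
#' @param noisy_anchors also perturb the anchors (default FALSE).
#' @param normalize peak-normalize the emitted series (default TRUE; set
#'   FALSE to inspect the raw noisy samples, e.g. for noise-model checks).
#' @return list with `x` and `g_m` (peak-normalized [circ_series()]) and
#'   `anchors` (data frame `t`, `r`, `sd`).
#' @export
sample_dataset <- function(sc, noisy_anchors = FALSE, normalize = TRUE) {
  stopifnot(inherits(sc, "circ_scenario"))
  T <- sc$period
  tt <- seq(sc$sampling_interval_h, T, by = sc$sampling_interval_h)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(sc$seed)
  lognoise <- function(n) {
    if (sc$noise_cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + sc$noise_cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  xs <- circ_series(tt, sc$x_true$fun(tt) * lognoise(length(tt)), T,
                    label = "protein", light_regime = "12L:12D")
  gs <- circ_series(tt, sc$g_m$fun(tt) * lognoise(length(tt)), T,
                    label = "mRNA", light_regime = "12L:12D")
  at <- fold_time(sc$anchor_times, T)
  ar <- sc$r_true$fun(at)
  if (noisy_anchors) ar <- ar * lognoise(length(at))
  if (normalize) {
    xs <- normalize_to_spline_peak(xs)
    gs <- normalize_to_spline_peak(gs)
  }
  list(x = xs, g_m = gs,
       anchors = data.frame(t = at, r = ar, sd = NA_real_))
}

#' Ground-truth recovery report for an inference run
#'
#' Compares a reconstructed degradation-rate curve and cost summary against
#' the scenario's ground truth: sup-norm and RMS error of r(t) on the
#' curve's grid (relative to max r_true), error in the recovered translation
#' constant (compared in the peak-normalized frame, where the true effective
#' constant is k * peak(g_m)/peak(x)), and error in the cost reduction
#' against the true (c_g - c)/c_g.
#'
#' @param sc a [make_scenario()] result.
#' @param inferred an `inferred_rate_curve` computed from
#'   [sample_dataset()] output.
#' @param cost optional `cost_summary` from the same run.
#' @param tm optional fitted `translation_model` (constant mode) to score.
#' @return list of error metrics (`r_sup_rel`, `r_rms_rel`, `k_rel_error`,
#'   `cost_reduction_true`, `cost_reduction_error`).
#' @export
recovery_report <- function(sc, inferred, cost = NULL, tm = NULL) {
  stopifnot(inherits(sc, "circ_scenario"),
            inherits(inferred, "inferred_rate_curve"))
  tt <- inferred$times
  r_true <- sc$r_true$fun(tt)
  scale <- max(r_true)
  err <- inferred$r - r_true
  out <- list(r_sup_rel = max(abs(err)) / scale,
              r_rms_rel = sqrt(mean(err^2)) / scale)
  if (!is.null(tm) && tm$mode == "constant" && sc$tm$mode == "constant") {
    grid <- seq(0.01, sc$period, by = 0.01)
    k_eff_true <- sc$tm$k * max(sc$g_m$fun(grid)) / max(sc$x_true$fun(grid))
    out$k_eff_true <- k_eff_true
    out$k_rel_error <- abs(tm$k - k_eff_true) / k_eff_true
  }
  true_cost <- production_cost(sc$x_true, sc$r_true)
  out$cost_reduction_true <- true_cost$cost_reduction
  if (!is.null(cost)) {
    out$cost_reduction_recovered <- cost$cost_reduction
    out$cost_reduction_error <-
      abs(cost$cost_reduction - true_cost$cost_reduction)
  }
  out
}
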
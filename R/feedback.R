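#' Two-component negative-feedback clock model
#'
#' The core mammalian (and insect) clock couples an activator complex
#' (CLOCK-BMAL1) to an inhibitor complex (PER-CRY) in the nucleus.  With
#' x_A and x_I the active and inactive activator concentrations and y the
#' free inhibitor, the dynamics are
#' \deqn{dx_A/dt = \tilde\alpha(t) + k_1 x_I - k y(t) x_A - r_1 x_A,}
#' \deqn{dx_I/dt = k y(t) x_A - k_1 x_I - r_2 x_I,}
#' where \eqn{\tilde\alpha(t)} is the nuclear-import rate of the activator,
#' k_1 and k the dissociation/association rate constants, and r_1, r_2 the
#' clearance rates.  Writing x_n = x_A + x_I, the active form obeys
#' dx_A/dt = g_A(t) - [r_0 + k y(t)] x_A with g_A = k_1 x_n + alpha-tilde
#' and r_0 = k_1 + r_1.
#'
#' @param alpha_tilde nuclear-import rate: a function of time, a
#'   [circ_waveform()], or a constant.
#' @param k1 dissociation rate constant (1/h).
#' @param k association rate constant (1/conc/h).
#' @param r1,r2 clearance rates (1/h) of the active and inactive forms.
#' @param period period T in hours.
#' @return a `feedback_model` list; `r0` = `k1 + r1` is precomputed.
#' @export
feedback_model <- function(alpha_tilde, k1, k, r1, r2, period = 24) {
  stopifnot(k1 >= 0, k >= 0, r1 >= 0, r2 >= 0, period > 0)
  af <- as_time_function(alpha_tilde)
  structure(list(alpha_tilde = af, k1 = k1, k = k, r1 = r1, r2 = r2,
                 r0 = k1 + r1, period = period),
            class = "feedback_model")
}

as_time_function <- function(x) {
  if (is_circ_waveform(x)) return(x$fun)
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  stop("expected a function, waveform or single number", call. = FALSE)
}

#' Simulate the feedback model to its periodic steady state
#'
#' Integrates the activator equations under a prescribed periodic free-
#' inhibitor drive y(t) until consecutive periods agree in sup norm, then
#' returns the limit-cycle waveforms of x_A and x_I as periodic splines.
#'
#' @param model a [feedback_model()].
#' @param y_drive free-inhibitor drive: function, [circ_waveform()] or
#'   constant; must be periodic with the model's period.
#' @param horizon maximum number of periods to integrate.
#' @param tol convergence tolerance: sup-norm difference between consecutive
#'   periods, relative to the solution scale.
#' @param grid_h output grid spacing in hours.
#' @return list with `x_A`, `x_I`, `x_n` ([circ_waveform()]s), the number of
#'   `periods` used and the final `residual`.
#' @export
simulate_feedback <- function(model, y_drive, horizon = 50, tol = 1e-8,
                              grid_h = 0.05) {
  stopifnot(inherits(model, "feedback_model"))
  yf <- as_time_function(y_drive)
  T <- model$period
  times <- seq(0, T, by = grid_h)
  deriv <- function(t, state, parms) {
    y <- yf(t)
    a <- model$alpha_tilde(t)
    dxA <- a + model$k1 * state[2L] -
      model$k * y * state[1L] - model$r1 * state[1L]
    dxI <- model$k * y * state[1L] - model$k1 * state[2L] -
      model$r2 * state[2L]
    list(c(dxA, dxI))
  }
  state <- c(xA = 0, xI = 0)
  prev <- NULL
  residual <- Inf
  for (p in seq_len(horizon)) {
    sol <- deSolve::ode(y = state, times = p * T - T + times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    traj <- sol[, c("xA", "xI"), drop = FALSE]
    state <- traj[nrow(traj), ]
    if (!is.null(prev)) {
      scale <- max(abs(traj), 1e-12)
      residual <- max(abs(traj - prev)) / scale
      if (residual < tol) {
        make_wave <- function(v, lab) {
          # drop the duplicate endpoint; periodic fit wraps it back
          fit_periodic_waveform(
            circ_series(times[-1L], pmax(v[-1L], 0), T, label = lab),
            method = "spline")
        }
        return(list(x_A = make_wave(traj[, 1L], "x_A"),
                    x_I = make_wave(traj[, 2L], "x_I"),
                    x_n = make_wave(traj[, 1L] + traj[, 2L], "x_n"),
                    periods = p, residual = residual))
      }
    }
    prev <- traj
  }
  stop(sprintf(
    "no periodic steady state within %d periods (residual %.3g)",
    horizon, residual), call. = FALSE)
}

#' Free-inhibitor waveform implied by an activator waveform
#'
#' Inverts the active-activator balance: k y(t) = [g_A(t) - x'(t)]/x(t)
#' - r_0.  Times where the implied y is negative are physically infeasible
#' (they would require a negative inhibitor concentration) and are flagged,
#' not raised.
#'
#' @param x active-activator [circ_waveform()], strictly positive.
#' @param g_A activation drive: function, waveform or constant (1/h units of
#'   concentration supply).
#' @param r0 combined dissociation + clearance rate (1/h).
#' @param k association rate constant (> 0).
#' @return a [circ_waveform()] for y with attributes `infeasible_times`
#'   (grid times where y < 0) and `feasible` (logical).
#' @export
inhibitor_from_activator <- function(x, g_A, r0, k) {
  assert_waveform(x)
  stopifnot(k > 0, r0 >= 0)
  gf <- as_time_function(g_A)
  T <- x$period
  grid <- seq(.circwave_defaults$grid_report_h, T,
              by = .circwave_defaults$grid_report_h)
  xv <- x$fun(grid)
  if (any(xv <= 0)) {
    stop("activator waveform must be strictly positive", call. = FALSE)
  }
  yfun <- function(t) ((gf(t) - x$deriv(t)) / x$fun(t) - r0) / k
  # derivative of y via the quotient rule needs x''; use a centered stencil
  h <- 1e-5
  yder <- function(t) (yfun(t + h) - yfun(t - h)) / (2 * h)
  yv <- yfun(grid)
  w <- circ_waveform(yfun, yder, T, method = "derived", label = "y(t)")
  attr(w, "infeasible_times") <- grid[yv < 0]
  attr(w, "feasible") <- all(yv >= 0)
  w
}

#' Drive specification for the activation rate g_A(t)
#'
#' Three stylized forms of the activation drive: constant (g_A = g, the
#' constitutive-BMAL1 scenario), `linear_lag` (g_A(t) = alpha +
#' beta x(t + tau), oscillating BMAL1 tracking the activator with lag tau),
#' and `half_period` (tau = T/2 + epsilon, handled through the half-period
#' antisymmetry approximation).
#'
#' @param mode `"constant"`, `"linear_lag"` or `"half_period"`.
#' @param g constant drive level (constant mode).
#' @param alpha,beta,tau linear-lag parameters (beta >= 0, tau >= 0).
#' @param epsilon offset from T/2 (half-period mode).
#' @return a `drive_spec` list.
#' @export
drive_spec <- function(mode = c("constant", "linear_lag", "half_period"),
                       g = NULL, alpha = NULL, beta = NULL, tau = NULL,
                       epsilon = NULL) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    constant = {
      stopifnot(is.numeric(g))
      list(mode = mode, g = g)
    },
    linear_lag = {
      stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(tau),
                beta >= 0, tau >= 0)
      list(mode = mode, alpha = alpha, beta = beta, tau = tau)
    },
    half_period = {
      stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(epsilon),
                beta >= 0)
      list(mode = mode, alpha = alpha, beta = beta, epsilon = epsilon)
    })
  structure(spec, class = "drive_spec")
}

#' Minimum feasible drive level
#'
#' The implied free inhibitor must satisfy r_0 + k y(t) >= 0 with x(t) >= 0,
#' which bounds the drive from below.  Constant mode: g_min = max_t x'(t).
#' Linear-lag mode: alpha_min = max\{ max_t [x'(t) - beta x(t + tau)],
#' max_t [-beta x(t)] \}.  For the analytic sinusoid the linear-lag floor has
#' the closed form
#' \deqn{\alpha_{min} = \max\{L \sqrt{1 - (2\beta/\omega)\sin(\omega\tau) +
#'   \beta^2/\omega^2} - \beta L/\omega,\ 0\} - \beta h_0,}
#' which is cross-checked against the grid maximization.
#'
#' @param x a [circ_waveform()] (a [sinusoid_waveform()] enables the closed
#'   form).
#' @param drive a [drive_spec()] of mode `"constant"` or `"linear_lag"`.
#' @return the floor (g_min or alpha_min) in the drive's units; for a
#'   sinusoid in linear-lag mode the attribute `closed_form` carries the
#'   analytic value.
#' @export
feasibility_floor <- function(x, drive) {
  assert_waveform(x)
  stopifnot(inherits(drive, "drive_spec"))
  T <- x$period
  if (drive$mode == "constant") {
    return(periodic_argmax(x$deriv, T)$value)
  }
  if (drive$mode != "linear_lag") {
    stop("feasibility floor is defined for constant and linear_lag drives",
         call. = FALSE)
  }
  beta <- drive$beta
  tau <- drive$tau
  m1 <- periodic_argmax(function(t) x$deriv(t) - beta * x$fun(t + tau), T)$value
  m2 <- periodic_argmax(function(t) -beta * x$fun(t), T)$value
  floor_num <- max(m1, m2)
  if (inherits(x, "sinusoid_waveform")) {
    L <- x$L; h0 <- x$h0; omega <- x$omega
    cf <- max(L * sqrt(1 - (2 * beta / omega) * sin(omega * tau) +
                         beta^2 / omega^2) - beta * L / omega, 0) -
      beta * h0
    if (abs(cf - floor_num) > 1e-3 * max(1, abs(cf))) {
      warning(sprintf(
        "closed-form floor %.6g differs from grid maximization %.6g", cf,
        floor_num))
    }
    attr(floor_num, "closed_form") <- cf
  }
  floor_num
}

new_phase_solution <- function(t_x, t_y, period, regime, feasible,
                               bounds = NULL, n_branch = NA_integer_) {
  omega <- 2 * pi / period
  phi <- omega * circ_dist(t_y, t_x, period)
  structure(list(t_x = t_x, t_y = t_y, phi = phi, period = period,
                 regime = regime, feasible = feasible, bounds = bounds,
                 n_branch = n_branch),
            class = "phase_solution")
}

#' @export
print.phase_solution <- function(x, ...) {
  cat(sprintf(
    "<phase_solution> t_x = %.3f h, t_y = %.3f h, phi = %.4f rad (%.3f pi)%s\n",
    x$t_x, x$t_y, x$phi, x$phi / pi,
    if (x$feasible) "" else "  [INFEASIBLE drive]"))
  cat(sprintf("  regime: %s\n", x$regime))
  invisible(x)
}

#' Peak-time difference under a constant activation drive
#'
#' For the analytic sinusoid x(t) and constant drive g_A = g, the phase
#' difference between x and the implied free inhibitor y has the closed form
#' \deqn{\phi = \pi - 2 \tan^{-1}[(\sqrt{C^2 - L^2 + g^2} - g)/(C + L)],}
#' with C = h_0 omega + L.  The solution is physically feasible only for
#' g >= g_min = L; an infeasible g is flagged, not raised.  The closed form
#' is cross-checked against numeric peak-finding of y(t).
#'
#' @param s a [sinusoid_waveform()].
#' @param g constant drive level (1/h concentration supply).
#' @param check numerically verify against grid peak-finding (default TRUE).
#' @return a `phase_solution` with t_x = T/2 and t_y on (0, T].
#' @examples
#' s <- sinusoid_waveform(3, 2, 24)
#' phase_constant_drive(s, g = 3)$phi / pi
#' @export
phase_constant_drive <- function(s, g, check = TRUE) {
  stopifnot(inherits(s, "sinusoid_waveform"))
  L <- s$L; C <- s$C; T <- s$period; omega <- s$omega
  feasible <- g >= L
  phi <- pi - 2 * atan((sqrt(C^2 - L^2 + g^2) - g) / (C + L))
  t_x <- T / 2
  t_y <- fold_time(t_x + phi / omega, T)
  if (check && feasible) {
    t_num <- periodic_argmax(function(t) (g - s$deriv(t)) / s$fun(t), T)$t
    if (circ_dist(t_num, t_y, T) > 1e-3) {
      warning(sprintf(
        "closed-form t_y = %.4f h disagrees with numeric argmax %.4f h",
        t_y, t_num))
    }
  }
  new_phase_solution(t_x, t_y, T, regime = "constant_drive",
                     feasible = feasible)
}

#' Peak-time difference under an oscillating activation drive
#'
#' For the sinusoid x(t) and the lagged-linear drive g_A(t) = alpha +
#' beta x(t + tau), the free-inhibitor peak time has the exact closed form
#' \deqn{\omega t_y = 2\pi n + 2\tan^{-1}\{[ \omega\alpha +
#'   C\beta(1-\cos\omega\tau) - \sqrt{(\omega\alpha +
#'   C\beta(1-\cos\omega\tau))^2 + (C^2-L^2)(\omega - \beta\sin\omega\tau)^2}
#'   ] / [(C+L)(\omega - \beta\sin\omega\tau)]\},}
#' with the branch integer n chosen so that 0 < omega t_y <= 2 pi.  Sweeping
#' alpha, beta and tau moves the phase difference anywhere from near
#' in-phase to near anti-phase.  The result is cross-checked against numeric
#' peak-finding of the exact y(t) (no small-tau approximation).
#'
#' @param s a [sinusoid_waveform()].
#' @param drive a [drive_spec()] of mode `"linear_lag"`.
#' @param check numerically verify against grid peak-finding (default TRUE).
#' @return a `phase_solution`; `feasible` is `FALSE` when alpha < alpha_min.
#' @export
phase_oscillating_drive <- function(s, drive, check = TRUE) {
  stopifnot(inherits(s, "sinusoid_waveform"),
            inherits(drive, "drive_spec"), drive$mode == "linear_lag")
  L <- s$L; C <- s$C; T <- s$period; omega <- s$omega
  alpha <- drive$alpha; beta <- drive$beta; tau <- drive$tau
  denom_rate <- omega - beta * sin(omega * tau)
  if (abs(denom_rate) < 1e-12) {
    stop("singular configuration: omega - beta*sin(omega*tau) = 0",
         call. = FALSE)
  }
  a_min <- feasibility_floor(s, drive)
  feasible <- alpha >= a_min - 1e-12
  num <- omega * alpha + C * beta * (1 - cos(omega * tau))
  disc <- sqrt(num^2 + (C^2 - L^2) * denom_rate^2)
  core <- 2 * atan((num - disc) / ((C + L) * denom_rate))
  n <- 0L
  repeat {
    wty <- 2 * pi * n + core
    if (wty > 0 && wty <= 2 * pi) break
    n <- n + if (wty <= 0) 1L else -1L
    if (abs(n) > 4L) stop("branch search failed", call. = FALSE)
  }
  t_y <- wty / omega
  t_x <- T / 2
  if (check && feasible) {
    yexact <- function(t) {
      (alpha + beta * s$fun(t + tau) - s$deriv(t)) / s$fun(t)
    }
    t_num <- periodic_argmax(yexact, T, grid_h = 1e-3)$t
    if (circ_dist(t_num, t_y, T) > 1e-2) {
      warning(sprintf(
        "closed-form t_y = %.4f h disagrees with numeric argmax %.4f h",
        t_y, t_num))
    }
  }
  sol <- new_phase_solution(t_x, t_y, T, regime = "oscillating_drive",
                            feasible = feasible, n_branch = n)
  sol$alpha_min <- a_min
  sol
}

#' Classify the inhibitor peak-time regime
#'
#' Under the small-lag approximation x(t + tau) ~ x(t) + tau x'(t), the
#' implied inhibitor k y(t) ~ [alpha - (1 - beta tau) x'(t)]/x(t) + beta -
#' r_0 falls into one of four regimes depending on the signs of alpha and
#' 1 - beta tau, each confining the peak time t_y to an interval between
#' waveform landmarks (hotspot t_R = argmax(-x'/x), trough t_b = argmax 1/x,
#' mirror hotspot argmax(x'/x), and peak t_x):
#'
#' * alpha > 0, beta tau < 1: t_y in \[t_R, t_b\] (the constant-drive range);
#' * alpha > 0, beta tau > 1: t_y in \[t_b, argmax(x'/x)\];
#' * alpha < 0, beta tau < 1: t_y in \[t_x, t_R\];
#' * alpha < 0, beta tau > 1: t_y in \[argmax(x'/x), t_x\].
#'
#' Intervals are circular (taken forward from the first landmark to the
#' second within one period).
#'
#' @param x a [circ_waveform()] (tau is assumed small relative to T).
#' @param drive a [drive_spec()] of mode `"linear_lag"`.
#' @return list with `regime` (1-4), `description`, `bounds` (circular
#'   interval `c(lo, hi)` in hours) and the computed `landmarks`.  A
#'   boundary case (alpha = 0 or beta tau = 1) yields regime `NA` with an
#'   explanatory description.
#' @export
classify_ty_regime <- function(x, drive) {
  assert_waveform(x)
  stopifnot(inherits(drive, "drive_spec"), drive$mode == "linear_lag")
  T <- x$period
  lm <- list(
    t_x = periodic_argmax(x$fun, T)$t,
    t_b = periodic_argmin(x$fun, T)$t,                       # argmax 1/x
    t_neg = periodic_argmax(function(t) -x$deriv(t) / x$fun(t), T)$t,
    t_pos = periodic_argmax(function(t) x$deriv(t) / x$fun(t), T)$t
  )
  a <- drive$alpha
  bt <- drive$beta * drive$tau
  if (a == 0 || abs(bt - 1) < 1e-12) {
    return(list(regime = NA_integer_,
                description = "boundary case (alpha = 0 or beta*tau = 1): regime undefined",
                bounds = NULL, landmarks = lm))
  }
  reg <- if (a > 0 && bt < 1) {
    list(1L, "alpha > 0, beta*tau < 1: t_y between hotspot and trough",
         c(lm$t_neg, lm$t_b))
  } else if (a > 0 && bt > 1) {
    list(2L, "alpha > 0, beta*tau > 1: t_y between trough and rising hotspot",
         c(lm$t_b, lm$t_pos))
  } else if (a < 0 && bt < 1) {
    list(3L, "alpha < 0, beta*tau < 1: t_y between peak and hotspot",
         c(lm$t_x, lm$t_neg))
  } else {
    list(4L, "alpha < 0, beta*tau > 1: t_y between rising hotspot and peak",
         c(lm$t_pos, lm$t_x))
  }
  list(regime = reg[[1L]], description = reg[[2L]], bounds = reg[[3L]],
       landmarks = lm)
}

#' Test whether a time lies in a circular interval
#'
#' @param t time in hours.
#' @param bounds `c(lo, hi)`; the interval runs forward from lo to hi,
#'   wrapping through T if necessary.
#' @param period period T in hours.
#' @param tol tolerance in hours.
#' @return logical.
#' @export
in_circular_interval <- function(t, bounds, period, tol = 1e-6) {
  span <- (bounds[2L] - bounds[1L]) %% period
  off <- (t - bounds[1L]) %% period
  off <= span + tol | off >= period - tol
}

#' Inhibitor waveform under a near-half-period lag
#'
#' When the drive lag is close to half a period (tau = T/2 + epsilon with
#' |epsilon| << T) and the waveform is approximately antisymmetric about its
#' mean level, x(t + T/2) ~ J - x(t) with J = (2/T) integral of x, the
#' implied inhibitor reduces to
#' \deqn{k y(t) \approx [\alpha + \beta J - (1 + \beta\epsilon) x'(t)]/x(t)
#'   - (r_0 + \beta).}
#' With beta*epsilon ~ -1 the x' term vanishes and y becomes symmetric about
#' its peak.  The antisymmetry assumption is checked and reported, not
#' enforced.
#'
#' @param x a [circ_waveform()].
#' @param epsilon lag offset from T/2 in hours.
#' @param alpha,beta drive parameters.
#' @param r0 combined rate (1/h).
#' @param k association constant (> 0).
#' @param antisym_tol tolerated sup-norm antisymmetry violation, relative to
#'   the waveform amplitude (default 0.05).
#' @return a [circ_waveform()] for y with attributes `J`,
#'   `antisymmetry_residual` and `antisymmetry_ok`.
#' @export
half_period_drive <- function(x, epsilon, alpha, beta, r0, k,
                              antisym_tol = 0.05) {
  assert_waveform(x)
  stopifnot(k > 0, beta >= 0)
  T <- x$period
  J <- 2 * time_average(x)
  grid <- seq(0.05, T, by = 0.05)
  amp <- diff(range(x$fun(grid)))
  resid <- max(abs(x$fun(grid + T / 2) - (J - x$fun(grid)))) / amp
  ok <- resid <= antisym_tol
  if (!ok) {
    warning(sprintf(
      "waveform violates half-period antisymmetry (residual %.3g of amplitude); approximation may be poor",
      resid))
  }
  coef_xp <- 1 + beta * epsilon
  yfun <- function(t) {
    ((alpha + beta * J - coef_xp * x$deriv(t)) / x$fun(t) - (r0 + beta)) / k
  }
  h <- 1e-5
  yder <- function(t) (yfun(t + h) - yfun(t - h)) / (2 * h)
  w <- circ_waveform(yfun, yder, T, method = "derived",
                     label = "y(t) half-period drive")
  attr(w, "J") <- J
  attr(w, "antisymmetry_residual") <- resid
  attr(w, "antisymmetry_ok") <- ok
  w
}

#' Waveform symmetry about the peak
#'
#' Quantifies how symmetric the ascending and descending flanks of a
#' periodic waveform are: the root-mean-square of w(t_peak - s) -
#' w(t_peak + s) over s in (0, T/2\], normalized by the peak-to-trough
#' amplitude.  Zero for a waveform perfectly symmetric about its peak
#' (e.g. any pure sinusoid); larger values indicate flank asymmetry.
#'
#' @param w a [circ_waveform()] with a unique maximum and nonzero amplitude.
#' @param grid_h resolution of the offset grid in hours.
#' @return the dimensionless symmetry index (>= 0).
#' @examples
#' symmetry_index(sinusoid_waveform(3, 2, 24))   # ~0
#' @export
symmetry_index <- function(w, grid_h = 0.01) {
  assert_waveform(w)
  T <- w$period
  tp <- periodic_argmax(w$fun, T)$t
  grid <- seq(grid_h, T, by = grid_h)
  amp <- diff(range(w$fun(grid)))
  if (amp <= 1e-12 * max(abs(w$fun(grid)), 1e-300)) {
    stop("flat waveform: symmetry index undefined (zero amplitude)",
         call. = FALSE)
  }
  s <- seq(grid_h, T / 2, by = grid_h)
  d <- w$fun(tp - s) - w$fun(tp + s)
  sqrt(mean(d^2)) / amp
}
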
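test_that("feedback simulation reaches the linear-algebra fixed point", {
  # constant import and constant inhibitor: the ODEs are linear with a
  # unique fixed point solvable as a 2x2 system
  m <- feedback_model(alpha_tilde = 1.2, k1 = 0.4, k = 0.8, r1 = 0.3,
                      r2 = 0.25, period = 24)
  yconst <- 0.9
  sim <- simulate_feedback(m, yconst, horizon = 80)
  A <- rbind(c(-(m$k * yconst + m$r1), m$k1),
             c(m$k * yconst, -(m$k1 + m$r2)))
  fp <- solve(A, c(-1.2, 0))
  g <- seq(0.5, 24, by = 0.5)
  expect_lt(max(abs(sim$x_A$fun(g) - fp[1])), 1e-6)
  expect_lt(max(abs(sim$x_I$fun(g) - fp[2])), 1e-6)
  # no inhibitor: x_I empties and x_A balances import against clearance
  sim0 <- simulate_feedback(m, 0, horizon = 80)
  expect_lt(max(abs(sim0$x_I$fun(g))), 1e-6)
  expect_lt(max(abs(sim0$x_A$fun(g) - 1.2 / m$r1)), 1e-6)
  # zero drive and zero inhibitor from zero state: identically zero
  mz <- feedback_model(alpha_tilde = 0, k1 = 0.4, k = 0.8, r1 = 0.3,
                       r2 = 0.25, period = 24)
  simz <- simulate_feedback(mz, 0, horizon = 15)
  expect_lt(max(abs(simz$x_A$fun(g))), 1e-10)
})

test_that("inhibitor reconstruction inverts the forward simulation", {
  m <- feedback_model(alpha_tilde = 1.5, k1 = 0.4, k = 0.8, r1 = 0.3,
                      r2 = 0.25, period = 24)
  ydrive <- function(t) 0.6 + 0.4 * sin(2 * pi * t / 24)
  sim <- simulate_feedback(m, ydrive, horizon = 120, tol = 1e-10)
  gA <- function(t) m$k1 * sim$x_n$fun(t) + 1.5
  y <- inhibitor_from_activator(sim$x_A, gA, r0 = m$r0, k = m$k)
  g <- seq(0.5, 23.5, by = 0.5)
  expect_lt(max(abs(y$fun(g) - ydrive(g))), 1e-4)
  # constant activator and drive give a constant inhibitor
  yc <- inhibitor_from_activator(constant_rate(2), 1.4, r0 = 0.5, k = 0.8)
  expect_equal(yc$fun(c(3, 17)), rep((1.4 / 2 - 0.5) / 0.8, 2),
               tolerance = 1e-10)
  # a drive below the feasibility floor flags negative-y times
  s <- sinusoid_waveform(3, 2, 24)
  ylow <- inhibitor_from_activator(s, 1.0, r0 = 0, k = 1)  # g < g_min = 3
  expect_false(attr(ylow, "feasible"))
  expect_gt(length(attr(ylow, "infeasible_times")), 0)
})

test_that("feasibility floors match their closed forms", {
  s <- sinusoid_waveform(3, 2, 24)
  # constant drive: g_min = max x' = L
  expect_equal(feasibility_floor(s, drive_spec("constant", g = 1)), 3,
               tolerance = 1e-6)
  # beta = 0 reduces the lagged floor to the constant one
  f0 <- feasibility_floor(s, drive_spec("linear_lag", alpha = 0, beta = 0,
                                        tau = 5))
  expect_equal(as.numeric(f0), 3, tolerance = 1e-6)
  # lagged drive closed form against a fine grid search
  dr <- drive_spec("linear_lag", alpha = 0, beta = 0.5, tau = 1)
  fl <- feasibility_floor(s, dr)
  g <- seq(1e-3, 24, by = 1e-3)
  oracle <- max(max(s$deriv(g) - 0.5 * s$fun(g + 1)),
                max(-0.5 * s$fun(g)))
  expect_equal(as.numeric(fl), oracle, tolerance = 1e-3)
  expect_equal(attr(fl, "closed_form"), -0.991, tolerance = 1e-3)
  # the floor is tight: at g = g_min the implied y just touches -r0/k
  r0 <- 0.4; k <- 0.7
  y <- inhibitor_from_activator(s, 3, r0 = r0, k = k)
  ymin <- min(y$fun(seq(0.01, 24, by = 0.01)))
  expect_equal(ymin, -r0 / k, tolerance = 1e-4)
})

test_that("constant-drive phase difference matches numeric peak-finding", {
  s <- sinusoid_waveform(3, 2, 24)
  # numeric oracle at g = g_min = 3: argmax of (g - x')/x on a fine grid
  g <- 3
  grid <- seq(1e-4, 24, by = 1e-4)
  yv <- (g - s$deriv(grid)) / s$fun(grid)
  t_y_num <- grid[which.max(yv)]
  phi_num <- abs(2 * pi / 24 * (t_y_num - 12))
  ps <- phase_constant_drive(s, g)
  expect_equal(ps$phi, phi_num, tolerance = 1e-4)
  expect_equal(ps$phi, 2.981, tolerance = 1e-3)
  expect_true(ps$feasible)
  # enormous drive pushes the relationship to exact anti-phase
  expect_equal(phase_constant_drive(s, 1e6)$phi, pi, tolerance = 1e-3)
  # infeasible drives are flagged, not raised
  expect_false(phase_constant_drive(s, 2)$feasible)
})

test_that("inhibitor peak stays between hotspot and trough for constant drives", {
  s <- sinusoid_waveform(3, 2, 24)
  p <- lower_bound_profile(s)
  set.seed(21)
  for (g in 3 + stats::rexp(100, rate = 0.2)) {
    ps <- phase_constant_drive(s, g, check = FALSE)
    expect_true(in_circular_interval(ps$t_y, c(p$t_R, p$t_b), 24,
                                     tol = 1e-3))
    expect_gte(ps$phi, 0)
    expect_lte(ps$phi, pi + 1e-12)
  }
})

test_that("oscillating-drive closed form agrees with exact peak-finding", {
  s <- sinusoid_waveform(3, 2, 24)
  # beta = 0 collapses onto the constant-drive solution with g = alpha
  d0 <- drive_spec("linear_lag", alpha = 5, beta = 0, tau = 3)
  expect_equal(phase_oscillating_drive(s, d0)$phi,
               phase_constant_drive(s, 5)$phi, tolerance = 1e-9)
  # reference configuration: numeric argmax of the exact y
  dr <- drive_spec("linear_lag", alpha = 0.009, beta = 0.5, tau = 1)
  ps <- phase_oscillating_drive(s, dr, check = FALSE)
  grid <- seq(1e-3, 24, by = 1e-3)
  yv <- (dr$alpha + dr$beta * s$fun(grid + dr$tau) - s$deriv(grid)) /
    s$fun(grid)
  expect_lt(circwave:::circ_dist(ps$t_y, grid[which.max(yv)], 24), 1e-2)
  # sweep over a feasibility-respecting (alpha, beta, tau) grid
  set.seed(4)
  for (i in 1:20) {
    beta <- stats::runif(1, 0, 0.9)
    tau <- stats::runif(1, 0, 3)
    dri <- drive_spec("linear_lag", alpha = 0, beta = beta, tau = tau)
    a_min <- as.numeric(feasibility_floor(s, dri))
    alpha <- a_min + stats::rexp(1, 0.5)
    dri <- drive_spec("linear_lag", alpha = alpha, beta = beta, tau = tau)
    psi <- phase_oscillating_drive(s, dri, check = FALSE)
    yvi <- (alpha + beta * s$fun(grid + tau) - s$deriv(grid)) / s$fun(grid)
    expect_lt(circwave:::circ_dist(psi$t_y, grid[which.max(yvi)], 24),
              1e-2)
  }
  # singular configuration refused
  tau_s <- asin(2 * pi / 24 / 0.95) / (2 * pi / 24)
  expect_error(phase_oscillating_drive(
    s, drive_spec("linear_lag", alpha = 1, beta = 0.95, tau = tau_s)),
    "singular")
})

test_that("oscillating drives span near in-phase to near anti-phase", {
  s <- sinusoid_waveform(3, 2, 24)
  dr0 <- drive_spec("linear_lag", alpha = 0, beta = 0.95, tau = 1)
  a_min <- as.numeric(feasibility_floor(s, dr0))
  phis <- sapply(seq(a_min, a_min + 50, length.out = 80), function(a) {
    phase_oscillating_drive(s, drive_spec("linear_lag", alpha = a,
                                          beta = 0.95, tau = 1),
                            check = FALSE)$phi
  })
  expect_lt(min(phis), 0.2 * pi)
  expect_gt(max(phis), 0.9 * pi)
})

test_that("regime classification confines the approximate peak time", {
  s <- sinusoid_waveform(3, 2, 24)
  grid <- seq(1e-3, 24, by = 1e-3)
  # alpha > 0, beta = 0: regime 1 with the constant-drive bounds
  p <- lower_bound_profile(s)
  c1 <- classify_ty_regime(s, drive_spec("linear_lag", alpha = 4, beta = 0,
                                         tau = 0.5))
  expect_equal(c1$regime, 1L)
  expect_equal(c1$bounds[1], p$t_R, tolerance = 1e-3)
  expect_lt(circwave:::circ_dist(c1$bounds[2], p$t_b, 24), 1e-3)
  # all four sign cases: the peak of the small-lag approximation of y
  # falls inside the declared interval
  cases <- list(list(alpha = 4, beta = 0.4, tau = 0.5),    # beta*tau < 1
                list(alpha = 4, beta = 2.0, tau = 1.0),    # beta*tau > 1
                list(alpha = -4, beta = 0.4, tau = 0.5),
                list(alpha = -4, beta = 2.0, tau = 1.0))
  for (cs in cases) {
    dr <- drive_spec("linear_lag", alpha = cs$alpha, beta = cs$beta,
                     tau = cs$tau)
    cls <- classify_ty_regime(s, dr)
    yv <- (cs$alpha - (1 - cs$beta * cs$tau) * s$deriv(grid)) / s$fun(grid)
    t_y <- grid[which.max(yv)]
    expect_true(in_circular_interval(t_y, cls$bounds, 24, tol = 0.05),
                info = sprintf("regime %d", cls$regime))
  }
  # boundary cases are reported, not classified
  expect_true(is.na(classify_ty_regime(
    s, drive_spec("linear_lag", alpha = 0, beta = 0.4, tau = 0.5))$regime))
})

test_that("half-period-lag drives behave per the antisymmetry reduction", {
  s <- sinusoid_waveform(3, 2, 24)
  # a pure sinusoid satisfies x(t + T/2) = J - x(t) exactly, J = 2<x>
  y0 <- half_period_drive(s, epsilon = 0, alpha = 4, beta = 0, r0 = 0.4,
                          k = 0.7)
  expect_equal(attr(y0, "J"), 2 * time_average(s), tolerance = 1e-6)
  expect_lt(attr(y0, "antisymmetry_residual"), 1e-8)
  # epsilon = 0, beta = 0 reduces to the constant drive with g = alpha
  ycon <- inhibitor_from_activator(s, 4, r0 = 0.4, k = 0.7)
  g <- seq(0.5, 23.5, by = 0.5)
  expect_equal(y0$fun(g), ycon$fun(g), tolerance = 1e-9)
  # beta*epsilon = -1 kills the x' term: y becomes symmetric about its peak
  ysym <- half_period_drive(s, epsilon = -2, alpha = 4, beta = 0.5,
                            r0 = 0.4, k = 0.7)
  expect_lt(symmetry_index(ysym), 1e-6)
  expect_gt(symmetry_index(y0), 0.01)
  # a strongly asymmetric waveform triggers the approximation warning
  skewed <- waveform_primitive(list(type = "truncated_sinusoid", base = 0.3,
                                    amplitude = 1, peak_t = 8), 24)
  expect_warning(half_period_drive(skewed, 0, 4, 0.5, 0.4, 0.7),
                 "antisymmetry")
})

test_that("the symmetry index separates symmetric from skewed waveforms", {
  expect_lt(symmetry_index(sinusoid_waveform(3, 2, 24)), 1e-9)
  # sawtooth-like skewed bump: ascending flank much longer than descending
  saw <- fit_periodic_waveform(circ_series(
    c(4, 8, 12, 16, 18, 20, 24), c(0.3, 0.55, 0.8, 1.0, 0.4, 0.2, 0.15),
    24))
  expect_gt(symmetry_index(saw), 0.1)
  # increasing constant drive makes the implied inhibitor ever more
  # symmetric (the x' term becomes negligible)
  s <- sinusoid_waveform(3, 2, 24)
  idx <- sapply(c(3.5, 6, 12, 30, 100), function(g) {
    symmetry_index(inhibitor_from_activator(s, g, r0 = 0.4, k = 0.7))
  })
  expect_true(all(diff(idx) < 0))
  expect_error(symmetry_index(constant_rate(2)), "flat")
})
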
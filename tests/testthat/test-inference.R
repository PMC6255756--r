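test_that("chase decay fitting recovers exponential rates", {
  d <- data.frame(time_h = 0:7, value = exp(-0.45 * (0:7)))
  fit <- fit_decay_rate(d, fit_from_h = 1)
  expect_equal(fit$r, 0.45, tolerance = 1e-10)
  expect_equal(fit$sd, 0)
  # constant series decays at rate zero
  expect_equal(fit_decay_rate(data.frame(time_h = 0:4,
                                         value = rep(2, 5)))$r, 0,
               tolerance = 1e-12)
  expect_error(fit_decay_rate(data.frame(time_h = 0:4,
                                         value = c(1, 1, 0, 1, 1))),
               "positive")
  expect_error(fit_decay_rate(d, fit_from_h = 7), "at least 2")
})

test_that("replicate-level decay sd matches independent per-replicate fits", {
  set.seed(11)
  tt <- c(0, 1, 3, 5, 7)
  reps <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(replicate = i, time_h = tt,
               value = exp(-(0.4 + 0.05 * i) * tt) *
                 exp(stats::rnorm(length(tt), 0, 0.05)))
  }))
  fit <- fit_decay_rate(reps, fit_from_h = 1)
  # oracle: refit each replicate independently
  slopes <- sapply(split(reps, reps$replicate), function(dd) {
    dd <- dd[dd$time_h >= 1, ]
    -unname(coef(stats::lm(log(value) ~ time_h, dd))[2])
  })
  expect_equal(fit$r, mean(slopes), tolerance = 1e-12)
  expect_equal(fit$sd, stats::sd(slopes), tolerance = 1e-12)
})

test_that("translation-constant estimation averages per-anchor values", {
  # noiseless forward-simulated scenario: k recovered from true waveforms
  sc <- smooth_recovery_scenario(seed = 3)
  at <- c(4, 12, 18)
  anchors <- data.frame(t = at, r = sc$r_true$fun(at))
  tm <- estimate_translation_constant(sc$x_true, sc$g_m, anchors)
  expect_equal(tm$k, 0.7, tolerance = 1e-3)
  # a single anchor returns its own k_i; two constructed anchors average
  xw <- constant_rate(2)           # constant x = 2
  gw <- constant_rate(1)           # constant g_m = 1
  # k_i = r_i * x / g_m = 2 r_i: choose rates giving k_i = 0.5 and 1.5
  two <- data.frame(t = c(6, 18), r = c(0.25, 0.75))
  tm2 <- estimate_translation_constant(xw, gw, two)
  expect_equal(unname(tm2$k_i), c(0.5, 1.5))
  expect_equal(tm2$k, 1.0)
  tm1 <- estimate_translation_constant(xw, gw, two[1, ])
  expect_equal(tm1$k, 0.5)
  gz <- constant_rate(0)
  expect_error(estimate_translation_constant(xw, gz, two), "not positive")
})

test_that("rate-curve reconstruction inverts the synthesis balance", {
  # constant profiles: r = k g_m / x everywhere
  xw <- constant_rate(2); gw <- constant_rate(1)
  tm <- estimate_translation_constant(xw, gw, data.frame(t = 6, r = 0.35))
  cv <- infer_rate_curve(xw, gw, tm, NULL, grid_h = 2)
  expect_equal(cv$r, rep(0.35, 12), tolerance = 1e-12)
  expect_true(all(cv$provenance == "inferred"))
  # noiseless smooth scenario: sub-1% sup-norm recovery of r_true and k
  sc <- smooth_recovery_scenario(seed = 5)
  d <- sample_dataset(sc)
  xs <- fit_periodic_waveform(d$x); gs <- fit_periodic_waveform(d$g_m)
  tmn <- estimate_translation_constant(xs, gs, d$anchors)
  cvn <- infer_rate_curve(xs, gs, tmn, d$anchors, grid_h = 2)
  rep <- recovery_report(sc, cvn, tm = tmn)
  expect_lt(rep$r_sup_rel, 0.01)
  expect_lt(rep$k_rel_error, 0.01)
  # anchor overrides carry the measured values exactly
  i <- match(d$anchors$t, cvn$times)
  expect_equal(cvn$r[i], d$anchors$r)
  expect_true(all(cvn$provenance[i] == "anchor"))
})

test_that("caps and floors clamp only non-anchor points and are idempotent", {
  grid <- seq(2, 24, by = 2)
  r <- c(0.4, 0.3, 0.2, 0.1, 0.25, 0.5, 0.9, 1.4, 2.4, 1.0, 0.6, 0.45)
  cv <- circwave:::new_rate_curve(grid, r, rep("inferred", 12), 24,
                                  anchors = data.frame(t = 8, r = 0.2,
                                                       sd = NA))
  cv$provenance[4] <- "anchor"
  # curve already within bounds: unchanged
  same <- apply_bounds(cv, cap = 5, floor = 0)
  expect_equal(same$r, cv$r)
  # PRR5-style cap at r_min = 1.69 pulls the 2.4 point down
  capped <- apply_bounds(cv, cap = list(rule = "r_min", value = 1.69),
                         floor = NULL)
  expect_equal(capped$r[9], 1.69)
  expect_equal(capped$provenance[9], "capped_high")
  # floor from the minimum anchor lifts the 0.1 point, but anchors stay
  floored <- apply_bounds(cv, cap = NULL, floor = list(rule = "min_anchor"))
  expect_equal(min(floored$r[-4]), 0.2)
  expect_equal(floored$r[4], 0.1)  # anchor value preserved
  # idempotence
  again <- apply_bounds(capped, cap = list(rule = "r_min", value = 1.69),
                        floor = NULL)
  expect_equal(again$r, capped$r)
  expect_error(apply_bounds(cv, cap = 0.1, floor = 0.5), "below floor")
  # window_max rule caps at the curve's own late-night maximum
  wcap <- apply_bounds(cv, cap = list(rule = "window_max",
                                      window = c(20, 22)))
  expect_equal(wcap$config$cap, max(r[10:11]))
})

test_that("artifact-window correction replaces points by the anchor line", {
  grid <- seq(2, 24, by = 2)
  cv <- circwave:::new_rate_curve(grid, rep(1, 12), rep("inferred", 12), 24)
  a2 <- data.frame(t = c(4, 12), r = c(0.3, 0.5))
  out <- correct_window(cv, c(2, 10), a2)
  # two-point line: r(2) = 0.25, r(10) = 0.45
  expect_equal(out$r[grid == 2], 0.25)
  expect_equal(out$r[grid == 10], 0.45)
  expect_true(all(out$provenance[grid >= 2 & grid <= 10] ==
                    "corrected_window"))
  expect_equal(out$r[grid == 12], 1)
  # single anchor: constant extrapolation
  out1 <- correct_window(cv, c(6, 10), data.frame(t = 12, r = 0.4))
  expect_equal(out1$r[grid %in% c(6, 8, 10)], rep(0.4, 3))
  # window with no grid points, and empty window: identity
  expect_equal(correct_window(cv, c(2.5, 3.5), a2)$r, cv$r)
  expect_identical(correct_window(cv, NULL, a2), cv)
  # idempotence
  expect_equal(correct_window(out, c(2, 10), a2)$r, out$r)
})

test_that("sinusoidal translation model is recovered from anchors", {
  T <- 24
  a <- 0.3; b <- 0.8; phi <- 0.6
  ktrue <- function(t) a * sin(2 * pi * t / T - phi) + b
  # build anchors whose per-anchor k_i equal k(t_i):
  # with x = const 2, g_m = const 1, k_i = 2 r_i, so r_i = k(t_i)/2
  xw <- constant_rate(2); gw <- constant_rate(1)
  at <- c(2, 7, 13, 19, 23)
  anchors <- data.frame(t = at, r = ktrue(at) / 2)
  tm <- fit_sinusoidal_translation(xw, gw, anchors)
  expect_equal(tm$a, a, tolerance = 0.01)
  expect_equal(tm$b, b, tolerance = 0.01)
  expect_equal(tm$phi, phi, tolerance = 0.01)
  expect_equal(tm$eps_k, min(ktrue(at)), tolerance = 1e-12)
  # degenerate a = 0 reduces to the constant model with k = b
  flat <- data.frame(t = at, r = rep(b / 2, 5))
  tmf <- fit_sinusoidal_translation(xw, gw, flat)
  expect_equal(tmf$a, 0, tolerance = 1e-8)
  expect_equal(tmf$b, b, tolerance = 1e-8)
  expect_equal(translation_rate(tmf, c(3, 9, 21), period = T),
               rep(b, 3), tolerance = 1e-6)
  # two anchors: per-phase 2x2 solve matches brute-force least squares
  two <- anchors[c(1, 3), ]
  fam <- fit_sinusoidal_translation(xw, gw, two,
                                    phi_grid = c(0.2, 0.6, 1.0))
  expect_s3_class(fam, "translation_family")
  for (m in fam) {
    th <- 2 * pi * two$t / T
    X <- cbind(sin(th - m$phi), 1)
    cf <- drop(qr.solve(X, 2 * two$r))   # exact two-point solve
    expect_equal(m$a, cf[1], tolerance = 1e-8)
    expect_equal(m$b, cf[2], tolerance = 1e-8)
  }
})

test_that("anchors-only reconstruction never violates the waveform bound", {
  x <- normalize_to_spline_peak(read_series(fixture("per2_protein_synthetic.csv")))
  xw <- fit_periodic_waveform(x)
  p <- lower_bound_profile(xw, smooth_window_h = 1)
  a <- read_anchors(fixture("per2_anchors_synthetic.csv"))
  cv <- infer_from_anchors_only(xw, a, grid_h = 0.5, profile = p)
  expect_true(all(cv$r >= p$R_fun(cv$times) - 1e-9))
  # anchors all far above R: pure periodic linear interpolation
  hi <- data.frame(t = c(6, 14, 20), r = c(2, 3, 2.5))
  cv_hi <- infer_from_anchors_only(xw, hi, grid_h = 0.5, profile = p)
  interp <- fit_periodic_waveform(
    circ_series(hi$t, hi$r, xw$period), method = "linear")
  expect_equal(cv_hi$r, interp$fun(cv_hi$times), tolerance = 1e-9)
  # a segment dipping below R near the hotspot is lifted onto R
  low <- data.frame(t = c(10, 20), r = c(0.05, 0.05))
  cv_low <- infer_from_anchors_only(xw, low, grid_h = 0.5, profile = p)
  lifted <- cv_low$provenance == "floored_low"
  expect_true(any(lifted))
  expect_equal(cv_low$r[lifted], p$R_fun(cv_low$times)[lifted],
               tolerance = 1e-9)
  expect_error(infer_from_anchors_only(xw, low[1, ]), "two anchors")
  # downstream cost of the packaged PER2-like case sits near 0.11 per h
  cost <- production_cost(xw, rate_curve_waveform(cv), profile = p)
  expect_equal(cost$c, 0.11, tolerance = 0.2 * 0.11)
})

test_that("reconstruction conserves synthesis and turnover on average", {
  # <k g_m> = <r x> for uncorrected curves (periodic balance)
  for (seed in c(2, 9)) {
    sc <- smooth_recovery_scenario(seed = seed)
    d <- sample_dataset(sc)
    xw <- fit_periodic_waveform(d$x); gw <- fit_periodic_waveform(d$g_m)
    tm <- estimate_translation_constant(xw, gw, d$anchors)
    cv <- infer_rate_curve(xw, gw, tm, d$anchors, grid_h = 2)
    lhs <- tm$k * time_average(gw)
    rw <- rate_curve_waveform(cv)
    rhs <- time_average(function(t) rw$fun(t) * xw$fun(t), period = 24)
    expect_equal(lhs, rhs, tolerance = 0.05)
  }
})

test_that("noisy sampling degrades recovery gracefully and reproducibly", {
  # 5% multiplicative noise, 2-h sampling, 50 seeded replicates: spline
  # differentiation amplifies noise, so pointwise errors concentrate near
  # the median but carry a heavier tail (see the methods vignette)
  sc <- smooth_recovery_scenario(seed = 1, noise_cv = 0.05)
  errs <- c()
  for (s in 1:50) {
    scs <- sc
    scs$seed <- 1000L + s
    d <- sample_dataset(scs)
    xw <- fit_periodic_waveform(d$x); gw <- fit_periodic_waveform(d$g_m)
    tm <- estimate_translation_constant(xw, gw, d$anchors)
    cv <- infer_rate_curve(xw, gw, tm, d$anchors, grid_h = 2)
    errs <- c(errs, abs(cv$r - scs$r_true$fun(cv$times)) /
                max(scs$r_true$fun(cv$times)))
  }
  expect_lt(stats::median(errs), 0.10)
  expect_gte(mean(errs <= 0.25), 0.90)
})
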
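# shared constructors for generated test inputs

# sample the analytic reference sinusoid on a grid
sinusoid_series <- function(L = 3, h0 = 2, period = 24, by = 2) {
  w <- sinusoid_waveform(L, h0, period)
  t <- seq(by, period, by = by)
  circ_series(t, w$fun(t), period, label = "sinusoid")
}

# constant degradation-rate waveform
constant_rate <- function(r, period = 24) {
  circ_waveform(function(t) rep(r, length(t)),
                function(t) rep(0, length(t)), period)
}

# random smooth strictly positive periodic waveform (low-order Fourier)
random_positive_waveform <- function(period = 24, n_harm = 2,
                                     min_level = 0.2) {
  a <- stats::rnorm(n_harm, sd = 1 / seq_len(n_harm))
  b <- stats::rnorm(n_harm, sd = 1 / seq_len(n_harm))
  om <- 2 * pi / period
  raw <- function(t) {
    out <- numeric(length(t))
    for (j in seq_len(n_harm)) {
      out <- out + a[j] * cos(j * om * t) + b[j] * sin(j * om * t)
    }
    out
  }
  draw <- function(t) {
    out <- numeric(length(t))
    for (j in seq_len(n_harm)) {
      out <- out - a[j] * j * om * sin(j * om * t) +
        b[j] * j * om * cos(j * om * t)
    }
    out
  }
  grid <- seq(0.01, period, by = 0.01)
  lift <- min_level - min(raw(grid))
  circ_waveform(function(t) raw(t) + lift, draw, period)
}

# smooth gently varying scenario for round-trip recovery checks
smooth_recovery_scenario <- function(seed = 1, noise_cv = 0) {
  make_scenario(
    g_m = list(type = "sinusoid", mean = 0.6, amplitude = 0.45, peak_t = 8),
    r_true = list(type = "sinusoid", mean = 0.35, amplitude = 0.2,
                  peak_t = 20),
    k = 0.7, seed = seed, noise_cv = noise_cv, sampling_interval_h = 2)
}

fixture <- function(name) circwave_example(name)
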
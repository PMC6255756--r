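#' Read and write periodic time-series CSV files
#'
#' The on-disk dialect is a plain CSV with one comment header line carrying
#' the metadata, e.g.
#' ```
#' # period_h=24 label=PRR7_protein units=normalized
#' time_h,value
#' 2,0.08
#' ```
#' Times are folded into (0, T] on read (a row at t = 0 is the same periodic
#' point as t = T; if both are present they must agree and are merged).
#'
#' @param path file path.
#' @return `read_series()` returns a [circ_series()]; `write_series()`
#'   returns `path` invisibly.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "#")) {
    stop("missing '# period_h=...' header line in ", path, call. = FALSE)
  }
  meta <- parse_meta(lines[1L])
  if (is.null(meta$period_h)) {
    stop("header lacks period_h in ", path, call. = FALSE)
  }
  T <- as.numeric(meta$period_h)
  body <- lines[-1L]
  if (!grepl("^\\s*time_h\\s*,\\s*value", body[1L])) {
    stop("expected 'time_h,value' column header in ", path, call. = FALSE)
  }
  rows <- body[-1L]
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(rows, ",", fixed = TRUE)
  tv <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L) {
      stop(sprintf("malformed row %d in %s", i + 2L, path), call. = FALSE)
    }
    out <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(out))) {
      stop(sprintf("non-numeric cell in row %d of %s", i + 2L, path),
           call. = FALSE)
    }
    out
  }, numeric(2))
  t <- fold_time(tv[1L, ], T)
  v <- tv[2L, ]
  # merge a duplicated periodic endpoint (t = 0 alias of t = T)
  if (anyDuplicated(t)) {
    keep <- !logical(length(t))
    for (d in unique(t[duplicated(t)])) {
      i <- which(t == d)
      if (max(v[i]) - min(v[i]) > 1e-9 * max(abs(v[i]), 1)) {
        stop(sprintf(
          "conflicting duplicate samples at periodic time %g h in %s",
          d, path), call. = FALSE)
      }
      keep[i[-1L]] <- FALSE
    }
    t <- t[keep]; v <- v[keep]
  }
  circ_series(t, v, T,
              label = if (is.null(meta$label)) "" else meta$label,
              light_regime = meta$light_regime)
}

parse_meta <- function(line) {
  line <- sub("^#\\s*", "", line)
  kv <- regmatches(line, gregexpr("[A-Za-z_]+=[^ ]+", line))[[1L]]
  out <- list()
  for (item in kv) {
    p <- strsplit(item, "=", fixed = TRUE)[[1L]]
    out[[p[1L]]] <- p[2L]
  }
  out
}

#' @rdname read_series
#' @param series a [circ_series()] to write.
#' @param units free-text units recorded in the header.
#' @export
write_series <- function(series, path, units = "normalized") {
  assert_series(series)
  hdr <- sprintf("# period_h=%.15g label=%s units=%s",
                 series$period,
                 if (nzchar(series$label)) gsub("\\s+", "_", series$label)
                 else "series", units)
  if (!is.null(series$light_regime)) {
    hdr <- paste0(hdr, " light_regime=", series$light_regime)
  }
  rows <- sprintf("%.15g,%.15g", series$times, series$values)
  writeLines(c(hdr, "time_h,value", rows), path)
  invisible(path)
}

#' Read degradation-rate anchors from CSV
#'
#' Expected columns: `time_h`, `rate_per_h`, optional `sd_per_h`, `source`.
#'
#' @param path file path.
#' @return data frame with columns `t`, `r`, `sd`, `source`.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_h", "rate_per_h") %in% names(d))) {
    stop("anchor file needs time_h and rate_per_h columns", call. = FALSE)
  }
  data.frame(t = d$time_h, r = d$rate_per_h,
             sd = if ("sd_per_h" %in% names(d)) d$sd_per_h else NA_real_,
             source = if ("source" %in% names(d)) d$source else "")
}

#' Path to a packaged example dataset
#'
#' The packaged profiles are *synthetic stand-ins*: constructed waveforms
#' emulating published clock-protein profiles (shape, sampling regime and
#' summary statistics), not digitized source data.  See the package vignette
#' for how they were built.
#'
#' @param name file name, e.g. `"prr7_protein_synthetic.csv"`; `NULL` lists
#'   all packaged files.
#' @return a file path, or a character vector of available names.
#' @export
circwave_example <- function(name = NULL) {
  dir <- system.file("extdata", package = "circwave")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("no packaged file '", name, "'; see circwave_example()",
         call. = FALSE)
  }
  path
}

#' Run the full waveform-to-cost pipeline
#'
#' Orchestrates the standard analysis sequence for one protein: read (or
#' accept) the protein profile, mRNA profile and rate anchors; peak-
#' normalize; optionally smooth trough points; compute R(t), r_min and the
#' hotspot; estimate the translation constant; reconstruct r(t); apply cap,
#' floor and artifact-window rules; and compute the cost summary, including
#' the anchor-sd sensitivity interval on the cost reduction when an anchor
#' carries a standard deviation.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `x`, `g_m` (paths or [circ_series()]), `anchors` (path or data frame);
#'   optional `trough_smoothing` (list with `target_times`, `source_time`),
#'   `R_smooth_window_h`, `k_mode` (`"constant"` or `"sinusoidal"`),
#'   `grid_h` (default 2), `cap` / `floor` rules as in [apply_bounds()],
#'   `artifact_window` (+ `artifact_anchor_times`, the anchor times defining
#'   the correction line), `out_dir` to write reports.
#' @return a `pipeline_report`: list with `series`, `profile`, `tm`,
#'   `curve_raw`, `curve` (bounded/corrected), `cost`, `anchor_check`,
#'   `cost_reduction_interval` (if anchor sds present), `log` (character
#'   vector of applied rules), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  get_series <- function(obj, what) {
    if (is_circ_series(obj)) return(obj)
    if (is.character(obj)) return(read_series(obj))
    stop("config$", what, " must be a circ_series or a file path",
         call. = FALSE)
  }
  xs <- get_series(config$x, "x")
  say("loaded protein series '%s' (%d samples, T = %g h)", xs$label,
      length(xs$times), xs$period)
  anchors <- config$anchors
  if (is.character(anchors)) anchors <- read_anchors(anchors)
  if (!is.null(anchors)) anchors <- as_anchor_frame(anchors)
  if (!is.null(config$trough_smoothing)) {
    ts <- config$trough_smoothing
    xs <- smooth_trough_points(xs, ts$target_times, ts$source_time)
    say("trough smoothing: x at t = {%s} h replaced by x(%g h)",
        paste(ts$target_times, collapse = ", "), ts$source_time)
  }
  xs <- normalize_to_spline_peak(xs)
  say("peak-normalized protein series")
  xw <- fit_periodic_waveform(xs, method = "spline")
  profile <- lower_bound_profile(xw, smooth_window_h = config$R_smooth_window_h)
  say("R(t): r_min = %.4g 1/h at t_R = %.2f h%s", profile$r_min,
      profile$t_R,
      if (is.null(config$R_smooth_window_h)) "" else
        sprintf(" (R smoothed, %g-h window)", config$R_smooth_window_h))
  anchor_check <- if (!is.null(anchors)) {
    validate_anchors(profile, anchors)
  } else NULL
  if (!is.null(anchor_check)) {
    say("anchor check: %d/%d measured rates satisfy r >= R",
        sum(anchor_check$pass), nrow(anchor_check))
  }
  grid_h <- if (is.null(config$grid_h)) 2 else config$grid_h
  # an "r_min" cap without an explicit value caps at the waveform's own r_min
  if (is.list(config$cap) && identical(config$cap$rule, "r_min") &&
      (is.null(config$cap$value) || is.na(config$cap$value))) {
    config$cap$value <- profile$r_min
  }
  if (!is.null(config$g_m)) {
    gs <- normalize_to_spline_peak(get_series(config$g_m, "g_m"))
    gw <- fit_periodic_waveform(gs, method = "spline")
    k_mode <- if (is.null(config$k_mode)) "constant" else config$k_mode
    tm <- if (k_mode == "sinusoidal") {
      fit_sinusoidal_translation(xw, gw, anchors,
                                 phi_grid = config$phi_grid)
    } else {
      estimate_translation_constant(xw, gw, anchors)
    }
    if (inherits(tm, "translation_family")) {
      stop("sinusoidal k underdetermined: pick one phase from the family",
           call. = FALSE)
    }
    say("translation model: %s", if (tm$mode == "constant")
      sprintf("constant k = %.4g", tm$k) else "sinusoidal k(t)")
    curve_raw <- infer_rate_curve(xw, gw, tm, anchors, grid_h = grid_h)
  } else {
    tm <- NULL
    say("no mRNA profile: anchors-only reconstruction")
    curve_raw <- infer_from_anchors_only(xw, anchors, grid_h = grid_h,
                                         profile = profile)
  }
  curve <- curve_raw
  if (!is.null(config$cap) || !is.null(config$floor)) {
    curve <- apply_bounds(curve, cap = config$cap, floor = config$floor)
    say("bounds applied: cap = %s, floor = %s",
        fmt_rule(curve$config$cap), fmt_rule(curve$config$floor))
  }
  if (!is.null(config$artifact_window)) {
    at <- config$artifact_anchor_times
    line_anchors <- anchors[fold_time(anchors$t, xs$period) %in%
                              fold_time(at, xs$period), , drop = FALSE]
    curve <- correct_window(curve, config$artifact_window, line_anchors)
    say("artifact window [%g, %g] h corrected via anchors at t = {%s} h",
        config$artifact_window[1L], config$artifact_window[2L],
        paste(at, collapse = ", "))
  }
  cost <- production_cost(xw, rate_curve_waveform(curve), profile = profile)
  say("cost: c = %.4g, c_g = %.4g, reduction = %.3f", cost$c, cost$c_g,
      cost$cost_reduction)
  interval <- cost_reduction_interval(xw, gw_if(config, tm), tm, anchors,
                                      config, profile, grid_h)
  if (!is.null(interval)) {
    say("anchor-sd sensitivity: cost reduction in [%.3f, %.3f]",
        interval[1L], interval[2L])
  }
  report <- structure(
    list(series = xs, profile = profile, tm = tm, curve_raw = curve_raw,
         curve = curve, cost = cost, anchor_check = anchor_check,
         cost_reduction_interval = interval, log = log, config = config),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

gw_if <- function(config, tm) {
  if (is.null(config$g_m) || is.null(tm)) return(NULL)
  gs <- if (is_circ_series(config$g_m)) config$g_m else
    read_series(config$g_m)
  fit_periodic_waveform(normalize_to_spline_peak(gs), method = "spline")
}

fmt_rule <- function(x) {
  if (is.null(x)) "none" else sprintf("%.4g", x)
}

# rerun the reconstruction with each sd-bearing anchor at r +/- sd and
# report the spanned cost-reduction interval
cost_reduction_interval <- function(xw, gw, tm, anchors, config, profile,
                                    grid_h) {
  if (is.null(anchors) || is.null(gw) || is.null(tm) ||
      !any(is.finite(anchors$sd) & anchors$sd > 0)) {
    return(NULL)
  }
  reductions <- c()
  for (i in which(is.finite(anchors$sd) & anchors$sd > 0)) {
    for (s in c(-1, 1)) {
      a2 <- anchors
      a2$r[i] <- max(a2$r[i] + s * a2$sd[i], 0)
      tm2 <- estimate_translation_constant(xw, gw, a2)
      cv <- infer_rate_curve(xw, gw, tm2, a2, grid_h = grid_h)
      if (!is.null(config$cap) || !is.null(config$floor)) {
        cv <- apply_bounds(cv, cap = config$cap, floor = config$floor)
      }
      if (!is.null(config$artifact_window)) {
        at <- config$artifact_anchor_times
        la <- a2[fold_time(a2$t, xw$period) %in%
                   fold_time(at, xw$period), , drop = FALSE]
        cv <- correct_window(cv, config$artifact_window, la)
      }
      reductions <- c(reductions,
                      production_cost(xw, rate_curve_waveform(cv),
                                      profile = profile)$cost_reduction)
    }
  }
  range(reductions)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cost <- report$cost
  payload <- list(
    package_version = as.character(utils::packageVersion("circwave")),
    r_min = cost$r_min, t_R = report$profile$t_R,
    t_a = report$profile$t_a, t_b = report$profile$t_b,
    c = cost$c, c_g = cost$c_g, cost_reduction = cost$cost_reduction,
    half_life_bound_min = cost$half_life_bound_min,
    fold_excess = cost$fold_excess,
    cost_reduction_interval = report$cost_reduction_interval,
    log = report$log
  )
  if (!is.null(report$anchor_check)) {
    payload$anchors <- lapply(seq_len(nrow(report$anchor_check)), function(i) {
      as.list(report$anchor_check[i, c("t", "r", "R", "margin", "pass")])
    })
  }
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  curve_df <- data.frame(time_h = report$curve$times,
                         rate_per_h = report$curve$r,
                         provenance = report$curve$provenance)
  utils::write.csv(curve_df, file.path(out_dir, "rate_curve.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Sweep phase differences over a drive-parameter grid
#'
#' Evaluates [phase_constant_drive()] (constant mode, sweeping `g`) or
#' [phase_oscillating_drive()] (linear-lag mode, sweeping `alpha`) across a
#' parameter grid for a sinusoidal activator waveform, flagging infeasible
#' rows rather than dropping them.
#'
#' @param s a [sinusoid_waveform()].
#' @param g values of the constant drive to sweep (constant mode), or `NULL`.
#' @param alpha values of alpha to sweep (linear-lag mode), or `NULL`.
#' @param beta,tau linear-lag parameters (scalars or vectors crossed with
#'   `alpha`).
#' @return data frame with columns `mode`, `g`/`alpha`, `beta`, `tau`,
#'   `phi_rad`, `t_y_h`, `feasible`.
#' @export
phase_sweep <- function(s, g = NULL, alpha = NULL, beta = 0, tau = 0) {
  stopifnot(inherits(s, "sinusoid_waveform"))
  rows <- list()
  if (!is.null(g)) {
    for (gg in g) {
      ps <- phase_constant_drive(s, gg, check = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = "constant", g = gg, alpha = NA_real_, beta = NA_real_,
        tau = NA_real_, phi_rad = ps$phi, t_y_h = ps$t_y,
        feasible = ps$feasible)
    }
  }
  if (!is.null(alpha)) {
    grid <- expand.grid(alpha = alpha, beta = beta, tau = tau)
    for (i in seq_len(nrow(grid))) {
      dr <- drive_spec("linear_lag", alpha = grid$alpha[i],
                       beta = grid$beta[i], tau = grid$tau[i])
      ps <- phase_oscillating_drive(s, dr, check = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = "linear_lag", g = NA_real_, alpha = grid$alpha[i],
        beta = grid$beta[i], tau = grid$tau[i], phi_rad = ps$phi,
        t_y_h = ps$t_y, feasible = ps$feasible)
    }
  }
  do.call(rbind, rows)
}
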
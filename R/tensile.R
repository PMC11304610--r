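#' Specimen geometry
#'
#' Gauge-region geometry of a tensile specimen. The thickness is the average
#' of exactly five measurements taken in the stretching area; the initial
#' cross-section A0 is width x mean thickness.
#'
#' @param width_mm specimen width (mm).
#' @param thickness_measurements_mm exactly five thickness readings (mm).
#' @param gauge_length_mm clamp separation at preload (mm).
#' @return A `specimen_geometry` object.
#' @export
specimen_geometry <- function(width_mm, thickness_measurements_mm, gauge_length_mm) {
  if (length(thickness_measurements_mm) != 5) {
    stop("exactly five thickness measurements are required", call. = FALSE)
  }
  thickness <- mean(thickness_measurements_mm)
  if (width_mm <= 0 || thickness <= 0 || gauge_length_mm <= 0) {
    stop("specimen dimensions must be positive", call. = FALSE)
  }
  structure(list(width_mm = width_mm,
                 thickness_measurements_mm = as.numeric(thickness_measurements_mm),
                 thickness_mm = thickness,
                 gauge_length_mm = gauge_length_mm,
                 area_mm2 = width_mm * thickness),
            class = "specimen_geometry")
}

#' Tensile record
#'
#' One uniaxial test: time (s, uniform 100 Hz unless stated), load (N) and
#' clamp displacement (mm), plus the specimen geometry and protocol.
#'
#' @param time_s,load_N,displacement_mm equal-length channels.
#' @param geometry a [specimen_geometry()].
#' @param model_id,sample_id labels.
#' @param protocol list of protocol settings (strain rate etc.).
#' @param sampling_hz nominal sampling rate; deviations beyond 1e-6 s in the
#'   median interval trigger resampling with a warning.
#' @return A `tensile_record`.
#' @export
tensile_record <- function(time_s, load_N, displacement_mm, geometry,
                           model_id = "sample", sample_id = "s1",
                           protocol = list(strain_rate_mm_min = 10,
                                           preload_mpa = 0.02,
                                           conditioning_cycles = 3),
                           sampling_hz = 100) {
  n <- length(time_s)
  if (length(load_N) != n || length(displacement_mm) != n) {
    stop("all channels must have equal length", call. = FALSE)
  }
  if (n >= 2) {
    if (any(diff(time_s) <= 0)) stop("time must be strictly increasing", call. = FALSE)
    dt <- stats::median(diff(time_s))
    if (abs(dt - 1 / sampling_hz) > 1e-6) {
      warning(sprintf("sampling interval %.6f s differs from %g Hz; resampling",
                      dt, sampling_hz), call. = FALSE)
      grid <- seq(time_s[1], time_s[n], by = 1 / sampling_hz)
      load_N <- stats::approx(time_s, load_N, grid)$y
      displacement_mm <- stats::approx(time_s, displacement_mm, grid)$y
      time_s <- grid
    }
  }
  stopifnot(inherits(geometry, "specimen_geometry"))
  structure(list(data = tibble::tibble(time_s = as.numeric(time_s),
                                       load_N = as.numeric(load_N),
                                       displacement_mm = as.numeric(displacement_mm)),
                 geometry = geometry, model_id = model_id, sample_id = sample_id,
                 protocol = protocol, sampling_hz = sampling_hz),
            class = "tensile_record")
}

#' @export
print.tensile_record <- function(x, ...) {
  cat(sprintf("<tensile_record> %s/%s: %d samples @ %g Hz, A0 = %.3f mm^2\n",
              x$model_id, x$sample_id, nrow(x$data), x$sampling_hz,
              x$geometry$area_mm2))
  invisible(x)
}

#' Engineering stress-strain curve
#'
#' sigma_E = load / A0 (MPa, with N and mm^2) and eps_E = clamp displacement
#' / gauge length (dimensionless). The pre-test conditioning cycles are
#' excluded by trimming the record to its final monotone loading ramp: the
#' curve starts at the last sample at (or below) zero displacement.
#'
#' @param record a [tensile_record()].
#' @param trim_conditioning drop everything before the final monotone ramp?
#' @return A tibble of class `stress_strain_curve` with columns `time_s`,
#'   `strain`, `stress_mpa` and attributes `model_id`, `sample_id`,
#'   `duration_s`.
#' @export
compute_stress_strain <- function(record, trim_conditioning = TRUE) {
  g <- record$geometry
  if (g$area_mm2 <= 0) stop("zero cross-section area", call. = FALSE)
  d <- record$data
  if (trim_conditioning && nrow(d) > 1) {
    tol <- 1e-9 + 1e-6 * max(abs(d$displacement_mm))
    at_zero <- which(d$displacement_mm <= tol)
    start <- if (length(at_zero)) max(at_zero) else 1L
    d <- d[start:nrow(d), , drop = FALSE]
  }
  out <- tibble::tibble(
    time_s = d$time_s - d$time_s[1],
    strain = d$displacement_mm / g$gauge_length_mm,
    stress_mpa = d$load_N / g$area_mm2
  )
  structure(tibble::new_tibble(out, class = "stress_strain_curve"),
            model_id = record$model_id, sample_id = record$sample_id,
            duration_s = out$time_s[nrow(out)])
}

new_curve <- function(df, template = NULL, class = "stress_strain_curve") {
  out <- tibble::new_tibble(df, class = class)
  if (!is.null(template)) {
    attr(out, "model_id") <- attr(template, "model_id")
    attr(out, "sample_id") <- attr(template, "sample_id")
  }
  out
}

#' Align curves onto a common grid
#'
#' Tests of different durations yield vectors of different lengths; each
#' curve is linearly interpolated onto a common fractional-duration grid
#' whose length is the median of the raw lengths (endpoints preserved).
#'
#' @param curves list of `stress_strain_curve` tibbles (>= 2, each with >=
#'   10 samples).
#' @return A tibble of class `aligned_curves` with columns `sample`, `idx`,
#'   `frac`, `strain`, `stress_mpa`; attribute `duration_s` is the median
#'   duration.
#' @export
align_curves <- function(curves) {
  if (length(curves) < 2) stop("need at least two curves to align", call. = FALSE)
  short <- vapply(curves, nrow, integer(1)) < 10
  if (any(short)) {
    warning(sum(short), " curve(s) with < 10 samples rejected", call. = FALSE)
    curves <- curves[!short]
    if (length(curves) < 2) stop("fewer than two usable curves", call. = FALSE)
  }
  n_grid <- as.integer(round(stats::median(vapply(curves, nrow, integer(1)))))
  frac <- seq(0, 1, length.out = n_grid)
  ids <- names(curves)
  if (is.null(ids)) ids <- vapply(curves, function(x) {
    s <- attr(x, "sample_id"); if (is.null(s)) NA_character_ else s
  }, character(1))
  ids[is.na(ids)] <- paste0("s", seq_along(curves))[is.na(ids)]
  out <- purrr::map2_dfr(curves, ids, function(cv, id) {
    f0 <- seq(0, 1, length.out = nrow(cv))
    tibble::tibble(sample = id, idx = seq_len(n_grid), frac = frac,
                   strain = stats::approx(f0, cv$strain, frac)$y,
                   stress_mpa = stats::approx(f0, cv$stress_mpa, frac)$y)
  })
  structure(tibble::new_tibble(out, class = "aligned_curves"),
            duration_s = stats::median(vapply(curves, function(cv) {
              attr(cv, "duration_s") %||% cv$time_s[nrow(cv)]
            }, numeric(1))),
            n_grid = n_grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# steady-state initial filter state for a unit-amplitude input (so a filter
# started on a constant signal produces that constant from sample one)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  A <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2), rep(0, n - 2)))
  B <- b[2:n] - b[1] * a[2:n]
  solve(diag(n - 1) - t(A), B)
}

# IIR filter, direct form II transposed, with initial state
lfilter <- function(b, a, x, zi) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(x); nz <- length(zi)
  z <- zi
  y <- numeric(n)
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z[1]
    for (k in seq_len(nz)) {
      z[k] <- (if (k < nz) z[k + 1] else 0) + b[k + 1] * x[i] - a[k + 1] * yi
    }
    y[i] <- yi
  }
  y
}

# zero-phase 2nd-order Butterworth low-pass; cutoff in Hz at sampling fs.
# Forward-backward filtering with odd-reflection padding and steady-state
# initial conditions, so edge transients do not leak into the curve.
butter_zero_phase <- function(x, cutoff_hz, fs, order = 2) {
  if (cutoff_hz >= fs / 2) {
    stop("config error: cutoff frequency must be below Nyquist", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  n <- length(x)
  p <- min(n - 1, max(3 * (max(length(a), length(b)) - 1),
                      ceiling(fs / cutoff_hz)))
  xe <- if (p >= 1) {
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else {
    x
  }
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, xe, zi * xe[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1):(p + n)]
}

#' Downsample, filter and average aligned curves
#'
#' The aligned curves are downsampled by `downsample` (every k-th sample),
#' low-pass filtered with a zero-phase second-order Butterworth filter
#' (cutoff `cutoff_hz`, interpreted at the post-downsampling sampling rate)
#' and averaged across samples. `average_first = TRUE` averages before
#' filtering instead.
#'
#' @param aligned an `aligned_curves` tibble.
#' @param downsample decimation factor (default 10).
#' @param cutoff_hz filter cutoff (default 0.1 Hz).
#' @param order filter order (default 2).
#' @param average_first average across samples before filtering?
#' @return A tibble of class `averaged_curve` with columns `time_s`, `frac`,
#'   `strain`, `stress_mpa`; attributes `fs_hz`, `cutoff_hz`, `order`,
#'   `duration_s`, `n_samples`.
#' @export
filter_pipeline <- function(aligned, downsample = 10, cutoff_hz = 0.1,
                            order = 2, average_first = FALSE) {
  stopifnot(inherits(aligned, "aligned_curves"))
  duration <- attr(aligned, "duration_s")
  keep <- seq(1, attr(aligned, "n_grid"), by = downsample)
  ds <- dplyr::filter(aligned, .data$idx %in% keep)
  fs <- length(keep) / duration
  filt <- function(v) butter_zero_phase(v, cutoff_hz, fs, order)
  if (average_first) {
    avg <- ds |>
      dplyr::group_by(.data$idx, .data$frac) |>
      dplyr::summarise(strain = mean(.data$strain),
                       stress_mpa = mean(.data$stress_mpa), .groups = "drop") |>
      dplyr::arrange(.data$idx) |>
      dplyr::mutate(strain = filt(.data$strain), stress_mpa = filt(.data$stress_mpa))
  } else {
    avg <- ds |>
      dplyr::group_by(.data$sample) |>
      dplyr::arrange(.data$idx, .by_group = TRUE) |>
      dplyr::mutate(strain = filt(.data$strain), stress_mpa = filt(.data$stress_mpa)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$idx, .data$frac) |>
      dplyr::summarise(strain = mean(.data$strain),
                       stress_mpa = mean(.data$stress_mpa), .groups = "drop") |>
      dplyr::arrange(.data$idx)
  }
  out <- tibble::tibble(time_s = avg$frac * duration, frac = avg$frac,
                        strain = avg$strain, stress_mpa = avg$stress_mpa)
  structure(tibble::new_tibble(out, class = "averaged_curve"),
            fs_hz = fs, cutoff_hz = cutoff_hz, order = order,
            duration_s = duration,
            n_samples = length(unique(aligned$sample)))
}

#' Incremental elastic modulus
#'
#' E_inc(eps) = d sigma / d eps, computed as the ratio of the central
#' differences of stress and strain with respect to time, each derivative
#' re-filtered with the same zero-phase Butterworth filter, restricted to a
#' window of the test duration (default 15-90%). Points where the strain
#' rate vanishes are masked with a warning.
#'
#' @param avg_curve an `averaged_curve` from [filter_pipeline()].
#' @param window length-2 fractions of the test duration, within (0, 1).
#' @return A tibble of class `e_inc_curve` with columns `time_s`, `frac`,
#'   `strain`, `e_inc_mpa`.
#' @export
incremental_modulus <- function(avg_curve, window = c(0.15, 0.90)) {
  stopifnot(inherits(avg_curve, "averaged_curve"))
  if (length(window) != 2 || window[1] <= 0 || window[2] >= 1 ||
      window[1] >= window[2]) {
    stop("window must be two increasing fractions inside (0, 1)", call. = FALSE)
  }
  n <- nrow(avg_curve)
  if (n < 5) stop("averaged curve too short for derivatives", call. = FALSE)
  central_diff <- function(v) {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    d[1] <- v[2] - v[1]
    d[n] <- v[n] - v[n - 1]
    d
  }
  fs <- attr(avg_curve, "fs_hz")
  cutoff <- attr(avg_curve, "cutoff_hz")
  ord <- attr(avg_curve, "order")
  dstress <- butter_zero_phase(central_diff(avg_curve$stress_mpa), cutoff, fs, ord)
  dstrain <- butter_zero_phase(central_diff(avg_curve$strain), cutoff, fs, ord)
  eps_rate_floor <- 1e-12 + 1e-3 * max(abs(dstrain))
  masked <- abs(dstrain) < eps_rate_floor
  if (any(masked)) warning(sum(masked), " points with vanishing strain rate masked",
                           call. = FALSE)
  e_inc <- ifelse(masked, NA_real_, dstress / dstrain)
  inside <- avg_curve$frac >= window[1] & avg_curve$frac <= window[2]
  out <- tibble::tibble(time_s = avg_curve$time_s[inside],
                        frac = avg_curve$frac[inside],
                        strain = avg_curve$strain[inside],
                        e_inc_mpa = e_inc[inside])
  structure(tibble::new_tibble(out, class = "e_inc_curve"), window = window)
}

#' Secant elastic modulus
#'
#' Slope of the chord from the origin to the point at strain `strain_point`:
#' sigma(eps*) / eps*, with sigma interpolated on the curve.
#'
#' @param curve any tibble with `strain` and `stress_mpa` columns.
#' @param strain_point strain at which to evaluate (> 0, within the curve).
#' @return Secant modulus in MPa.
#' @export
secant_modulus <- function(curve, strain_point) {
  if (strain_point == 0) stop("secant modulus is undefined at zero strain", call. = FALSE)
  rng <- range(curve$strain)
  if (strain_point < rng[1] || strain_point > rng[2]) {
    stop("strain_point outside the curve range", call. = FALSE)
  }
  s <- stats::approx(curve$strain, curve$stress_mpa, strain_point, ties = "ordered")$y
  s / strain_point
}

#' Batch summary of tensile curves
#'
#' Max stress and the strain at max stress are taken from the raw
#' (unfiltered) curves -- the global stress maximum per sample, first index
#' on ties. Mean, sample standard deviation and coefficient of variation are
#' computed across samples. Strain is reported in percent.
#'
#' @param curves list of raw `stress_strain_curve` tibbles.
#' @param model_id label for the batch.
#' @param secant_at optional strain at which to also report the secant
#'   modulus of the batch (mean across samples).
#' @return A one-row tibble of class `tensile_summary`: `model_id`, `n`,
#'   `max_stress_mpa`, `max_stress_sd`, `strain_at_max_pct`,
#'   `strain_at_max_sd`, `cov_stress`, `cov_strain`, `secant_modulus_mpa`.
#' @export
summarize_tensile <- function(curves, model_id = "model", secant_at = NULL) {
  if (inherits(curves, "stress_strain_curve")) curves <- list(curves)
  if (length(curves) < 1) stop("need at least one curve", call. = FALSE)
  per <- purrr::map_dfr(curves, function(cv) {
    i <- which.max(cv$stress_mpa)          # first maximum on ties
    tibble::tibble(max_stress = cv$stress_mpa[i], strain_at_max = cv$strain[i])
  })
  n <- nrow(per)
  sd_or_na <- function(x) if (n >= 2) stats::sd(x) else NA_real_
  mu_s <- mean(per$max_stress); sd_s <- sd_or_na(per$max_stress)
  mu_e <- mean(per$strain_at_max); sd_e <- sd_or_na(per$strain_at_max)
  sec <- if (!is.null(secant_at)) {
    mean(vapply(curves, secant_modulus, numeric(1), strain_point = secant_at))
  } else NA_real_
  out <- tibble::tibble(
    model_id = model_id, n = n,
    max_stress_mpa = mu_s, max_stress_sd = sd_s,
    strain_at_max_pct = 100 * mu_e, strain_at_max_sd = 100 * sd_e,
    cov_stress = sd_s / mu_s, cov_strain = sd_e / mu_e,
    secant_modulus_mpa = sec
  )
  tibble::new_tibble(out, class = "tensile_summary")
}

#' One-sided Welch t-test from summary moments
#'
#' Welch's unequal-variance t statistic computed from (mean, sd, n) pairs,
#' with the one-sided p-value in the requested direction and rejection at
#' the 5% level. `classify_relation()` runs both directions and labels the
#' pair "greater"/"smaller" if the corresponding one-sided test rejects,
#' otherwise "equal".
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 summary moments of the two groups
#'   (n >= 2, sd >= 0).
#' @param direction `"greater"` tests mean1 > mean2; `"less"` tests
#'   mean1 < mean2.
#' @param alpha significance level (default 0.05).
#' @return `welch_one_sided` object (list with `t`, `df`, `p`, `reject`,
#'   `direction`); use [generics::tidy()] for a tibble.
#' @export
welch_one_sided <- function(mean1, sd1, n1, mean2, sd2, n2,
                            direction = c("greater", "less"), alpha = 0.05) {
  direction <- match.arg(direction)
  if (any(c(n1, n2) < 2)) stop("dispersion needs n >= 2 in both groups", call. = FALSE)
  if (any(is.na(c(sd1, sd2)))) {
    stop("missing standard deviation: supply assumed n and sd for this group",
         call. = FALSE)
  }
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  if (!is.finite(df) || se2 == 0) { # both sds zero
    t <- ifelse(mean1 == mean2, 0, sign(mean1 - mean2) * Inf)
    df <- n1 + n2 - 2
  }
  p <- if (direction == "greater") stats::pt(t, df, lower.tail = FALSE) else stats::pt(t, df)
  structure(list(t = t, df = df, p = p, reject = p < alpha,
                 direction = direction, alpha = alpha,
                 mean1 = mean1, mean2 = mean2),
            class = "welch_one_sided")
}

#' @export
print.welch_one_sided <- function(x, ...) {
  cat(sprintf("Welch one-sided t-test (%s): t = %.3f, df = %.2f, p = %.4f (%s)\n",
              x$direction, x$t, x$df, x$p,
              if (x$reject) "reject" else "no rejection"))
  invisible(x)
}

#' @rdname welch_one_sided
#' @export
classify_relation <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  g <- welch_one_sided(mean1, sd1, n1, mean2, sd2, n2, "greater", alpha)
  l <- welch_one_sided(mean1, sd1, n1, mean2, sd2, n2, "less", alpha)
  if (g$reject) "greater" else if (l$reject) "smaller" else "equal"
}
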
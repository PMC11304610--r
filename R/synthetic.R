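#' Material models for synthetic tensile records
#'
#' Closed-form engineering stress-strain laws used to emulate the materials
#' the pipeline is designed for:
#' * `polymer_softening`: sigma = a * eps / (1 + b * eps) -- its tangent
#'   modulus a / (1 + b eps)^2 decreases monotonically, the typical printed
#'   elastomer response;
#' * `tissue_stiffening`: sigma = A * (exp(B * eps) - 1) -- a one-dimensional
#'   proxy for the exponential collagen-recruitment response of the aortic
#'   wall (tangent modulus A B exp(B eps) increases with strain);
#' * `composite_rupture`: mixture (1 - f) * matrix + f * lattice whose total
#'   stress drops by `post_rupture_drop` once the matrix ruptures, then
#'   continues (lattice-only stretch) until final rupture.
#'
#' @param kind one of `"polymer_softening"`, `"tissue_stiffening"`,
#'   `"composite_rupture"`.
#' @param a,b polymer parameters (MPa, -); a > 0, b >= 0.
#' @param A,B tissue parameters (MPa, -); both > 0.
#' @param rupture_strain strain at which the material fails (record ends).
#' @param matrix_model,lattice_model component models for the composite.
#' @param lattice_fraction volume/load fraction f of the lattice in `[0, 1]`.
#' @param matrix_rupture_strain,final_rupture_strain ordered rupture strains.
#' @param post_rupture_drop fractional stress drop at matrix rupture, in
#'   `[0, 1)`.
#' @return A `material_model` object.
#' @export
material_model <- function(kind = c("polymer_softening", "tissue_stiffening",
                                    "composite_rupture"),
                           a = 1.2, b = 2, A = 0.05, B = 3,
                           rupture_strain = NULL,
                           matrix_model = NULL, lattice_model = NULL,
                           lattice_fraction = 0.25,
                           matrix_rupture_strain = 0.72,
                           post_rupture_drop = 0.4,
                           final_rupture_strain = 1.0) {
  kind <- match.arg(kind)
  if (kind == "polymer_softening") {
    if (a <= 0 || b < 0) stop("polymer requires a > 0, b >= 0", call. = FALSE)
    rupture_strain <- rupture_strain %||% 1.35
    m <- list(kind = kind, a = a, b = b, rupture_strain = rupture_strain)
  } else if (kind == "tissue_stiffening") {
    if (A <= 0 || B <= 0) stop("tissue requires A > 0, B > 0", call. = FALSE)
    rupture_strain <- rupture_strain %||% 1.0
    m <- list(kind = kind, A = A, B = B, rupture_strain = rupture_strain)
  } else {
    matrix_model <- matrix_model %||% material_model("polymer_softening")
    lattice_model <- lattice_model %||% material_model("tissue_stiffening")
    if (lattice_fraction < 0 || lattice_fraction > 1) {
      stop("lattice_fraction must be in [0, 1]", call. = FALSE)
    }
    if (post_rupture_drop < 0 || post_rupture_drop >= 1) {
      stop("post_rupture_drop must be in [0, 1)", call. = FALSE)
    }
    if (matrix_rupture_strain >= final_rupture_strain) {
      stop("rupture strains must be ordered: matrix < final", call. = FALSE)
    }
    m <- list(kind = kind, matrix_model = matrix_model,
              lattice_model = lattice_model,
              lattice_fraction = lattice_fraction,
              matrix_rupture_strain = matrix_rupture_strain,
              post_rupture_drop = post_rupture_drop,
              rupture_strain = final_rupture_strain)
  }
  structure(m, class = "material_model")
}

#' Evaluate a material model
#'
#' Engineering stress at the given strains (vectorised). Strains beyond the
#' model's final rupture return `NA` (end-of-test marker).
#'
#' @param model a [material_model()].
#' @param strain numeric vector of engineering strains (>= 0).
#' @return Stress in MPa.
#' @export
stress_at <- function(model, strain) {
  stopifnot(inherits(model, "material_model"))
  if (any(strain < 0)) stop("strain must be >= 0", call. = FALSE)
  s <- switch(model$kind,
    polymer_softening = model$a * strain / (1 + model$b * strain),
    tissue_stiffening = model$A * (expm1(model$B * strain)),
    composite_rupture = {
      base <- (1 - model$lattice_fraction) * stress_at_raw(model$matrix_model, strain) +
        model$lattice_fraction * stress_at_raw(model$lattice_model, strain)
      drop <- ifelse(strain > model$matrix_rupture_strain, 1 - model$post_rupture_drop, 1)
      base * drop
    })
  s[strain > model$rupture_strain] <- NA_real_
  s
}

# component evaluation without the component's own rupture cut-off
stress_at_raw <- function(model, strain) {
  switch(model$kind,
    polymer_softening = model$a * strain / (1 + model$b * strain),
    tissue_stiffening = model$A * expm1(model$B * strain))
}

#' Test protocol for synthetic records
#'
#' @param strain_rate_mm_min constant crosshead rate (default 10 mm/min).
#' @param sampling_hz sampling rate (default 100 Hz).
#' @param gauge_length_mm initial clamp separation (default 10 mm).
#' @param geometry a [specimen_geometry()] template; defaults to the printed
#'   slab cross-section (10.13 mm x 2.60 mm) at the default gauge length.
#' @param conditioning_cycles loading-unloading cycles from 0 to
#'   `conditioning_load_n` before the ramp (default 3).
#' @param conditioning_load_n peak conditioning load (default 1 N).
#' @return A `test_protocol`.
#' @export
test_protocol <- function(strain_rate_mm_min = 10, sampling_hz = 100,
                          gauge_length_mm = 10, geometry = NULL,
                          conditioning_cycles = 3, conditioning_load_n = 1) {
  if (any(c(strain_rate_mm_min, sampling_hz, gauge_length_mm) <= 0)) {
    stop("protocol values must be positive", call. = FALSE)
  }
  geometry <- geometry %||% specimen_geometry(10.13, rep(2.60, 5), gauge_length_mm)
  structure(list(strain_rate_mm_min = strain_rate_mm_min,
                 sampling_hz = sampling_hz,
                 gauge_length_mm = gauge_length_mm,
                 geometry = geometry,
                 conditioning_cycles = conditioning_cycles,
                 conditioning_load_n = conditioning_load_n),
            class = "test_protocol")
}

#' Noise model
#'
#' Additive Gaussian noise on the load channel plus a multiplicative
#' inter-sample jitter of the material's stress scale (the batch-to-batch
#' variability of printed specimens).
#'
#' @param load_noise_sd load-cell noise standard deviation in N (default
#'   0.01 N).
#' @param inter_sample_cov coefficient of variation of the per-sample stress
#'   scale (default 0.05).
#' @return A `noise_model`.
#' @export
noise_model <- function(load_noise_sd = 0.01, inter_sample_cov = 0.05) {
  if (load_noise_sd < 0 || inter_sample_cov < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  structure(list(load_noise_sd = load_noise_sd,
                 inter_sample_cov = inter_sample_cov),
            class = "noise_model")
}

# scale a model's stress amplitude by a factor (per-sample jitter)
scale_model <- function(model, factor) {
  switch(model$kind,
    polymer_softening = { model$a <- model$a * factor; model },
    tissue_stiffening = { model$A <- model$A * factor; model },
    composite_rupture = {
      model$matrix_model <- scale_model(model$matrix_model, factor)
      model$lattice_model <- scale_model(model$lattice_model, factor)
      model
    })
}

# strain at which the model carries the given load (N); used to size the
# conditioning cycles
strain_at_load <- function(model, load_n, area_mm2) {
  target <- load_n / area_mm2
  f <- function(e) stress_at_raw_any(model, e) - target
  upper <- model$rupture_strain
  if (f(upper) < 0) return(upper * 0.5)
  stats::uniroot(f, c(1e-9, upper))$root
}

stress_at_raw_any <- function(model, e) {
  if (model$kind == "composite_rupture") {
    (1 - model$lattice_fraction) * stress_at_raw(model$matrix_model, e) +
      model$lattice_fraction * stress_at_raw(model$lattice_model, e)
  } else {
    stress_at_raw(model, e)
  }
}

#' Generate one synthetic tensile record
#'
#' Constant-rate displacement ramp sampled at the protocol rate, preceded by
#' the conditioning cycles (triangular displacement ramps sized to reach the
#' conditioning load); load = sigma(eps) * A0 + Gaussian noise. The record
#' ends at the model's final rupture.
#'
#' @param model a [material_model()].
#' @param protocol a [test_protocol()].
#' @param noise a [noise_model()].
#' @param seed integer seed (reproducible).
#' @param model_id,sample_id labels.
#' @return A [tensile_record()].
#' @export
generate_record <- function(model, protocol = test_protocol(),
                            noise = noise_model(), seed = 1,
                            model_id = model$kind, sample_id = "s1") {
  stopifnot(inherits(model, "material_model"), inherits(protocol, "test_protocol"))
  set.seed(as.integer(seed))
  g <- protocol$geometry
  rate <- protocol$strain_rate_mm_min / 60          # mm/s
  dt <- 1 / protocol$sampling_hz
  L <- protocol$gauge_length_mm
  d_final <- model$rupture_strain * L
  ramp_d <- seq(0, d_final, by = rate * dt)
  disp <- ramp_d
  if (protocol$conditioning_cycles > 0) {
    e_cond <- strain_at_load(model, protocol$conditioning_load_n, g$area_mm2)
    d_cond <- e_cond * L
    half <- seq(0, d_cond, by = rate * dt)
    cyc <- c(half, rev(half)[-1])                 # up then down, ends at 0
    disp <- c(rep(cyc, protocol$conditioning_cycles), ramp_d)
  }
  time_s <- (seq_along(disp) - 1) * dt
  eps <- disp / L
  sigma <- stress_at(model, pmin(eps, model$rupture_strain))
  load <- sigma * g$area_mm2 + stats::rnorm(length(sigma), 0, noise$load_noise_sd)
  tensile_record(time_s, load, disp, g, model_id = model_id,
                 sample_id = sample_id,
                 protocol = list(strain_rate_mm_min = protocol$strain_rate_mm_min,
                                 preload_mpa = 0.02,
                                 conditioning_cycles = protocol$conditioning_cycles),
                 sampling_hz = protocol$sampling_hz)
}

#' Generate a batch of synthetic records
#'
#' Draws `n` records whose stress scale is jittered multiplicatively with
#' the noise model's `inter_sample_cov` (factor 1 + cov * z, truncated at
#' 0.1). Sub-seeds are `seed * 1000 + i`, so batches are reproducible and
#' records within a batch independent.
#'
#' @inheritParams generate_record
#' @param n number of specimens (default 6, one printed batch).
#' @return A list of [tensile_record()]s.
#' @export
generate_batch <- function(model, protocol = test_protocol(),
                           noise = noise_model(), n = 6, seed = 1,
                           model_id = model$kind) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  factors <- pmax(0.1, 1 + noise$inter_sample_cov * stats::rnorm(n))
  purrr::map(seq_len(n), function(i) {
    generate_record(scale_model(model, factors[i]), protocol, noise,
                    seed = as.integer(seed) * 1000L + i,
                    model_id = model_id, sample_id = paste0("s", i))
  })
}
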
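# shared fixtures: small noiseless protocols and quick batches

quiet_protocol <- function(gauge = 10, cycles = 0) {
  test_protocol(gauge_length_mm = gauge, conditioning_cycles = cycles)
}

noiseless <- function() noise_model(load_noise_sd = 0, inter_sample_cov = 0)

linear_model <- function(E = 2, rupture = 1) {
  material_model("polymer_softening", a = E, b = 0, rupture_strain = rupture)
}

tissue_default <- function() {
  material_model("tissue_stiffening", A = 0.05, B = 3, rupture_strain = 1)
}

# stress-strain curve straight from vectors (bypasses record generation)
make_curve <- function(strain, stress, duration = 60, sample_id = "s1") {
  out <- tibble::tibble(
    time_s = seq(0, duration, length.out = length(strain)),
    strain = strain, stress_mpa = stress
  )
  structure(tibble::new_tibble(out, class = "stress_strain_curve"),
            model_id = "fixture", sample_id = sample_id, duration_s = duration)
}

# n sample values with exactly the requested mean and sd (for Welch oracles)
moment_matched_sample <- function(mean, sd, n) {
  z <- scale(seq_len(n))[, 1]
  mean + sd * z / stats::sd(z)
}
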
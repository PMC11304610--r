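test_that("stress and strain are the load/area and displacement/gauge ratios", {
  g <- specimen_geometry(2, rep(1, 5), 10)          # A0 = 2 mm^2
  rec <- tensile_record(c(0, 0.01, 0.02), c(0, 0.5, 1), c(0, 5, 10), g)
  cv <- compute_stress_strain(rec, trim_conditioning = FALSE)
  expect_equal(cv$stress_mpa, c(0, 0.25, 0.5))      # 1 N / 2 mm^2 = 0.5 MPa
  expect_equal(cv$strain, c(0, 0.5, 1))             # displacement = gauge -> 1
  expect_error(specimen_geometry(2, rep(1, 4), 10), "five")
})

test_that("stress/strain are exactly linear in load and displacement", {
  g <- specimen_geometry(4, rep(2, 5), 20)
  t <- seq(0, 0.1, by = 0.01)
  base <- tensile_record(t, t * 10, t * 40, g)
  scaled <- tensile_record(t, t * 30, t * 120, g)
  c1 <- compute_stress_strain(base, FALSE)
  c2 <- compute_stress_strain(scaled, FALSE)
  expect_equal(c2$stress_mpa, 3 * c1$stress_mpa)
  expect_equal(c2$strain, 3 * c1$strain)
})

test_that("conditioning cycles are trimmed to the final monotone ramp", {
  tis <- tissue_default()
  rec <- generate_record(tis, test_protocol(conditioning_cycles = 3),
                         noiseless(), seed = 11)
  cv <- compute_stress_strain(rec)
  expect_equal(cv$strain[1], 0)
  expect_false(is.unsorted(cv$strain))
  expect_equal(max(cv$strain), 1)
  # curve matches the generator truth exactly without noise
  expect_equal(cv$stress_mpa, stress_at(tis, cv$strain), tolerance = 1e-12)
})

test_that("alignment maps different sampling onto a common median-length grid", {
  f <- function(x) 0.3 * x                          # linear: interpolation exact
  c1 <- make_curve(seq(0, 1, length.out = 601), f(seq(0, 1, length.out = 601)), 60, "a")
  c2 <- make_curve(seq(0, 1, length.out = 901), f(seq(0, 1, length.out = 901)), 90, "b")
  c3 <- make_curve(seq(0, 1, length.out = 701), f(seq(0, 1, length.out = 701)), 70, "c")
  al <- align_curves(list(c1, c2, c3))
  expect_equal(attr(al, "n_grid"), 701)
  wide <- tidyr::pivot_wider(al, id_cols = "idx", names_from = "sample",
                             values_from = "stress_mpa")
  expect_equal(wide[[2]], wide[[3]], tolerance = 1e-9)
  expect_equal(wide[[2]], wide[[4]], tolerance = 1e-9)
  # endpoints preserved
  expect_equal(max(al$strain), 1)
})

test_that("linear interpolation error on a smooth curve obeys the h^2 bound", {
  # quadratic stress in normalized time: f'' = 2 constant
  n_raw <- 101
  x <- seq(0, 1, length.out = n_raw)
  c1 <- make_curve(x, x^2, 60, "s1")
  c2 <- make_curve(seq(0, 1, length.out = 501), seq(0, 1, length.out = 501)^2, 60, "s2")
  al <- align_curves(list(c1, c2, make_curve(x, x^2, 60, "s3")))
  h <- 1 / (n_raw - 1)
  bound <- h^2 * 2 / 8
  coarse <- dplyr::filter(al, .data$sample == "s1")
  expect_lte(max(abs(coarse$stress_mpa - coarse$frac^2)), bound + 1e-12)
})

test_that("curves with fewer than 10 samples are rejected from alignment", {
  ok <- make_curve(seq(0, 1, length.out = 50), seq(0, 1, length.out = 50), 60, "a")
  ok2 <- make_curve(seq(0, 1, length.out = 60), seq(0, 1, length.out = 60), 60, "b")
  bad <- make_curve(c(0, 0.5, 1), c(0, 0.5, 1), 60, "c")
  expect_warning(al <- align_curves(list(a = ok, b = ok2, c = bad)), "rejected")
  expect_setequal(unique(al$sample), c("a", "b"))
  expect_error(align_curves(list(ok)), "at least two")
})

test_that("the filter leaves constants unchanged and decimates by 10", {
  const <- make_curve(seq(0, 1, length.out = 1000), rep(0.4, 1000), 60, "a")
  const2 <- make_curve(seq(0, 1, length.out = 1000), rep(0.4, 1000), 60, "b")
  al <- align_curves(list(const, const2))
  avg <- filter_pipeline(al)
  expect_equal(nrow(avg), 100)                      # 1000 -> 100 samples
  expect_equal(avg$stress_mpa, rep(0.4, 100), tolerance = 1e-6)
})

test_that("a sinusoid at ten times the cutoff is strongly attenuated", {
  # duration 60 s, 600 post-decimation samples -> fs = 10 Hz, cutoff 0.1 Hz;
  # 1 Hz input; zero-phase 2nd-order Butterworth applied twice in magnitude:
  # |H|^2 = 1 / (1 + (f/fc)^4) -> amplitude ~ 1e-4, well below 0.03
  n <- 6000
  tt <- seq(0, 60, length.out = n)
  sine <- make_curve(seq(0, 1, length.out = n), sin(2 * pi * 1 * tt), 60, "a")
  sine2 <- make_curve(seq(0, 1, length.out = n), sin(2 * pi * 1 * tt), 60, "b")
  al <- align_curves(list(sine, sine2))
  avg <- filter_pipeline(al)
  # measured inside the analysis window, past the zero-phase edge transients
  interior <- avg$frac >= 0.15 & avg$frac <= 0.85
  expect_lt(max(abs(avg$stress_mpa[interior])), 0.03)
})

test_that("cutoff at or above Nyquist is a configuration error", {
  const <- make_curve(seq(0, 1, length.out = 1000), rep(1, 1000), 60, "a")
  al <- align_curves(list(const, make_curve(seq(0, 1, length.out = 1000),
                                            rep(1, 1000), 60, "b")))
  expect_error(filter_pipeline(al, cutoff_hz = 50), "Nyquist")
})

test_that("incremental modulus of a linear material is its slope", {
  E <- 2
  batch <- generate_batch(linear_model(E), quiet_protocol(), noiseless(),
                          n = 3, seed = 5)
  curves <- lapply(batch, compute_stress_strain)
  einc <- incremental_modulus(filter_pipeline(align_curves(curves)))
  expect_true(all(abs(einc$e_inc_mpa - E) / E < 0.02))
  expect_true(all(einc$frac >= 0.15 & einc$frac <= 0.90))
})

test_that("incremental modulus tracks the tissue model's analytic derivative", {
  A <- 0.05; B <- 3
  batch <- generate_batch(tissue_default(), quiet_protocol(), noiseless(),
                          n = 3, seed = 5)
  curves <- lapply(batch, compute_stress_strain)
  einc <- incremental_modulus(filter_pipeline(align_curves(curves)))
  truth <- A * B * exp(B * einc$strain)
  inner <- einc$frac >= 0.2 & einc$frac <= 0.85
  expect_true(all(abs(einc$e_inc_mpa[inner] - truth[inner]) / truth[inner] < 0.05))
})

test_that("a stress drop produces negative incremental modulus in its band", {
  comp <- material_model("composite_rupture", matrix_rupture_strain = 0.72,
                         post_rupture_drop = 0.4, final_rupture_strain = 1)
  batch <- generate_batch(comp, quiet_protocol(), noise_model(0.01, 0.05),
                          n = 6, seed = 9)
  curves <- lapply(batch, compute_stress_strain)
  einc <- incremental_modulus(filter_pipeline(align_curves(curves)))
  band <- einc$strain >= 0.70 & einc$strain <= 0.80
  expect_true(any(einc$e_inc_mpa[band] < 0, na.rm = TRUE))
})

test_that("vanishing strain rate is masked with a warning", {
  n <- 2000
  strain <- c(seq(0, 0.5, length.out = n / 2), rep(0.5, n / 2))  # plateau
  cv <- make_curve(strain, strain * 2, 60, "a")
  al <- align_curves(list(cv, make_curve(strain, strain * 2, 60, "b")))
  avg <- filter_pipeline(al)
  expect_warning(einc <- incremental_modulus(avg), "vanishing")
  expect_true(any(is.na(einc$e_inc_mpa)))
})

test_that("secant modulus follows its definition and grows on convex curves", {
  lin <- make_curve(seq(0, 1, length.out = 100), 3 * seq(0, 1, length.out = 100), 60)
  expect_equal(secant_modulus(lin, 0.7), 3, tolerance = 1e-9)
  x <- seq(0, 1, length.out = 1001)
  quad <- make_curve(x, x^2, 60)
  expect_equal(secant_modulus(quad, 0.5), 0.5, tolerance = 1e-4)
  sec <- vapply(seq(0.1, 1, by = 0.1), secant_modulus, numeric(1), curve = quad)
  expect_true(all(diff(sec) > 0))                   # convex -> non-decreasing
  expect_error(secant_modulus(quad, 0), "undefined")
  expect_error(secant_modulus(quad, 2), "range")
})

test_that("summaries use raw maxima with first-index tie-breaking", {
  x <- seq(0, 1, length.out = 101)
  peak <- make_curve(x, pmin(x, 0.7 - 0 * x, 1.4 - x), 60)  # plateau at 0.7
  s <- summarize_tensile(list(peak), "m")
  expect_equal(s$max_stress_mpa, 0.7)
  expect_equal(s$strain_at_max_pct, 70)             # first index of the tie
  expect_true(is.na(s$max_stress_sd))               # n = 1: dispersion flagged

  trio <- lapply(1:3, function(i) make_curve(x, 0.5 * x / max(x), 60))
  s3 <- summarize_tensile(trio, "m3")
  expect_equal(s3$max_stress_mpa, 0.5)
  expect_equal(s3$max_stress_sd, 0)
  expect_equal(s3$cov_stress, 0)
})

test_that("summaries are invariant to the filtering configuration", {
  batch <- generate_batch(tissue_default(), quiet_protocol(),
                          noise_model(0.01, 0.05), n = 4, seed = 21)
  curves <- lapply(batch, compute_stress_strain)
  s <- summarize_tensile(curves, "t")
  # filtering config never touches the raw summaries
  for (cut in c(0.05, 0.2)) {
    al <- align_curves(curves)
    invisible(filter_pipeline(al, cutoff_hz = cut))
    expect_identical(summarize_tensile(curves, "t"), s)
  }
})

test_that("Welch test matches the textbook formula and a brute-force t-test", {
  w <- welch_one_sided(1, 0.1, 6, 0.9, 0.1, 6, "greater")
  expect_equal(w$t, 0.1 / (0.1 * sqrt(2 / 6)), tolerance = 1e-12)
  expect_equal(w$df, 10)
  # brute force: reconstruct samples with matching moments, use stats::t.test
  a <- moment_matched_sample(0.56, 0.03, 6)
  b <- moment_matched_sample(0.41, 0.03, 6)
  ref <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  w2 <- welch_one_sided(0.56, 0.03, 6, 0.41, 0.03, 6, "greater")
  expect_equal(w2$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(w2$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(w2$p, ref$p.value, tolerance = 1e-9)
})

test_that("identical summaries give t = 0 and relation 'equal'", {
  w <- welch_one_sided(0.5, 0.1, 6, 0.5, 0.1, 6, "greater")
  expect_equal(w$t, 0)
  expect_false(w$reject)
  expect_equal(classify_relation(0.5, 0.1, 6, 0.5, 0.1, 6), "equal")
  expect_error(welch_one_sided(1, NA, 6, 1, 0.1, 6), "assumed")
})

test_that("tidy and glance return well-formed tibbles", {
  w <- welch_one_sided(1, 0.1, 6, 0.9, 0.1, 6, "greater")
  td <- generics::tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "statistic", "parameter", "p.value",
                     "alternative", "reject"))
  gl <- generics::glance(w)
  expect_equal(gl$statistic, w$t)
})
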
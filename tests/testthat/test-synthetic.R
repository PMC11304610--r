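test_that("material models evaluate their closed forms", {
  tis <- material_model("tissue_stiffening", A = 0.05, B = 3)
  expect_equal(stress_at(tis, 0), 0)
  expect_equal(stress_at(tis, 1), 0.05 * (exp(3) - 1), tolerance = 1e-12)
  pol <- material_model("polymer_softening", a = 1.2, b = 2)
  expect_equal(stress_at(pol, 0), 0)
  expect_equal(stress_at(pol, 0.5), 1.2 * 0.5 / 2)
  # polymer tangent modulus a/(1+b eps)^2 is strictly decreasing
  eps <- seq(0, 1.3, by = 0.01)
  tangent <- diff(stress_at(pol, eps)) / diff(eps)
  expect_true(all(diff(tangent) < 0))
  expect_error(stress_at(pol, -0.1), "strain")
  expect_error(material_model("tissue_stiffening", A = -1), "tissue")
  expect_error(material_model("composite_rupture", matrix_rupture_strain = 1.2,
                              final_rupture_strain = 1), "ordered")
})

test_that("composite stress mixes components and drops after matrix rupture", {
  comp <- material_model("composite_rupture", lattice_fraction = 0.25,
                         matrix_rupture_strain = 0.72, post_rupture_drop = 0.4,
                         final_rupture_strain = 1)
  m <- comp$matrix_model; l <- comp$lattice_model
  mix <- function(e) 0.75 * stress_at(m, e) + 0.25 * stress_at(l, e)
  expect_equal(stress_at(comp, 0.5), mix(0.5), tolerance = 1e-12)
  expect_equal(stress_at(comp, 0.8), 0.6 * mix(0.8), tolerance = 1e-12)
  expect_true(is.na(stress_at(comp, 1.05)))        # beyond final rupture
})

test_that("the same seed reproduces a record bit for bit", {
  r1 <- generate_record(tissue_default(), test_protocol(), noise_model(), seed = 42)
  r2 <- generate_record(tissue_default(), test_protocol(), noise_model(), seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- generate_record(tissue_default(), test_protocol(), noise_model(), seed = 43)
  expect_false(identical(r3$data, r1$data))
})

test_that("ramp duration follows rate x gauge arithmetic", {
  # 10 mm/min on a 10 mm gauge to rupture strain 1 -> 10 mm at 1/6 mm/s = 60 s
  rec <- generate_record(tissue_default(), quiet_protocol(), noiseless(), seed = 1)
  expect_equal(max(rec$data$time_s), 60, tolerance = 1e-9)
  expect_equal(nrow(rec$data), 6001)               # 100 Hz inclusive of t = 0
  expect_equal(max(rec$data$displacement_mm), 10)
})

test_that("a noiseless linear model inverts exactly through the analysis", {
  E <- 1.5
  rec <- generate_record(linear_model(E), quiet_protocol(), noiseless(), seed = 2)
  cv <- compute_stress_strain(rec)
  expect_equal(cv$stress_mpa, E * cv$strain, tolerance = 1e-12)
})

test_that("zero inter-sample CoV gives identical curves and zero dispersion", {
  batch <- generate_batch(tissue_default(), quiet_protocol(), noiseless(),
                          n = 4, seed = 3)
  curves <- lapply(batch, compute_stress_strain)
  s <- summarize_tensile(curves, "t")
  expect_equal(s$max_stress_sd, 0)
  expect_equal(s$cov_stress, 0)
})

test_that("batch CoV of max stress approaches the configured jitter", {
  covs <- vapply(1:30, function(r) {
    batch <- generate_batch(tissue_default(), quiet_protocol(),
                            noise_model(0.01, 0.05), n = 6, seed = 300 + r)
    summarize_tensile(lapply(batch, compute_stress_strain), "t")$cov_stress
  }, numeric(1))
  expect_gt(mean(covs), 0.02)
  expect_lt(mean(covs), 0.08)
})

test_that("tissue and polymer curves reproduce the strain-stiffening crossover", {
  # matched secant modulus at 30% strain
  tis <- material_model("tissue_stiffening", A = 0.05, B = 3)
  target <- stress_at(tis, 0.3)
  a <- target * (1 + 2 * 0.3) / 0.3
  pol <- material_model("polymer_softening", a = a, b = 2)
  lo <- seq(0.05, 0.4, by = 0.05)
  ratio_lo <- stress_at(tis, lo) / stress_at(pol, lo)
  expect_true(all(ratio_lo > 0.3 & ratio_lo < 1.4))  # similar below ~40%
  hi <- seq(0.6, 1.0, by = 0.1)
  expect_true(all(stress_at(tis, hi) > 1.5 * stress_at(pol, hi)))
})

test_that("generator output always satisfies the record invariants", {
  for (kind in c("polymer_softening", "tissue_stiffening", "composite_rupture")) {
    m <- material_model(kind)
    rec <- generate_record(m, test_protocol(), noise_model(), seed = 8)
    expect_s3_class(rec, "tensile_record")
    expect_false(is.unsorted(rec$data$time_s, strictly = TRUE))
    expect_equal(median(diff(rec$data$time_s)), 0.01, tolerance = 1e-9)
    expect_true(all(!is.na(rec$data$load_N)))
  }
})
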
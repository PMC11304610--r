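test_that("the bundled reference table carries the transcribed values", {
  refs <- aorta_reference_table()
  ht <- refs[refs$label == "HT Circ (Maizato 2023)", ]
  expect_equal(ht$max_stress_mpa, 0.76)
  expect_equal(ht$max_stress_sd, 0.23)
  expect_equal(ht$strain_at_max_pct, 57.18)
  expect_equal(ht$strain_at_max_sd, 7.96)
  reeps <- refs[refs$label == "AAA Circ (Reeps 2012)", ]
  expect_true(is.na(reeps$strain_at_max_pct))      # source reports no strain
})

test_that("recomputed CoV matches the published CoV within rounding", {
  refs <- aorta_reference_table()
  printed_cov_stress <- c(0.43, 0.73, 0.30, 0.46, 0.04, 0.11, 0.08)
  printed_cov_strain <- c(0.002, 0.35, 0.14, NA, 0.07, 0.14, 0.12)
  expect_true(all(abs(refs$max_stress_sd / refs$max_stress_mpa -
                      printed_cov_stress) <= 0.01))
  cov_strain <- refs$strain_at_max_sd / refs$strain_at_max_pct
  ok <- !is.na(printed_cov_strain)
  expect_true(all(abs(cov_strain[ok] - printed_cov_strain[ok]) <= 0.01))
})

test_that("reference table round-trips through CSV and JSON unchanged", {
  refs <- aorta_reference_table()
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(refs, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(refs))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(refs, js, dataframe = "rows", digits = NA)
  back2 <- jsonlite::fromJSON(js)
  expect_equal(back2$max_stress_mpa, refs$max_stress_mpa)
  expect_equal(back2$strain_at_max_pct, refs$strain_at_max_pct)
})

test_that("flexible control matches the healthy abdominal aorta, stiff models differ", {
  s <- printed_model_summaries()
  cmp <- compare_to_reference(s, metric = "max_stress", assumed_n = 6)
  pick <- function(model, ref) cmp$relation[cmp$model_id == model & cmp$reference == ref]
  expect_equal(pick("Ctrl_SHA30", "HA Circ (Vallabhaneni 2004)"), "equal")
  expect_equal(pick("Ch_T600_SDB", "HA Circ (Vallabhaneni 2004)"), "greater")
  expect_equal(pick("Ctrl_T600", "HA Long (Vallabhaneni 2004)"), "smaller")
})

test_that("relations are antisymmetric between the two directions", {
  cases <- list(c(0.56, 0.03), c(0.41, 0.03), c(0.88, 0.02), c(0.61, 0.07))
  for (i in seq_along(cases)) {
    for (j in seq_along(cases)) {
      ab <- classify_relation(cases[[i]][1], cases[[i]][2], 6,
                              cases[[j]][1], cases[[j]][2], 6)
      ba <- classify_relation(cases[[j]][1], cases[[j]][2], 6,
                              cases[[i]][1], cases[[i]][2], 6)
      expected <- switch(ab, greater = "smaller", smaller = "greater", equal = "equal")
      expect_equal(ba, expected)
    }
  }
})

test_that("widely separated means classify deterministically", {
  # means ten pooled standard deviations apart
  expect_equal(classify_relation(1.0, 0.05, 6, 1.0 - 10 * 0.05, 0.05, 6), "greater")
  expect_equal(classify_relation(1.0 - 10 * 0.05, 0.05, 6, 1.0, 0.05, 6), "smaller")
})

test_that("match table pairs summaries with their nearest references", {
  empty <- printed_model_summaries()[0, ]
  expect_equal(nrow(build_match_table(empty)), 0)

  refs <- aorta_reference_table()
  synth <- tibble::tibble(
    model_id = paste0("m", seq_len(nrow(refs))),
    n = 6L,
    max_stress_mpa = refs$max_stress_mpa,
    max_stress_sd = 0.02,
    strain_at_max_pct = 100, strain_at_max_sd = 1,
    cov_stress = NA_real_, cov_strain = NA_real_, secant_modulus_mpa = NA_real_
  )
  mt <- build_match_table(synth, refs, assumed_n = 6)
  for (k in seq_len(nrow(refs))) {
    row <- mt[mt$reference == refs$label[k], ]
    expect_true(grepl(paste0("\\bm", k, "\\b"), row$models_equal),
                label = paste("reference", k, "matched by its own summary"))
  }
  # deterministic function of its inputs
  expect_identical(mt, build_match_table(synth, refs, assumed_n = 6))
})

test_that("match table flags the closest model when none is equal", {
  one <- tibble::tibble(model_id = "far", n = 6L,
                        max_stress_mpa = 5, max_stress_sd = 0.01,
                        strain_at_max_pct = 100, strain_at_max_sd = 1,
                        cov_stress = NA_real_, cov_strain = NA_real_,
                        secant_modulus_mpa = NA_real_)
  mt <- build_match_table(one)
  expect_true(all(mt$closest_flagged))
  expect_true(all(mt$closest_model == "far"))
  expect_true(all(mt$models_equal == ""))
})

test_that("strain comparisons warn when a reference lacks strain data", {
  s <- printed_model_summaries()
  expect_warning(cmp <- compare_to_reference(s, metric = "strain_at_max"),
                 "unavailable")
  expect_false("AAA Circ (Reeps 2012)" %in% cmp$reference)
})
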
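#' Bundled aortic-tissue reference values
#'
#' Uniaxial tensile results for healthy and aneurysmal aortas transcribed
#' from the published literature compilation: per study, the tissue state,
#' region, loading orientation and max stress / strain at max stress as mean
#' +/- standard deviation (stress in MPa, strain in percent; stretch-based
#' studies were already converted to strain in the source compilation).
#' Strain entries that the sources did not report are `NA`. Reference sample
#' sizes are not published; comparisons use a configurable `assumed_n`.
#'
#' @return A tibble with one row per reference entry.
#' @export
aorta_reference_table <- function() {
  tibble::tibble(
    label = c("TAA Circ (Forsell 2014)", "AAA Long (Forsell 2012)",
              "HT Circ (Maizato 2023)", "AAA Circ (Reeps 2012)",
              "AAA Long (Vallabhaneni 2004)", "HA Circ (Vallabhaneni 2004)",
              "HA Long (Vallabhaneni 2004)"),
    study = c("Forsell et al. (2014)", "Forsell et al. (2012)",
              "Maizato et al. (2023)", "Reeps et al. (2012)",
              "Vallabhaneni et al. (2004)", "Vallabhaneni et al. (2004)",
              "Vallabhaneni et al. (2004)"),
    tissue_state = c("aneurysm", "aneurysm", "healthy", "aneurysm",
                     "aneurysm", "healthy", "healthy"),
    region = c("thoracic", "abdominal", "thoracic", "abdominal",
               "abdominal", "abdominal", "abdominal"),
    orientation = c("circumferential", "longitudinal", "circumferential",
                    "circumferential", "longitudinal", "circumferential",
                    "longitudinal"),
    max_stress_mpa = c(0.486, 0.437, 0.76, 1.063, 0.53, 0.61, 1.30),
    max_stress_sd = c(0.21, 0.319, 0.23, 0.49, 0.02, 0.07, 0.11),
    strain_at_max_pct = c(52.11, 32.5, 57.18, NA, 30, 29, 33),
    strain_at_max_sd = c(0.13, 11.3, 7.96, NA, 2, 4, 4)
  )
}

#' Bundled printed-model tensile summaries
#'
#' Max stress and strain at max stress of the eight printed models (mean +/-
#' standard deviation over n = 6 printed specimens each), as published, for
#' use in comparisons when no raw curves are supplied.
#'
#' @return A `tensile_summary` tibble with one row per printed model.
#' @export
printed_model_summaries <- function() {
  out <- tibble::tibble(
    model_id = c("Ctrl_SHA30", "Ch_T600_SHA85", "Ch_T600_SDB",
                 "Knit_SHA30_SHA95", "DiaCr_SHA30_SHA70", "Ori_SHA30_SHA70",
                 "Ctrl_T600", "Knit_T600_SHA85"),
    n = 6L,
    max_stress_mpa = c(0.56, 0.81, 0.88, 0.74, 0.70, 0.70, 0.41, 0.39),
    max_stress_sd = c(0.03, 0.02, 0.02, 0.02, 0.05, 0.07, 0.03, 0.01),
    strain_at_max_pct = c(139.46, 132.95, 70.44, 152.94, 158.21, 124.40,
                          127.33, 108.70),
    strain_at_max_sd = c(9.81, 3.61, 0.86, 5.73, 8.99, 9.77, 7.47, 5.93)
  )
  out$cov_stress <- out$max_stress_sd / out$max_stress_mpa
  out$cov_strain <- out$strain_at_max_sd / out$strain_at_max_pct
  out$secant_modulus_mpa <- NA_real_
  tibble::new_tibble(out, class = "tensile_summary")
}

#' Printed-model design table
#'
#' The printed models with their unit cells and matrix/lattice materials.
#'
#' @return A tibble.
#' @export
printed_model_designs <- function() {
  tibble::tibble(
    model_id = c("Ctrl_SHA30", "Ch_T600_SHA85", "Ch_T600_SDB",
                 "Knit_SHA30_SHA95", "DiaCr_SHA30_SHA70", "Ori_SHA30_SHA70",
                 "Ctrl_T600", "Knit_T600_SHA85"),
    unit_cell = c(NA, "chain", "chain", "knitted", "diamond_crystal",
                  "origami", NA, "knitted"),
    matrix_material = c("SHA30", "T600", "T600", "SHA30", "SHA30", "SHA30",
                        "T600", "T600"),
    lattice_material = c(NA, "SHA85", "SDB", "SHA95", "SHA70", "SHA70",
                         NA, "SHA85")
  )
}

#' Compare model summaries against reference entries
#'
#' For every (model, reference) pair, runs Welch one-sided tests in both
#' directions on the chosen metric and classifies the relation as
#' "greater", "smaller" or "equal" (neither one-sided test rejects at the
#' 5% level). Reference dispersions use `assumed_n` samples.
#'
#' @param summaries a `tensile_summary` tibble (one row per model).
#' @param references reference tibble, defaults to [aorta_reference_table()].
#' @param metric `"max_stress"` or `"strain_at_max"`.
#' @param assumed_n assumed reference sample size (default 6).
#' @param alpha significance level (default 0.05).
#' @return A tibble with one row per pair: `model_id`, `reference`,
#'   `metric`, `relation`, `t`, `p_greater`, `p_smaller`.
#' @export
compare_to_reference <- function(summaries, references = aorta_reference_table(),
                                 metric = c("max_stress", "strain_at_max"),
                                 assumed_n = 6, alpha = 0.05) {
  metric <- match.arg(metric)
  mcol <- if (metric == "max_stress") "max_stress_mpa" else "strain_at_max_pct"
  scol <- if (metric == "max_stress") "max_stress_sd" else "strain_at_max_sd"
  refs <- references[!is.na(references[[mcol]]), , drop = FALSE]
  if (nrow(refs) < nrow(references)) {
    refs_missing <- setdiff(references$label, refs$label)
    if (metric == "strain_at_max" && length(refs_missing)) {
      warning("metric unavailable for reference(s): ",
              paste(refs_missing, collapse = ", "), call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(summaries)), j = seq_len(nrow(refs)))
  purrr::pmap_dfr(grid, function(i, j) {
    m1 <- summaries[[mcol]][i]; s1 <- summaries[[scol]][i]; n1 <- summaries$n[i]
    m2 <- refs[[mcol]][j]; s2 <- refs[[scol]][j]
    g <- welch_one_sided(m1, s1, n1, m2, s2, assumed_n, "greater", alpha)
    l <- welch_one_sided(m1, s1, n1, m2, s2, assumed_n, "less", alpha)
    tibble::tibble(
      model_id = summaries$model_id[i],
      reference = refs$label[j],
      metric = metric,
      relation = if (g$reject) "greater" else if (l$reject) "smaller" else "equal",
      t = g$t, p_greater = g$p, p_smaller = l$p
    )
  })
}

#' Models statistically equal to each reference
#'
#' For every reference entry, lists the models whose max stress is "equal"
#' (neither one-sided Welch test rejects); when no model is equal, the model
#' with the smallest |mean difference| is reported and flagged closest.
#'
#' @inheritParams compare_to_reference
#' @return A tibble: `reference`, `models_equal` (comma-separated, possibly
#'   empty), `closest_model`, `closest_flagged` (TRUE when no model is
#'   equal).
#' @export
build_match_table <- function(summaries, references = aorta_reference_table(),
                              assumed_n = 6, alpha = 0.05) {
  if (nrow(summaries) == 0) {
    return(tibble::tibble(reference = character(), models_equal = character(),
                          closest_model = character(), closest_flagged = logical()))
  }
  cmp <- compare_to_reference(summaries, references, "max_stress", assumed_n, alpha)
  cmp |>
    dplyr::group_by(.data$reference) |>
    dplyr::reframe({
      eq <- .data$model_id[.data$relation == "equal"]
      ref_mu <- references$max_stress_mpa[match(.data$reference[1], references$label)]
      dists <- abs(summaries$max_stress_mpa - ref_mu)
      tibble::tibble(
        models_equal = paste(eq, collapse = ", "),
        closest_model = summaries$model_id[which.min(dists)],
        closest_flagged = length(eq) == 0
      )
    })
}
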
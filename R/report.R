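#' Render a tensile-comparison report
#'
#' Writes Markdown, CSV and JSON report files: the model summary table, the
#' lattice volume fractions, the reference table, the relation comparisons
#' and the reference match table, plus (optionally) the max-stress scatter
#' figure. Empty inputs yield a valid empty-report skeleton.
#'
#' @param summaries a `tensile_summary` tibble (may have zero rows).
#' @param comparisons comparison tibble from [compare_to_reference()] (or
#'   `NULL` to recompute when summaries are present).
#' @param volume_fractions optional tibble with columns `kind` and
#'   `volume_pct`.
#' @param path output directory (created if needed).
#' @param assumed_n assumed reference sample size used when recomputing.
#' @param figure also write the scatter figure (`scatter.png`)?
#' @return Invisibly, a named list of written file paths.
#' @export
render_report <- function(summaries, comparisons = NULL, volume_fractions = NULL,
                          path, assumed_n = 6, figure = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (is.null(summaries)) summaries <- printed_model_summaries()[0, ]
  refs <- aorta_reference_table()
  if (is.null(comparisons) && nrow(summaries) > 0) {
    comparisons <- compare_to_reference(summaries, refs, "max_stress", assumed_n)
  }
  if (is.null(comparisons)) {
    comparisons <- tibble::tibble(model_id = character(), reference = character(),
                                  metric = character(), relation = character(),
                                  t = numeric(), p_greater = numeric(),
                                  p_smaller = numeric())
  }
  match_tbl <- if (nrow(summaries) > 0) {
    build_match_table(summaries, refs, assumed_n)
  } else {
    tibble::tibble(reference = character(), models_equal = character(),
                   closest_model = character(), closest_flagged = logical())
  }

  files <- list(
    summary_csv = file.path(path, "summary.csv"),
    comparisons_csv = file.path(path, "comparisons.csv"),
    references_csv = file.path(path, "references.csv"),
    match_csv = file.path(path, "match_table.csv"),
    report_json = file.path(path, "report.json"),
    report_md = file.path(path, "report.md")
  )
  readr::write_csv(summaries, files$summary_csv)
  readr::write_csv(comparisons, files$comparisons_csv)
  readr::write_csv(refs, files$references_csv)
  readr::write_csv(match_tbl, files$match_csv)

  payload <- list(
    generated = "aortamimic report",
    assumed_n = assumed_n,
    summaries = summaries,
    volume_fractions = volume_fractions %||% tibble::tibble(kind = character(),
                                                            volume_pct = numeric()),
    comparisons = comparisons,
    references = refs,
    match_table = match_tbl
  )
  jsonlite::write_json(payload, files$report_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")

  md_table <- function(df) {
    if (nrow(df) == 0) return("(none)")
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4)))
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(hdr, sep, rows), collapse = "\n")
  }
  md <- c(
    "# Lattice-reinforced model tensile report", "",
    "## Lattice volume fractions", md_table(payload$volume_fractions), "",
    "## Model summaries (max stress, strain at max stress)", md_table(summaries), "",
    "## Aortic-tissue references", md_table(refs), "",
    sprintf("## Relations to references (max stress, Welch one-sided, assumed n = %d)",
            assumed_n),
    md_table(comparisons), "",
    "## Models equal to each reference", md_table(match_tbl), ""
  )
  writeLines(md, files$report_md)

  if (figure && nrow(summaries) > 0) {
    files$scatter_png <- file.path(path, "scatter.png")
    p <- plot_stress_strain_scatter(summaries, refs)
    ggplot2::ggsave(files$scatter_png, p, width = 7, height = 5, dpi = 150)
  }
  invisible(files)
}
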
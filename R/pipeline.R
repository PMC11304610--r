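#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration for a full synthetic
#' run: which material models to emulate, the batch size, the analysis
#' window and filter settings, which lattice designs to build, and the seed.
#' All defaults equal the published protocol (10 mm/min, 100 Hz, downsample
#' 10, 2nd-order 0.1 Hz Butterworth, 15-90% window, n = 6, assumed_n = 6).
#'
#' @param config a named list or a YAML file path with any of the fields
#'   below; missing fields take the defaults.
#' @return A validated `pipeline_config` list with fields `models`, `n_samples`,
#'   `seed`, `window`, `downsample`, `cutoff_hz`, `filter_order`,
#'   `average_first`, `assumed_n`, `designs`, `noise`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    models = list(
      polymer = list(kind = "polymer_softening", a = 1.2, b = 2),
      tissue = list(kind = "tissue_stiffening", A = 0.05, B = 3),
      composite = list(kind = "composite_rupture")
    ),
    n_samples = 6, seed = 1,
    window = c(0.15, 0.90), downsample = 10, cutoff_hz = 0.1,
    filter_order = 2, average_first = FALSE,
    assumed_n = 6,
    designs = character(0),
    noise = list(load_noise_sd = 0.01, inter_sample_cov = 0.05)
  )
  cfg <- utils::modifyList(def, config)
  # list-valued stages replace wholesale (an empty list disables the stage)
  for (key in c("models", "designs")) {
    if (key %in% names(config)) cfg[[key]] <- config[[key]]
  }
  if (cfg$n_samples < 1 || cfg$downsample < 1) stop("invalid pipeline config", call. = FALSE)
  if (length(cfg$window) != 2 || cfg$window[1] <= 0 || cfg$window[2] >= 1) {
    stop("analysis window must lie inside (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

model_from_config <- function(mc) {
  do.call(material_model, mc)
}

#' Run the full synthetic pipeline
#'
#' Generate -> analyse -> compare -> report: draws seeded synthetic batches
#' for every configured material model, runs the tensile pipeline
#' (stress/strain, alignment, filtering, incremental modulus), summarises
#' the batches, compares them against the bundled aortic references,
#' optionally builds the requested lattice designs, and renders the report.
#' Deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()] (or list/YAML path coerced to one).
#' @param out_dir output directory for report artifacts (default a temp
#'   directory).
#' @return A list with `summaries`, `curves`, `e_inc`, `comparisons`,
#'   `volume_fractions`, `files`, `timings_s`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("aortamimic_")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (length(config$models) == 0 && length(config$designs) == 0) {
    warning("pipeline config has no stages; nothing to do", call. = FALSE)
    return(invisible(list(summaries = NULL, files = NULL)))
  }
  noise <- noise_model(config$noise$load_noise_sd, config$noise$inter_sample_cov)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  summaries <- list(); curves_out <- list(); einc_out <- list()
  seed_i <- 0
  for (nm in names(config$models)) {
    t0 <- tic()
    seed_i <- seed_i + 1
    model <- model_from_config(config$models[[nm]])
    batch <- generate_batch(model, test_protocol(), noise, n = config$n_samples,
                            seed = config$seed * 100L + seed_i, model_id = nm)
    curves <- purrr::map(batch, compute_stress_strain)
    aligned <- align_curves(curves)
    avg <- filter_pipeline(aligned, config$downsample, config$cutoff_hz,
                           config$filter_order, config$average_first)
    einc <- incremental_modulus(avg, config$window)
    summaries[[nm]] <- summarize_tensile(curves, model_id = nm)
    curves_out[[nm]] <- avg
    einc_out[[nm]] <- einc
    timings[paste0("analyze_", nm)] <- toc(t0)
    message(sprintf("[aortamimic] %-10s n=%d analysed in %.2f s", nm, config$n_samples,
                    timings[paste0("analyze_", nm)]))
  }
  summaries <- if (length(summaries)) dplyr::bind_rows(summaries) else NULL

  vf <- NULL
  if (length(config$designs) > 0) {
    t0 <- tic()
    vf <- purrr::map_dfr(config$designs, function(k) {
      lat <- build_design_lattice(k)
      tibble::tibble(kind = k, volume_pct = 100 * volume_fraction(lat),
                     cell_count = attr(lat, "cell_count"))
    })
    timings["lattice"] <- toc(t0)
    message(sprintf("[aortamimic] %d lattice design(s) built in %.2f s",
                    length(config$designs), timings["lattice"]))
  }

  comparisons <- NULL
  files <- NULL
  if (!is.null(summaries)) {
    t0 <- tic()
    comparisons <- compare_to_reference(summaries, assumed_n = config$assumed_n)
    files <- render_report(summaries, comparisons, vf, out_dir,
                           assumed_n = config$assumed_n)
    timings["report"] <- toc(t0)
  }
  list(summaries = summaries, curves = curves_out, e_inc = einc_out,
       comparisons = comparisons, volume_fractions = vf,
       files = files, timings_s = timings)
}
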
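#' Read and write tensile-test CSV files
#'
#' The on-disk format is one record per file: a commented header block
#' (`# key: value`) carrying `model_id`, `sample_id`, `width_mm`,
#' `thickness_mm` (five comma-separated readings), `gauge_length_mm`, then
#' the channels `time_s,load_N,displacement_mm`.
#'
#' @param paths character vector of CSV paths (wildcards not expanded).
#' @return `read_tensile_csv()`: a list of [tensile_record()]s.
#' @export
read_tensile_csv <- function(paths) {
  purrr::map(paths, read_one_tensile_csv)
}

read_one_tensile_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    hdr[[key]] <- val
  }
  need <- c("width_mm", "thickness_mm", "gauge_length_mm")
  if (!all(need %in% names(hdr))) {
    stop("missing specimen geometry header in ", path, call. = FALSE)
  }
  geom <- specimen_geometry(
    width_mm = as.numeric(hdr$width_mm),
    thickness_measurements_mm = as.numeric(strsplit(hdr$thickness_mm, ",")[[1]]),
    gauge_length_mm = as.numeric(hdr$gauge_length_mm)
  )
  dat <- utils::read.csv(path, comment.char = "#")
  need_cols <- c("time_s", "load_N", "displacement_mm")
  if (!all(need_cols %in% names(dat))) {
    stop("CSV must have columns time_s, load_N, displacement_mm", call. = FALSE)
  }
  tensile_record(dat$time_s, dat$load_N, dat$displacement_mm, geom,
                 model_id = hdr$model_id %||% "model",
                 sample_id = hdr$sample_id %||% "s1")
}

#' @rdname read_tensile_csv
#' @param record a [tensile_record()].
#' @param path output path.
#' @export
write_tensile_csv <- function(record, path) {
  g <- record$geometry
  hdr <- c(
    sprintf("# model_id: %s", record$model_id),
    sprintf("# sample_id: %s", record$sample_id),
    sprintf("# width_mm: %g", g$width_mm),
    sprintf("# thickness_mm: %s", paste(g$thickness_measurements_mm, collapse = ",")),
    sprintf("# gauge_length_mm: %g", g$gauge_length_mm)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(record$data, con, row.names = FALSE)
  invisible(path)
}
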
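#' Write a synthetic study to CSV files
#'
#' Emits the standard file layout consumed by [run_pipeline()]:
#' `design.csv`, `gas.csv`, `nutrients.csv`, `peaks_nosZI.csv`,
#' `peaks_nosZII.csv`, `standards.csv`, `qpcr.csv` and `truth.csv` (the
#' truth file is never read by any analysis stage).
#'
#' @param study An `n2o_study` from [generate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "n2o_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj)) return()
    path <- file.path(dir, name)
    readr::write_csv(obj, path)
    files <<- c(files, path)
  }
  design <- dplyr::distinct(
    study$gas, .data$fertilization, .data$temperature_C, .data$replicate,
    .data$c2h2_level, .data$day, .data$arm
  )
  emit(design, "design.csv")
  emit(study$gas, "gas.csv")
  emit(study$nutrients, "nutrients.csv")
  emit(study$peaks_nosZI, "peaks_nosZI.csv")
  emit(study$peaks_nosZII, "peaks_nosZII.csv")
  emit(study$standards, "standards.csv")
  emit(study$qpcr, "qpcr.csv")
  emit(study$truth_cells, "truth.csv")
  invisible(files)
}

# Read a CSV and check for required columns.
read_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(what, " file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read the standard input tables
#'
#' Light wrappers over [readr::read_csv()] that validate the expected
#' columns for each table of the pipeline's CSV layout.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_gas <- function(path) {
  read_checked(path, c("fertilization", "temperature_C", "replicate",
                       "c2h2_level", "day", "conc_t0_ppbv", "conc_t24_ppbv"),
               "gas")
}

#' @rdname read_gas
#' @export
read_rates <- function(path) {
  read_checked(path, c("fertilization", "temperature_C", "replicate",
                       "c2h2_level", "day", "rate_ngN_g_d"), "rates")
}

#' @rdname read_gas
#' @export
read_peaks <- function(path) {
  read_checked(path, c("sample_id", "fragment_bp", "height"), "peaks")
}

#' @rdname read_gas
#' @export
read_standards <- function(path) {
  read_checked(path, c("gene", "log10_copies", "cq"), "standards")
}

#' @rdname read_gas
#' @export
read_qpcr <- function(path) {
  read_checked(path, c("sample_id", "gene", "cq"), "qpcr")
}

#' @rdname read_gas
#' @export
read_nutrients <- function(path) {
  read_checked(path, c("fertilization", "day", "nh4_ug_g", "no3_ug_g"),
               "nutrients")
}
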
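# CSV dialects for datasets and JSON serialization of run reports.
#
# Spectra file: first column `sample_id`, second `source`, remaining columns
# one per wavenumber with numeric headers in cm^-1, descending 4000 -> 400.
# Concentration file: `sample_id` plus one column per analyte, mg g^-1.

#' Write a dataset to the spectra/concentration CSV pair
#'
#' @param dataset a [nutri_dataset()].
#' @param spectra_path,conc_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, spectra_path, conc_path) {
  stopifnot(inherits(dataset, "nutri_dataset"))
  sp <- data.frame(sample_id = rownames(dataset$spectra),
                   source = as.character(dataset$sources),
                   dataset$spectra, check.names = FALSE)
  utils::write.csv(sp, spectra_path, row.names = FALSE)
  co <- data.frame(sample_id = rownames(dataset$concentrations),
                   dataset$concentrations, check.names = FALSE)
  utils::write.csv(co, conc_path, row.names = FALSE)
  invisible(c(spectra_path, conc_path))
}

#' Read a dataset from the spectra/concentration CSV pair
#'
#' Validates that both files describe the same samples in the same order
#' (mismatched IDs are reported explicitly) and that the wavenumber header
#' is strictly monotone descending.
#'
#' @param spectra_path,conc_path CSV paths as written by [write_dataset()].
#' @return A [nutri_dataset()] with `provenance` recording the file origin.
#' @export
read_dataset <- function(spectra_path, conc_path) {
  sp <- utils::read.csv(spectra_path, check.names = FALSE)
  co <- utils::read.csv(conc_path, check.names = FALSE)
  if (!identical(names(sp)[1:2], c("sample_id", "source"))) {
    stop_nutrispec("spectra file must start with columns sample_id, source")
  }
  if (names(co)[1] != "sample_id") {
    stop_nutrispec("concentration file must start with column sample_id")
  }
  only_sp <- setdiff(sp$sample_id, co$sample_id)
  only_co <- setdiff(co$sample_id, sp$sample_id)
  if (length(only_sp) > 0 || length(only_co) > 0) {
    stop_nutrispec(
      "sample IDs disagree between files; ",
      if (length(only_sp) > 0)
        paste0("missing from concentrations: ",
               paste(only_sp, collapse = ", "), "; ") else "",
      if (length(only_co) > 0)
        paste0("missing from spectra: ",
               paste(only_co, collapse = ", ")) else "")
  }
  co <- co[match(sp$sample_id, co$sample_id), , drop = FALSE]
  wn <- suppressWarnings(as.numeric(names(sp)[-(1:2)]))
  if (anyNA(wn)) stop_nutrispec("non-numeric wavenumber column header(s)")
  if (any(diff(wn) >= 0)) {
    stop_nutrispec("wavenumber header must be strictly descending")
  }
  spectra <- as.matrix(sp[, -(1:2), drop = FALSE])
  rownames(spectra) <- sp$sample_id
  conc <- as.matrix(co[, -1, drop = FALSE])
  rownames(conc) <- co$sample_id
  nutri_dataset(spectra, conc, sp$source,
                provenance = list(spectra_path = spectra_path,
                                  conc_path = conc_path))
}

#' Write a run report to JSON
#'
#' Numbers are serialized at full precision; rounding happens only in
#' human-readable views.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run report back from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return A `run_report` object (lists in place of data frames are
#'   restored for the per-analyte table).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw, class = "run_report")
}
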
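psm_required_cols <- c("spectrum_id", "run_id", "peptide", "charge",
                       "modifications", "proteins", "is_decoy",
                       "is_contaminant", "has_tmt_label", "pep", "purity")

#' Read a PSM table
#'
#' Tab-separated with a header. Required columns: `spectrum_id`, `run_id`,
#' `peptide`, `charge`, `modifications`, `proteins` (semicolon-separated
#' accessions), `is_decoy`, `is_contaminant`, `has_tmt_label`, `pep`,
#' `purity`, plus one `intensity_<channel>` column per reporter channel. An
#' empty intensity cell is a missing measurement (`NA`), distinct from a
#' measured zero. Row order is preserved so error messages can reference
#' line numbers.
#'
#' @param path Path to the TSV file.
#' @return A PSM tibble.
#' @export
read_psm_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(psm_required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("PSM table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "secretr_schema_error")
  }
  icols <- grep("^intensity_", names(df), value = TRUE)
  if (length(icols) == 0) {
    abort("PSM table has no intensity_<channel> columns.",
          class = "secretr_schema_error")
  }
  for (cl in c(icols, "pep", "purity")) {
    v <- df[[cl]]
    if (is.logical(v) && all(is.na(v))) {
      df[[cl]] <- as.numeric(v)  # all-empty column
    } else if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0) {
        abort(sprintf("Non-numeric value in column `%s` at data row %d.",
                      cl, bad[1]),
              class = "secretr_schema_error")
      }
      df[[cl]] <- suppressWarnings(as.numeric(v))
    }
  }
  if (nrow(df) == 0) warn(sprintf("PSM table `%s` has zero rows.", path))
  df |>
    mutate(
      spectrum_id = as.character(.data$spectrum_id),
      run_id = as.character(.data$run_id),
      peptide = as.character(.data$peptide),
      charge = as.integer(.data$charge),
      modifications = dplyr::coalesce(as.character(.data$modifications), ""),
      proteins = as.character(.data$proteins),
      is_decoy = as.logical(.data$is_decoy),
      is_contaminant = as.logical(.data$is_contaminant),
      has_tmt_label = as.logical(.data$has_tmt_label),
      pep = as.numeric(.data$pep),
      purity = as.numeric(.data$purity)
    )
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; missing intensities become empty cells.
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @return `psms`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms, path, na = "", progress = FALSE)
  invisible(psms)
}

#' Read a protein annotation table
#'
#' TSV with columns `accession`, `has_signal_peptide`, `has_tm_domain`.
#'
#' @param path Path to the TSV file.
#' @return An annotation tibble.
#' @export
read_annotation_table <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  need <- c("accession", "has_signal_peptide", "has_tm_domain")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Annotation table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "secretr_schema_error")
  }
  if (anyDuplicated(df$accession)) {
    abort("Annotation accessions must be unique.", class = "secretr_schema_error")
  }
  df |>
    mutate(accession = as.character(.data$accession),
           has_signal_peptide = as.logical(.data$has_signal_peptide),
           has_tm_domain = as.logical(.data$has_tm_domain))
}
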
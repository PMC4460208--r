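# Dissolution datasets are plain tibbles with one row per observation:
#   formulation_id (chr), d_mm, L_mm, t_min, Q_pct
# plus a "provenance" attribute tracking which transform produced them
# (original / noised / balanced / scaled / enhanced / synthetic). dplyr
# verbs may drop the attribute; it is bookkeeping, not semantics.

.dissolution_cols <- c("formulation_id", "d_mm", "L_mm", "t_min", "Q_pct")

#' Validate a dissolution dataset
#'
#' Checks the five-column record contract: positive geometry, nonnegative
#' times, Q in \[0, 110\] (a small assay overshoot above 100% is
#' tolerated), and identical (d, L) within each formulation.
#'
#' @param ds A data frame of dissolution records.
#' @param provenance Optional provenance tag to stamp on the result.
#' @return The dataset as a tibble, invisibly validated.
#' @export
validate_dissolution_data <- function(ds, provenance = NULL) {
  assert_that(is.data.frame(ds), "ds must be a data frame")
  missing_cols <- setdiff(.dissolution_cols, names(ds))
  assert_that(length(missing_cols) == 0,
              paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
              "dissolvegp_format_error")
  assert_that(nrow(ds) > 0, "dataset must be nonempty", "dissolvegp_format_error")
  num_cols <- c("d_mm", "L_mm", "t_min", "Q_pct")
  for (col in num_cols) {
    bad <- which(!is.finite(ds[[col]]) & !is.na(ds[[col]]))
    assert_that(length(bad) == 0,
                sprintf("non-numeric value in column %s at row %d", col, bad[1]),
                "dissolvegp_parse_error")
  }
  assert_that(all(ds$d_mm > 0, na.rm = TRUE), "d_mm must be > 0",
              "dissolvegp_validation_error")
  assert_that(all(ds$L_mm > 0, na.rm = TRUE), "L_mm must be > 0",
              "dissolvegp_validation_error")
  assert_that(all(ds$t_min >= 0, na.rm = TRUE), "t_min must be >= 0",
              "dissolvegp_validation_error")
  bad_q <- which(ds$Q_pct < 0 | ds$Q_pct > 110)
  assert_that(length(bad_q) == 0,
              sprintf("Q_pct outside [0, 110] at row %d", bad_q[1]),
              "dissolvegp_validation_error")
  out <- as_tibble(ds)
  if (!is.null(provenance)) attr(out, "provenance") <- provenance
  out
}

#' Provenance tag of a dataset
#'
#' @param ds A dissolution dataset.
#' @return The provenance string, or `NA` if the attribute was lost.
#' @export
provenance <- function(ds) {
  attr(ds, "provenance") %||% NA_character_
}

set_provenance <- function(ds, tag) {
  attr(ds, "provenance") <- tag
  ds
}

#' Read a dissolution dataset from CSV
#'
#' The CSV dialect is one header row with columns
#' `formulation_id,d_mm,L_mm,t_min,Q_pct`, UTF-8, RFC 4180. Each row is one
#' (formulation, time, release) observation.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of records with provenance `"original"`.
#' @export
read_dissolution_csv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path),
              "dissolvegp_format_error")
  ds <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      formulation_id = readr::col_character(),
                      d_mm = readr::col_double(),
                      L_mm = readr::col_double(),
                      t_min = readr::col_double(),
                      Q_pct = readr::col_double()
                    ))),
    error = function(e) abort(paste0("cannot parse CSV: ", conditionMessage(e)),
                              class = "dissolvegp_format_error")
  )
  assert_that(nrow(ds) > 0, "empty dissolution file", "dissolvegp_format_error")
  probs <- readr::problems(ds)
  if (nrow(probs) > 0) {
    abort(sprintf("non-numeric cell at data row %d (column %d)",
                  probs$row[1], probs$col[1]),
          class = "dissolvegp_parse_error")
  }
  validate_dissolution_data(ds, provenance = "original")
}

#' Write a dissolution dataset to CSV
#'
#' @param ds A dissolution dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(ds, path) {
  ds <- validate_dissolution_data(ds)
  readr::write_csv(ds[, .dissolution_cols], path, progress = FALSE)
  invisible(path)
}

#' Formulation geometry table of a dataset
#'
#' @param ds A dissolution dataset.
#' @return A tibble with one row per formulation: `formulation_id`, `d_mm`,
#'   `L_mm`.
#' @export
formulations_of <- function(ds) {
  specs <- dplyr::distinct(ds, .data$formulation_id, .data$d_mm, .data$L_mm)
  dup <- specs$formulation_id[duplicated(specs$formulation_id)]
  assert_that(length(dup) == 0,
              paste0("formulation(s) with inconsistent geometry: ",
                     paste(unique(dup), collapse = ", ")),
              "dissolvegp_validation_error")
  dplyr::arrange(specs, .data$formulation_id)
}
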
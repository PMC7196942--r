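#' Read and validate a vessel assessment CSV
#'
#' UTF-8, comma-separated, header row required, `.` decimal point, empty
#' fields as missing. Columns: `patient_id`, `vessel`, `side`, `modality`,
#' `stenosis_percent`, `grade`, `blood_flow_ml_min`. Validation errors carry
#' row numbers.
#'
#' @param path Path to the CSV.
#' @return Validated vessel tibble (see [validate_vessels()]).
#' @export
read_vessel_csv <- function(path) {
  d <- read_casus_csv(path)
  validate_vessels(d)
}

#' Read and validate an endpoint CSV
#'
#' Columns: `patient_id`, `event_type`, `event_day`, `followup_end_day`,
#' `lost_to_followup`.
#'
#' @param path Path to the CSV.
#' @return Validated endpoint tibble (see [validate_endpoints()]).
#' @export
read_endpoint_csv <- function(path) {
  d <- read_casus_csv(path)
  validate_endpoints(d)
}

read_casus_csv <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Input file does not exist: %s", path))
  }
  d <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA")),
    error = function(e) abort_validation(sprintf(
      "Could not parse %s as CSV: %s", path, conditionMessage(e)))
  )
  if (nrow(d) == 0) {
    abort_validation(sprintf("Input file is empty: %s", path))
  }
  d
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    abort_validation(sprintf(
      "Output %s exists; pass force = TRUE to overwrite.", path))
  }
  invisible(path)
}

write_casus_csv <- function(d, path, force = FALSE) {
  check_overwrite(path, force)
  readr::write_csv(d, path, na = "")
  invisible(path)
}
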
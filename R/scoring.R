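VESSEL_NAMES <- c("CCA", "ICA", "VA")
SIDES <- c("left", "right")
MODALITIES <- c("ultrasound", "angiography")

#' Validate and normalise a vessel assessment table
#'
#' Checks the one-row-per-vessel table produced by duplex ultrasound or
#' CTA/MRA reading: recognised vessel/side/modality labels, grade labels,
#' no duplicate (patient, vessel, side, modality) rows, grade-percent
#' consistency, non-negative flow, and the occlusion convention (an occluded
#' vessel has zero flow). Adds the per-vessel stenosis score `ss` computed by
#' the narrowest-segment rule.
#'
#' Multi-segment vessels encode their segment grades in the `grade` column
#' separated by `;` (e.g. `"mild;severe"`); the highest grade governs.
#' When both `grade` and `stenosis_percent` are present, the grade must agree
#' with the category implied by the percent; disagreement is an error, never
#' silently resolved. When only the percent is present the grade is derived
#' from it.
#'
#' @param vessels Data frame with columns `patient_id`, `vessel`, `side`,
#'   `modality`, and at least one of `grade`, `stenosis_percent`; optionally
#'   `blood_flow_ml_min`.
#' @return A tibble with harmonised types and an added integer `ss` column.
#' @export
validate_vessels <- function(vessels) {
  required <- c("patient_id", "vessel", "side", "modality")
  missing_cols <- setdiff(required, names(vessels))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("Vessel table lacks column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(vessels) == 0) {
    abort_validation("Vessel table is empty.")
  }
  if (!"grade" %in% names(vessels)) vessels$grade <- NA_character_
  if (!"stenosis_percent" %in% names(vessels)) vessels$stenosis_percent <- NA_real_
  if (!"blood_flow_ml_min" %in% names(vessels)) vessels$blood_flow_ml_min <- NA_real_

  v <- tibble::as_tibble(vessels)
  v$patient_id <- as.character(v$patient_id)
  v$vessel <- toupper(trimws(as.character(v$vessel)))
  v$side <- tolower(trimws(as.character(v$side)))
  v$modality <- tolower(trimws(as.character(v$modality)))
  v$grade <- as.character(v$grade)
  v$grade[!is.na(v$grade) & trimws(v$grade) == ""] <- NA_character_
  v$stenosis_percent <- as.numeric(v$stenosis_percent)
  v$blood_flow_ml_min <- as.numeric(v$blood_flow_ml_min)

  check_levels <- function(x, levels, what) {
    bad <- which(!is.na(x) & !x %in% levels)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Row %s: %s %s not one of {%s}.",
        paste(bad, collapse = ", "), what,
        paste(unique(x[bad]), collapse = ", "),
        paste(levels, collapse = ", ")
      ))
    }
  }
  check_levels(v$vessel, VESSEL_NAMES, "vessel")
  check_levels(v$side, SIDES, "side")
  check_levels(v$modality, MODALITIES, "modality")

  dup <- duplicated(v[c("patient_id", "vessel", "side", "modality")])
  if (any(dup)) {
    abort_validation(sprintf(
      "Duplicate (patient, vessel, side, modality) row(s): %s.",
      paste(which(dup), collapse = ", ")
    ))
  }

  if (any(!is.na(v$stenosis_percent) &
          (v$stenosis_percent < 0 | v$stenosis_percent > 100))) {
    bad <- which(!is.na(v$stenosis_percent) &
                   (v$stenosis_percent < 0 | v$stenosis_percent > 100))
    abort_validation(sprintf("Row %s: stenosis_percent outside [0, 100].",
                             paste(bad, collapse = ", ")))
  }
  if (any(!is.na(v$blood_flow_ml_min) & v$blood_flow_ml_min < 0)) {
    bad <- which(!is.na(v$blood_flow_ml_min) & v$blood_flow_ml_min < 0)
    abort_validation(sprintf("Row %s: negative blood flow.",
                             paste(bad, collapse = ", ")))
  }

  # narrowest-segment rule; percent fallback; consistency when both present
  grade_ss <- purrr::map_int(strsplit(v$grade, ";", fixed = TRUE), function(g) {
    if (length(g) == 0 || all(is.na(g))) return(NA_integer_)
    vessel_ss(g)
  })
  pct_ss <- grade_score(grade_from_percent(v$stenosis_percent))
  both <- !is.na(grade_ss) & !is.na(pct_ss)
  if (any(both & grade_ss != pct_ss)) {
    bad <- which(both & grade_ss != pct_ss)
    abort_validation(sprintf(
      "Row %s: grade and stenosis_percent disagree (no silent resolution).",
      paste(bad, collapse = ", ")
    ))
  }
  v$ss <- dplyr::coalesce(grade_ss, pct_ss)
  if (any(is.na(v$ss))) {
    abort_validation(sprintf(
      "Row %s: neither grade nor stenosis_percent supplied.",
      paste(which(is.na(v$ss)), collapse = ", ")
    ))
  }

  occluded_with_flow <- v$ss == 4L & !is.na(v$blood_flow_ml_min) &
    v$blood_flow_ml_min > 0
  if (any(occluded_with_flow)) {
    abort_validation(sprintf(
      "Row %s: occluded vessel with non-zero blood flow.",
      paste(which(occluded_with_flow), collapse = ", ")
    ))
  }
  v$blood_flow_ml_min[v$ss == 4L] <- 0
  v
}

tss_one <- function(ss, vessel, side, vessel_set, strict, patient_id = "?") {
  expected <- 2L * length(vessel_set)
  keep <- vessel %in% vessel_set
  n_found <- sum(keep)
  if (n_found < expected) {
    msg <- sprintf(
      "Patient %s: %d of %d vessels assessed; missing vessels scored as grade none.",
      patient_id, n_found, expected
    )
    if (strict) abort_validation(msg) else rlang::warn(msg)
  }
  sum(ss[keep])
}

#' Total stenosis score of one patient
#'
#' Sums the per-vessel stenosis scores over the bilateral vessel set — by
#' default the common carotid, internal carotid and vertebral arteries, so the
#' score ranges 0-24. Applied to ultrasound rows this is the TSS; applied with
#' `modality = "angiography"` to CTA/MRA rows, the identical rule yields the
#' radiological-imaging total (RI-TSS).
#'
#' @param vessels Vessel table for a single patient (see [validate_vessels()]).
#' @param modality `"ultrasound"` (TSS) or `"angiography"` (RI-TSS).
#' @param vessel_set Vessel names contributing bilaterally (default
#'   `c("CCA", "ICA", "VA")`).
#' @param strict If `TRUE`, a missing contributing vessel is an error; the
#'   default scores missing vessels as grade none with a warning.
#' @return Integer total stenosis score.
#' @examples
#' v <- tibble::tibble(
#'   patient_id = "p1", vessel = c("ICA", "ICA"), side = c("left", "right"),
#'   modality = "ultrasound", grade = c("severe", "mild")
#' )
#' suppressWarnings(total_stenosis_score(v, vessel_set = "ICA"))
#' @export
total_stenosis_score <- function(vessels, modality = "ultrasound",
                                 vessel_set = c("CCA", "ICA", "VA"),
                                 strict = FALSE) {
  v <- validate_vessels(vessels)
  if (length(unique(v$patient_id)) > 1) {
    abort_validation("`total_stenosis_score()` expects one patient; use `score_patients()` for a cohort.")
  }
  v <- v[v$modality == modality, ]
  tss_one(v$ss, v$vessel, v$side, vessel_set, strict, v$patient_id[1] %||% "?")
}

gbf_one <- function(ss, flow, vessel, vessel_set, strict, patient_id = "?") {
  keep <- vessel %in% vessel_set
  expected <- 2L * length(vessel_set)
  ss <- ss[keep]; flow <- flow[keep]
  problem <- NULL
  if (sum(keep) < expected) {
    problem <- sprintf("only %d of %d flow-contributing vessels present",
                       sum(keep), expected)
  } else if (any(is.na(flow) & ss < 4L)) {
    problem <- "blood flow missing on a non-occluded contributing vessel"
  }
  if (!is.null(problem)) {
    msg <- sprintf("Patient %s: %s; GBF not computed (no imputation).",
                   patient_id, problem)
    if (strict) abort_validation(msg) else {
      rlang::warn(msg)
      return(NA_real_)
    }
  }
  flow[ss == 4L] <- 0
  sum(flow)
}

#' Global blood flow of one patient
#'
#' Sums the measured volumetric flows over the bilateral flow-contributing
#' vessels — by default the internal carotid and vertebral arteries, the
#' vessels whose flow the ultrasound protocol records. An occluded vessel has
#' no detectable flow and contributes 0 by convention. A missing flow on a
#' non-occluded contributing vessel is never imputed: it is an error in strict
#' mode and yields `NA` with a warning otherwise.
#'
#' @param vessels Vessel table (ultrasound rows) for a single patient.
#' @param vessel_set Flow-contributing vessels (default `c("ICA", "VA")`).
#' @param strict Error instead of `NA` + warning on missing data.
#' @return Total flow in mL/min.
#' @export
global_blood_flow <- function(vessels, vessel_set = c("ICA", "VA"),
                              strict = FALSE) {
  v <- validate_vessels(vessels)
  if (length(unique(v$patient_id)) > 1) {
    abort_validation("`global_blood_flow()` expects one patient; use `score_patients()` for a cohort.")
  }
  v <- v[v$modality == "ultrasound", ]
  gbf_one(v$ss, v$blood_flow_ml_min, v$vessel, vessel_set, strict,
          v$patient_id[1] %||% "?")
}

#' Score a cohort: TSS, RI-TSS and GBF per patient
#'
#' The cohort-level driver: validates the vessel table, then per patient sums
#' ultrasound stenosis scores into the TSS, angiography scores (when CTA/MRA
#' rows are present) into the RI-TSS, and ultrasound flows into the GBF.
#' Missing-vessel handling follows [total_stenosis_score()] and
#' [global_blood_flow()]; warnings are aggregated across patients.
#'
#' @param vessels Vessel table for any number of patients.
#' @param tss_vessels Bilateral vessel set entering the stenosis total
#'   (default CCA + ICA + VA, score range 0-24).
#' @param gbf_vessels Bilateral vessel set entering the flow total
#'   (default ICA + VA).
#' @param strict Error on any missing vessel or flow instead of warning.
#' @return Tibble with one row per patient: `patient_id`, `tss`, `ri_tss`
#'   (`NA` when no angiography rows), `gbf_ml_min`.
#' @export
score_patients <- function(vessels, tss_vessels = c("CCA", "ICA", "VA"),
                           gbf_vessels = c("ICA", "VA"), strict = FALSE) {
  v <- validate_vessels(vessels)
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  us <- v[v$modality == "ultrasound", ]
  ang <- v[v$modality == "angiography", ]
  ids <- unique(v$patient_id)

  res <- collect(
    dplyr::reframe(
      dplyr::group_by(us, .data$patient_id),
      tss = tss_one(.data$ss, .data$vessel, .data$side, tss_vessels, strict,
                    .data$patient_id[1]),
      gbf_ml_min = gbf_one(.data$ss, .data$blood_flow_ml_min, .data$vessel,
                           gbf_vessels, strict, .data$patient_id[1])
    )
  )
  if (nrow(ang) > 0) {
    ri <- collect(
      dplyr::reframe(
        dplyr::group_by(ang, .data$patient_id),
        ri_tss = tss_one(.data$ss, .data$vessel, .data$side, tss_vessels,
                         strict, .data$patient_id[1])
      )
    )
    res <- dplyr::left_join(res, ri, by = "patient_id")
  } else {
    res$ri_tss <- NA_integer_
  }
  res <- dplyr::left_join(tibble::tibble(patient_id = ids), res,
                          by = "patient_id")
  if (length(warnings_seen) > 0) {
    rlang::warn(c(
      sprintf("%d incomplete patient record(s) while scoring:",
              length(warnings_seen)),
      utils::head(warnings_seen, 5),
      if (length(warnings_seen) > 5) sprintf("... and %d more",
                                             length(warnings_seen) - 5)
    ))
  }
  res[c("patient_id", "tss", "ri_tss", "gbf_ml_min")]
}
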
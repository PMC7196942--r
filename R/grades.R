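#' Stenosis grade labels in score order
#'
#' The five-level ultrasound grading of a carotid or vertebral artery:
#' no stenosis, mild (<50 % lumen narrowing), moderate (50-69 %), severe
#' (70-99 %) and occlusion (100 %), scored 0-4 respectively.
#'
#' @format Character vector of length 5, ordered by score.
#' @export
casus_grade_levels <- c("none", "mild", "moderate", "severe", "occlusion")

as_grade <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    return(grade_from_score(x))
  }
  x <- tolower(trimws(x))
  bad <- !is.na(x) & !x %in% casus_grade_levels
  if (any(bad)) {
    abort_validation(sprintf(
      "Unknown stenosis grade label(s): %s. Expected one of %s.",
      paste(unique(x[bad]), collapse = ", "),
      paste(casus_grade_levels, collapse = ", ")
    ))
  }
  factor(x, levels = casus_grade_levels, ordered = TRUE)
}

#' Convert stenosis grades to integer scores
#'
#' Fixed mapping none -> 0, mild -> 1, moderate -> 2, severe -> 3,
#' occlusion -> 4.
#'
#' @param grade Character vector or factor of grade labels.
#' @return Integer vector of scores in 0..4 (NA preserved).
#' @examples
#' grade_score(c("mild", "occlusion"))
#' @export
grade_score <- function(grade) {
  as.integer(as_grade(grade)) - 1L
}

#' Convert integer scores back to grade labels
#'
#' @param score Integer vector with values in 0..4.
#' @return Ordered factor of grade labels.
#' @export
grade_from_score <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 4 | score != round(score)))) {
    abort_domain("Stenosis scores must be integers in 0..4.")
  }
  factor(casus_grade_levels[as.integer(score) + 1L],
         levels = casus_grade_levels, ordered = TRUE)
}

#' Grade a stenosis from its percent lumen narrowing
#'
#' Applies the categorical grading used throughout the scale: 0 % -> none,
#' (0, 50) -> mild, \[50, 70) -> moderate, \[70, 100) -> severe and exactly
#' 100 % -> occlusion. Interval boundaries are half-open so that 50 is
#' moderate and 70 is severe, matching the printed category labels.
#'
#' @param percent Numeric vector of percent stenosis in \[0, 100\].
#' @return Ordered factor of grade labels (NA preserved).
#' @examples
#' grade_from_percent(c(0, 45, 50, 69.9, 70, 100))
#' @export
grade_from_percent <- function(percent) {
  if (any(!is.na(percent) & (percent < 0 | percent > 100))) {
    abort_domain("`percent` must lie in [0, 100].")
  }
  score <- dplyr::case_when(
    is.na(percent) ~ NA_integer_,
    percent == 0 ~ 0L,
    percent < 50 ~ 1L,
    percent < 70 ~ 2L,
    percent < 100 ~ 3L,
    TRUE ~ 4L
  )
  grade_from_score(score)
}

#' Stenosis score of one vessel from its segment grades
#'
#' A vessel may carry several stenotic segments; the narrowest segment (the
#' highest grade) governs the vessel's stenosis score.
#'
#' @param grades Non-empty character vector or factor of segment grades for a
#'   single vessel.
#' @return Integer score in 0..4.
#' @examples
#' vessel_ss(c("mild", "severe")) # 3
#' @export
vessel_ss <- function(grades) {
  grades <- grades[!is.na(grades)]
  if (length(grades) == 0) {
    abort_validation("A vessel needs at least one segment grade (use \"none\" if unaffected).")
  }
  max(grade_score(grades))
}
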
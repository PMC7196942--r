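#' Reference chart of vessel blood flow by stenosis grade
#'
#' Per-vessel, per-grade mean and SD of volumetric blood flow (mL/min) and of
#' the flow reduction relative to the no-stenosis mean, for the internal
#' carotid (ICA) and vertebral (VA) arteries. These published summary values
#' anchor both the calculated-stenosis-score validation statistic and the
#' synthetic cohort generator. For stenotic grades the flow mean is the
#' no-stenosis mean minus the grade's mean reduction; occlusion has zero flow
#' by convention and its reduction equals the full no-stenosis mean.
#'
#' @format Tibble with columns `vessel`, `grade`, `bf_mean`, `bf_sd`,
#'   `reduction_mean`, `reduction_sd` (flows in mL/min).
#' @export
casus_flow_chart <- tibble::tibble(
  vessel = rep(c("ICA", "VA"), each = 5),
  grade = rep(c("none", "mild", "moderate", "severe", "occlusion"), 2),
  reduction_mean = c(0, 109.1, 189.4, 301.0, 418.4,
                     0, 53.2, 86.5, 141.3, 172.2),
  reduction_sd = c(0, 76.3, 66.9, 63.8, 73.5,
                   0, 31.9, 30.7, 28.5, 32.9),
  bf_mean = c(418.4 - c(0, 109.1, 189.4, 301.0, 418.4),
              172.2 - c(0, 53.2, 86.5, 141.3, 172.2)),
  bf_sd = c(73.5, 76.3, 66.9, 63.8, 0,
            32.9, 31.9, 30.7, 28.5, 0)
)

#' Blood-flow reduction relative to the no-stenosis mean
#'
#' The difference between the mean flow of unaffected vessels and the mean
#' flow at a given stenosis grade. A negative reduction (grade mean above the
#' no-stenosis mean) is reported but flagged with a warning, since it usually
#' signals swapped inputs.
#'
#' @param mean_no_stenosis Mean flow of vessels without stenosis (mL/min).
#' @param mean_with_grade Mean flow of vessels at the grade of interest.
#' @return Flow reduction in mL/min.
#' @examples
#' bf_reduction(418.4, 309.3) # 109.1
#' @export
bf_reduction <- function(mean_no_stenosis, mean_with_grade) {
  if (any(mean_no_stenosis < 0) || any(mean_with_grade < 0)) {
    abort_domain("Flows must be non-negative.")
  }
  out <- mean_no_stenosis - mean_with_grade
  if (any(out < 0)) {
    rlang::warn("Negative blood-flow reduction: grade mean exceeds the no-stenosis mean.")
  }
  out
}

#' Calculated stenosis score
#'
#' The validation statistic for the 0-4 grading: a grade's mean flow
#' reduction divided by the reference reduction, defined as the mean
#' reduction of mild stenosis. By construction the mild grade scores exactly
#' 1; a grading is internally consistent when the quotients land near the
#' integer scores. Occlusion, whose flow cannot be measured, is fixed at 4 by
#' convention. Reported rounded to one decimal (half-up).
#'
#' @param reduction Mean flow reduction of the grade (mL/min).
#' @param reference_reduction Mean reduction of mild stenosis (mL/min); must
#'   be positive unless `is_occlusion`.
#' @param is_occlusion Logical; `TRUE` returns exactly 4.
#' @param digits Decimals for the reported value (default 1); `NA` to skip
#'   rounding.
#' @return Non-negative calculated score.
#' @examples
#' calculated_ss(189.4, 109.1) # 1.7
#' calculated_ss(301.0, 109.1) # 2.8
#' @export
calculated_ss <- function(reduction, reference_reduction,
                          is_occlusion = FALSE, digits = 1) {
  is_occlusion <- rep_len(is_occlusion, length(reduction))
  if (any(!is_occlusion & reference_reduction <= 0)) {
    abort_domain("`reference_reduction` must be positive (except for the occlusion convention).")
  }
  out <- ifelse(is_occlusion, 4, reduction / reference_reduction)
  if (is.na(digits)) out else round_half_up(out, digits)
}

#' Nearest-integer (approximate) stenosis score
#'
#' @param calculated Calculated score(s) from [calculated_ss()].
#' @param is_occlusion Logical; occlusion stays fixed at 4.
#' @return Integer score.
#' @export
approximate_ss <- function(calculated, is_occlusion = FALSE) {
  out <- as.integer(round_half_up(calculated, 0))
  out[rep_len(is_occlusion, length(out))] <- 4L
  out
}

#' Calculated and approximate stenosis scores for a whole flow chart
#'
#' Builds the per-vessel score-calculation chart: for each vessel the mild
#' reduction is the reference, each grade's quotient is the calculated score,
#' and its nearest integer the approximate score (occlusion fixed at 4).
#'
#' @param chart Flow chart shaped like [casus_flow_chart] (columns `vessel`,
#'   `grade`, `reduction_mean`).
#' @return Tibble with `vessel`, `grade`, `reduction_mean`, `calculated_ss`,
#'   `approximate_ss`.
#' @examples
#' stenosis_score_chart()
#' @export
stenosis_score_chart <- function(chart = casus_flow_chart) {
  chart |>
    dplyr::group_by(.data$vessel) |>
    dplyr::mutate(
      calculated_ss = calculated_ss(
        .data$reduction_mean,
        .data$reduction_mean[.data$grade == "mild"],
        is_occlusion = .data$grade == "occlusion"
      ),
      approximate_ss = approximate_ss(.data$calculated_ss,
                                      .data$grade == "occlusion")
    ) |>
    dplyr::ungroup() |>
    dplyr::select("vessel", "grade", "reduction_mean",
                  "calculated_ss", "approximate_ss")
}

#' Impute the SD of a within-group change from baseline
#'
#' The standard systematic-review imputation for the spread of a change when
#' only baseline and final SDs are reported:
#' `sqrt(sd1^2 + sd2^2 - 2 * corr * sd1 * sd2)`, where `corr` is the
#' baseline-final correlation.
#'
#' @param sd_baseline,sd_final Non-negative SDs on the same scale.
#' @param corr Baseline-final correlation in \[-1, 1\] (default 0.5, a common
#'   conservative choice; always set it explicitly when a better estimate
#'   exists).
#' @return Non-negative imputed SD of the change.
#' @examples
#' sd_of_change(3, 4, 0) # 5
#' @export
sd_of_change <- function(sd_baseline, sd_final, corr = 0.5) {
  if (any(sd_baseline < 0) || any(sd_final < 0)) {
    abort_domain("SDs must be non-negative.")
  }
  if (any(abs(corr) > 1)) {
    abort_domain("`corr` must lie in [-1, 1].")
  }
  sqrt(pmax(0, sd_baseline^2 + sd_final^2 - 2 * corr * sd_baseline * sd_final))
}

#' Bin patients into global-blood-flow quintiles
#'
#' Five groups split at the empirical 20th/40th/60th/80th percentiles; a
#' value tied with a cut point goes to the lower bin.
#'
#' @param gbf Numeric vector of global blood flows (mL/min).
#' @return Integer bin 1 (lowest flow) to 5 (highest).
#' @export
gbf_quintile <- function(gbf) {
  cuts <- stats::quantile(gbf, probs = c(0.2, 0.4, 0.6, 0.8), na.rm = TRUE,
                          names = FALSE)
  # right-closed intervals: ties with a cut point fall into the lower bin
  as.integer(cut(gbf, breaks = c(-Inf, cuts, Inf), right = TRUE))
}

#' Cohort descriptive summary
#'
#' Counts and percentages of stenotic vessels (overall and by vessel type),
#' endpoint event incidences, and patients binned into global-blood-flow
#' quintiles. Percentages are reported at one decimal, half-up.
#'
#' @param vessels Vessel table (see [validate_vessels()]); ultrasound rows are
#'   summarised.
#' @param endpoints Optional endpoint table (see [validate_endpoints()]).
#' @param scores Optional patient-score tibble from [score_patients()]; when
#'   given, a quintile column is added and group sizes reported.
#' @return List of tibbles of class `casus_summary`: `$vessels`, and when
#'   inputs allow, `$events` and `$gbf_quintiles`.
#' @export
cohort_summary <- function(vessels, endpoints = NULL, scores = NULL) {
  v <- validate_vessels(vessels)
  v <- v[v$modality == "ultrasound", ]
  if (nrow(v) == 0) abort_validation("No ultrasound rows to summarise.")

  by_type <- v |>
    dplyr::group_by(vessel = .data$vessel) |>
    dplyr::summarise(n_vessels = dplyr::n(),
                     n_stenotic = sum(.data$ss > 0), .groups = "drop")
  vs <- dplyr::bind_rows(
    tibble::tibble(vessel = "all", n_vessels = nrow(v),
                   n_stenotic = sum(v$ss > 0)),
    by_type
  ) |>
    dplyr::mutate(pct_stenotic = percent_of(.data$n_stenotic, .data$n_vessels))

  out <- list(vessels = vs)

  if (!is.null(endpoints)) {
    e <- validate_endpoints(endpoints)
    n_pat <- length(unique(e$patient_id))
    ev <- e |>
      dplyr::filter(!is.na(.data$event_type)) |>
      dplyr::group_by(event_type = .data$event_type) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$patient_id),
                       .groups = "drop") |>
      dplyr::mutate(pct = percent_of(.data$n, n_pat))
    lost <- sum(!duplicated(e$patient_id) & e$lost_to_followup)
    out$events <- dplyr::bind_rows(
      ev,
      tibble::tibble(event_type = "lost_to_followup", n = lost,
                     pct = percent_of(lost, n_pat))
    )
  }

  if (!is.null(scores)) {
    q <- gbf_quintile(scores$gbf_ml_min)
    out$gbf_quintiles <- tibble::tibble(quintile = q) |>
      dplyr::filter(!is.na(.data$quintile)) |>
      dplyr::count(.data$quintile, name = "n_patients")
  }
  structure(out, class = "casus_summary")
}

#' @export
print.casus_summary <- function(x, ...) {
  cat("Cohort summary\n\nStenotic vessels:\n")
  print(x$vessels)
  if (!is.null(x$events)) {
    cat("\nEndpoint events:\n")
    print(x$events)
  }
  if (!is.null(x$gbf_quintiles)) {
    cat("\nGBF quintile group sizes:\n")
    print(x$gbf_quintiles)
  }
  invisible(x)
}
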
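EVENT_TYPES <- c("recurrent_stroke", "cardiac_death", "noncardiac_death",
                 "nonfatal_mi")
DEATH_TYPES <- c("cardiac_death", "noncardiac_death")
ENDPOINT_NAMES <- c("all_cause_death", "cardiovascular_death",
                    "recurrent_stroke", "nonfatal_mi", "composite_cv")

#' Validate a follow-up endpoint table
#'
#' One row per event, plus a single (eventless) row for patients with no
#' event. Checks event types, day ordering (events on or before the
#' follow-up end), and that a death terminates the record: no event may
#' occur after a death.
#'
#' @param endpoints Data frame with columns `patient_id`, `event_type`
#'   (one of recurrent_stroke, cardiac_death, noncardiac_death, nonfatal_mi,
#'   or empty/NA), `event_day`, `followup_end_day`, `lost_to_followup`.
#' @return Normalised tibble.
#' @export
validate_endpoints <- function(endpoints) {
  required <- c("patient_id", "event_type", "event_day", "followup_end_day",
                "lost_to_followup")
  missing_cols <- setdiff(required, names(endpoints))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("Endpoint table lacks column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(endpoints) == 0) abort_validation("Endpoint table is empty.")
  e <- tibble::as_tibble(endpoints)
  e$patient_id <- as.character(e$patient_id)
  e$event_type <- as.character(e$event_type)
  e$event_type[!is.na(e$event_type) & trimws(e$event_type) == ""] <- NA_character_
  e$event_day <- as.numeric(e$event_day)
  e$followup_end_day <- as.numeric(e$followup_end_day)
  e$lost_to_followup <- as.logical(e$lost_to_followup)

  bad <- which(!is.na(e$event_type) & !e$event_type %in% EVENT_TYPES)
  if (length(bad) > 0) {
    abort_validation(sprintf("Row %s: unknown event_type.",
                             paste(bad, collapse = ", ")))
  }
  has_event <- !is.na(e$event_type)
  if (any(has_event & is.na(e$event_day))) {
    abort_validation("Events must carry an event_day.")
  }
  if (any(has_event & (e$event_day < 0 | e$event_day > e$followup_end_day))) {
    bad <- which(has_event & (e$event_day < 0 |
                                e$event_day > e$followup_end_day))
    abort_validation(sprintf(
      "Row %s: event_day outside [0, followup_end_day].",
      paste(bad, collapse = ", ")))
  }

  death_day <- e |>
    dplyr::filter(.data$event_type %in% DEATH_TYPES) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(death_day = min(.data$event_day), .groups = "drop")
  chk <- dplyr::inner_join(e[has_event, ], death_day, by = "patient_id")
  if (any(chk$event_day > chk$death_day)) {
    abort_validation("Inconsistent record: event after death.")
  }
  e
}

#' Classify follow-up endpoints at a horizon
#'
#' Reduces the event table to per-patient binary endpoint flags at a given
#' assessment day: a flag is true iff the qualifying event occurred on or
#' before the horizon. The primary endpoint is recurrence of symptomatic
#' stroke; the composite cardiovascular endpoint combines recurrent stroke,
#' cardiac death and non-fatal myocardial infarction (non-cardiac death does
#' not qualify); all-cause death counts any death. Patients lost to
#' follow-up before the horizon with no qualifying event are flagged
#' `censored_early` and are excluded from horizon-based denominators
#' downstream.
#'
#' @param endpoints Endpoint table (see [validate_endpoints()]).
#' @param horizon_day Assessment day: 30, 90 or 180 (default 180, the final
#'   assessment).
#' @return Tibble, one row per patient: logical columns `primary`,
#'   `recurrent_stroke`, `nonfatal_mi`, `all_cause_death`,
#'   `cardiovascular_death`, `composite_cv`, `censored_early`.
#' @export
classify_endpoints <- function(endpoints, horizon_day = 180) {
  if (!horizon_day %in% c(30, 90, 180)) {
    abort_domain("`horizon_day` must be one of 30, 90, 180.")
  }
  e <- validate_endpoints(endpoints)
  by_event <- function(types) {
    !is.na(e$event_type) & e$event_type %in% types &
      e$event_day <= horizon_day
  }
  flags <- tibble::tibble(
    patient_id = e$patient_id,
    recurrent_stroke = by_event("recurrent_stroke"),
    nonfatal_mi = by_event("nonfatal_mi"),
    all_cause_death = by_event(DEATH_TYPES),
    cardiovascular_death = by_event("cardiac_death"),
    end_day = e$followup_end_day,
    lost = e$lost_to_followup
  ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(c("recurrent_stroke", "nonfatal_mi",
                                     "all_cause_death", "cardiovascular_death"),
                                   any),
                     end_day = max(.data$end_day), lost = any(.data$lost),
                     .groups = "drop")
  flags |>
    dplyr::mutate(
      primary = .data$recurrent_stroke,
      composite_cv = .data$recurrent_stroke | .data$cardiovascular_death |
        .data$nonfatal_mi,
      any_event = .data$composite_cv | .data$all_cause_death,
      censored_early = .data$lost & .data$end_day < horizon_day &
        !.data$any_event
    ) |>
    dplyr::select("patient_id", "primary", "recurrent_stroke", "nonfatal_mi",
                  "all_cause_death", "cardiovascular_death", "composite_cv",
                  "censored_early")
}

#' AUC by the Mann-Whitney pair-counting statistic
#'
#' The area under the empirical ROC curve, computed in its rank
#' (Mann-Whitney) form: over all case-control pairs, a concordant pair
#' scores 1, a tie 0.5. The standard error uses the Hanley-McNeil
#' exponential-approximation formula.
#'
#' @param scores_pos Predictor values of the cases (event occurred).
#' @param scores_neg Predictor values of the controls.
#' @return One-row tibble: `auc`, `se`, `n_pos`, `n_neg`.
#' @examples
#' auc_mann_whitney(c(3, 5), c(1, 4)) # AUC 0.75
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  m <- length(scores_pos); n <- length(scores_neg)
  if (m == 0 || n == 0) abort_validation("Both score groups must be non-empty.")
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  tibble::tibble(auc = auc, se = hanley_mcneil_se(auc, m, n),
                 n_pos = m, n_neg = n)
}

#' Hanley-McNeil standard error of an AUC
#'
#' @param auc Estimated area under the curve.
#' @param n_pos,n_neg Case and control counts.
#' @return Standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt(pmax(0, auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties half), and vice versa. Column means both equal the AUC.
delong_placements <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(1 - psi),
       auc = mean(psi))
}

#' DeLong standard error of a single AUC
#'
#' The nonparametric (placement-value) variance estimate of the empirical
#' AUC.
#'
#' @param scores Predictor values.
#' @param labels Logical event indicator, same length.
#' @return Standard error.
#' @export
delong_se <- function(scores, labels) {
  labels <- as.logical(labels)
  p <- delong_placements(scores, labels)
  m <- sum(labels); n <- sum(!labels)
  sqrt(stats::var(p$v10) / m + stats::var(p$v01) / n)
}

#' Compare two correlated AUCs by the DeLong test
#'
#' Both predictors are scored on the same patients, so their AUCs are
#' correlated; the DeLong covariance of the placement values accounts for
#' the pairing. Two-sided normal p-value. Degenerate case: when the ROC
#' curves coincide (zero-variance difference with zero AUC difference, e.g.
#' a monotone transform of the same predictor) the difference is reported as
#' 0 with p = 1.
#'
#' @param scores_a,scores_b Predictor values on the same patients, higher =
#'   higher risk (negate a protective predictor first).
#' @param labels Logical event indicator.
#' @return One-row tibble: `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    abort_validation("Both predictors must be scored on the same patients as the labels.")
  }
  if (all(labels) || !any(labels)) {
    abort_validation("Need at least one case and one control.")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Best prediction point (Youden-optimal threshold)
#'
#' Scans the observed score values and returns the threshold maximising
#' Youden's J = sensitivity + specificity - 1. For a risk score
#' (`direction = "greater"`) a patient is called positive when
#' `score >= threshold`; for a protective measure such as global blood flow
#' (`direction = "less"`), when `score <= threshold`. Ties in J are broken
#' towards the smallest qualifying threshold (the threshold closest to
#' calling fewest patients positive is not sought; the reported value mirrors
#' integer clinical cutpoints). If no threshold does better than chance
#' (max J = 0) the smallest observed score is returned with a warning.
#'
#' @param scores Predictor values.
#' @param labels Logical event indicator.
#' @param direction `"greater"` (higher score = higher risk, default) or
#'   `"less"`.
#' @return One-row tibble: `threshold`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @examples
#' best_prediction_point(c(8, 9, 10, 1, 2, 3),
#'                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
best_prediction_point <- function(scores, labels,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    abort_validation("Need at least one case and one control.")
  }
  s <- if (direction == "less") -scores else scores
  cand <- sort(unique(s))
  j <- vapply(cand, function(thr) {
    sens <- mean(s[labels] >= thr)
    spec <- mean(s[!labels] < thr)
    sens + spec - 1
  }, numeric(1))
  if (max(j) <= 0) {
    rlang::warn("No threshold beats chance (max Youden J = 0); returning the smallest observed score.")
  }
  best <- cand[which.max(j)] # which.max takes the first = smallest threshold
  sens <- mean(s[labels] >= best)
  spec <- mean(s[!labels] < best)
  tibble::tibble(
    threshold = if (direction == "less") -best else best,
    youden_j = max(j), sensitivity = sens, specificity = spec
  )
}

#' Evaluate TSS, RI-TSS and GBF as prognostic predictors
#'
#' The full prognostic report: for every endpoint (all-cause death,
#' cardiovascular death, recurrent stroke, non-fatal myocardial infarction,
#' composite cardiovascular events) and every available predictor, the AUC
#' with Hanley-McNeil SE, normal-approximation 95 % CI (clipped to \[0, 1\]),
#' the best prediction point, and an accuracy flag (AUC >= 0.7, the
#' conventional cutoff for an accurate model). Global blood flow is
#' protective, so it enters the ROC negated and its best prediction point is
#' a lower bound. Pairwise DeLong comparisons between predictors are
#' reported per endpoint on the patients with both predictors available.
#' Endpoints with no events at the horizon are skipped with a warning;
#' patients lost to follow-up before the horizon without an event are
#' excluded.
#'
#' @param scores Patient-score tibble from [score_patients()] (columns
#'   `patient_id`, `tss`, `ri_tss`, `gbf_ml_min`).
#' @param endpoints Endpoint table (see [validate_endpoints()]).
#' @param horizon_day Assessment day (30, 90 or 180; default 180).
#' @param predictors Named character vector mapping predictor columns to
#'   their risk direction.
#' @return A `casus_roc_report`: `$roc` (one row per predictor x endpoint)
#'   and `$comparisons` (pairwise DeLong tests).
#' @export
evaluate_predictors <- function(scores, endpoints, horizon_day = 180,
                                predictors = c(tss = "greater",
                                               ri_tss = "greater",
                                               gbf_ml_min = "less")) {
  flags <- classify_endpoints(endpoints, horizon_day)
  d <- dplyr::inner_join(scores, flags, by = "patient_id") |>
    dplyr::filter(!.data$censored_early)
  predictors <- predictors[names(predictors) %in% names(d)]
  predictors <- predictors[vapply(names(predictors),
                                  function(p) any(!is.na(d[[p]])), logical(1))]
  if (length(predictors) == 0) abort_validation("No usable predictor columns.")

  roc_rows <- list(); cmp_rows <- list()
  for (ep in ENDPOINT_NAMES) {
    lab <- d[[ep]]
    if (sum(lab, na.rm = TRUE) == 0) {
      rlang::warn(sprintf("Endpoint %s has no events by day %d; skipped.",
                          ep, horizon_day))
      next
    }
    for (p in names(predictors)) {
      keep <- !is.na(d[[p]]) & !is.na(lab)
      s <- d[[p]][keep]; l <- lab[keep]
      if (sum(l) == 0 || sum(!l) == 0) next
      s_dir <- if (predictors[[p]] == "less") -s else s
      a <- auc_mann_whitney(s_dir[l], s_dir[!l])
      bpp <- suppressWarnings(
        best_prediction_point(s, l, direction = predictors[[p]]))
      roc_rows[[length(roc_rows) + 1]] <- tibble::tibble(
        endpoint = ep, predictor = p, auc = a$auc, se = a$se,
        ci_low = max(0, a$auc - 1.96 * a$se),
        ci_high = min(1, a$auc + 1.96 * a$se),
        bpp = bpp$threshold, n_pos = a$n_pos, n_neg = a$n_neg,
        accurate = a$auc >= 0.7
      )
    }
    pairs <- utils::combn(names(predictors), 2, simplify = FALSE)
    for (pr in pairs) {
      keep <- !is.na(d[[pr[1]]]) & !is.na(d[[pr[2]]]) & !is.na(lab)
      if (sum(lab[keep]) == 0 || sum(!lab[keep]) == 0) next
      sa <- d[[pr[1]]][keep]; sb <- d[[pr[2]]][keep]
      if (predictors[[pr[1]]] == "less") sa <- -sa
      if (predictors[[pr[2]]] == "less") sb <- -sb
      cmp <- compare_auc_delong(sa, sb, lab[keep])
      cmp_rows[[length(cmp_rows) + 1]] <- dplyr::mutate(
        cmp, endpoint = ep, predictor_a = pr[1], predictor_b = pr[2],
        .before = 1)
    }
  }
  if (length(roc_rows) == 0) abort_computation("No endpoint had events; nothing to report.")
  structure(
    list(roc = dplyr::bind_rows(roc_rows),
         comparisons = dplyr::bind_rows(cmp_rows),
         horizon_day = horizon_day),
    class = "casus_roc_report"
  )
}

#' @export
print.casus_roc_report <- function(x, ...) {
  cat(sprintf("Prognostic ROC report (horizon day %d)\n\n", x$horizon_day))
  print(x$roc, n = Inf)
  if (nrow(x$comparisons) > 0) {
    cat("\nPairwise DeLong comparisons:\n")
    print(x$comparisons, n = Inf)
  }
  invisible(x)
}

#' @export
tidy.casus_roc_report <- function(x, ...) x$roc

#' @export
glance.casus_roc_report <- function(x, ...) {
  tibble::tibble(
    horizon_day = x$horizon_day,
    n_endpoints = length(unique(x$roc$endpoint)),
    n_predictors = length(unique(x$roc$predictor)),
    all_accurate = all(x$roc$accurate)
  )
}

#' @export
autoplot.casus_roc_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$endpoint, y = .data$auc,
                               colour = .data$predictor)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "AUC (95% CI)", x = NULL,
                  title = sprintf("Predictive value at day %d",
                                  object$horizon_day)) +
    ggplot2::theme_minimal()
}
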
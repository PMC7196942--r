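default_grade_probabilities <- function() {
  list(
    ICA = c(none = 0.13, mild = 0.44, moderate = 0.24, severe = 0.13,
            occlusion = 0.06),
    VA = c(none = 0.13, mild = 0.44, moderate = 0.24, severe = 0.13,
           occlusion = 0.06),
    CCA = c(none = 0.50, mild = 0.32, moderate = 0.12, severe = 0.05,
            occlusion = 0.01)
  )
}

#' Configuration for the synthetic stroke-cohort generator
#'
#' Defines the statistical structure of a simulated first-stroke cohort:
#' per-vessel stenosis-grade prevalences (defaults put ~87 % of carotid and
#' vertebral arteries in a stenotic grade, as in the study population the
#' generator emulates), per-grade Normal flow models anchored to the
#' published flow chart, a piecewise-cubic whole-brain compensation curve
#' with knots at total scores 5 and 10 that produces the inverse-S
#' flow-score relationship, logistic 180-day event models calibrated to
#' target incidences and a design AUC, and a loss-to-follow-up rate.
#'
#' @param n_patients Cohort size (default 750).
#' @param grade_probabilities Named list (`ICA`, `VA`, `CCA`) of probability
#'   vectors over the five grades; each must sum to 1.
#' @param flow_chart Per-vessel, per-grade flow means/SDs
#'   (default [casus_flow_chart]).
#' @param compensation Collateral-compensation curve parameters: `knots`
#'   (score thresholds, default `c(5, 10)`), `plateau_rescue` (mL/min of
#'   flow regained per score point across the plateau through collateral
#'   recruitment, default 56 — about 90 % of the uncompensated per-point
#'   loss, so the plateau declines only gently), `post_collapse` and
#'   `post_quad` (extra per-point loss and its acceleration once compensation
#'   is exhausted past the second knot, defaults 90 and 6), and `floor`
#'   (minimum planned global flow, default 30 mL/min). `NULL` disables
#'   compensation: flows then follow the per-grade chart independently.
#' @param incidence Named 180-day target incidences (defaults: recurrent
#'   stroke 0.077, all-cause death 0.052, non-fatal MI 0.034).
#' @param design_auc Target AUC of the total stenosis score for each
#'   endpoint (default 0.75).
#' @param cardiac_death_fraction Fraction of deaths that are cardiac
#'   (default 16/39).
#' @param loss_to_followup_prob Probability of loss to follow-up before day
#'   180 (default 0.024).
#' @param ri_mismatch_prob Probability that the angiographic (CTA/MRA) grade
#'   of a vessel differs by one category from the ultrasound grade
#'   (default 0.10).
#' @return A `casus_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 750,
                          grade_probabilities = default_grade_probabilities(),
                          flow_chart = casus_flow_chart,
                          compensation = list(knots = c(5, 10),
                                              plateau_rescue = 56,
                                              post_collapse = 90,
                                              post_quad = 6,
                                              floor = 30),
                          incidence = c(recurrent_stroke = 0.077,
                                        all_cause_death = 0.052,
                                        nonfatal_mi = 0.034),
                          design_auc = 0.75,
                          cardiac_death_fraction = 16 / 39,
                          loss_to_followup_prob = 0.024,
                          ri_mismatch_prob = 0.10) {
  if (n_patients < 1) abort_validation("`n_patients` must be at least 1.")
  for (v in names(grade_probabilities)) {
    p <- grade_probabilities[[v]]
    if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort_validation(sprintf(
        "Grade probabilities for %s must be 5 non-negative values summing to 1.", v))
    }
  }
  if (!is.null(compensation) &&
      !(length(compensation$knots) == 2 &&
          compensation$knots[1] < compensation$knots[2])) {
    abort_validation("Compensation knots must be an increasing pair.")
  }
  if (design_auc < 0.5 || design_auc >= 1) {
    abort_domain("`design_auc` must lie in [0.5, 1).")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         grade_probabilities = grade_probabilities,
         flow_chart = flow_chart,
         compensation = compensation,
         incidence = incidence,
         design_auc = design_auc,
         cardiac_death_fraction = cardiac_death_fraction,
         loss_to_followup_prob = loss_to_followup_prob,
         ri_mismatch_prob = ri_mismatch_prob),
    class = "casus_cohort_config"
  )
}

#' Collateral-compensation adjustment curve
#'
#' The whole-brain compensation term kappa(TSS) in mL/min, relative to the
#' uncompensated linear decline of global flow in the total stenosis score:
#' zero below the first knot (collaterals not yet recruited, sharp decline),
#' a linear flow rescue across the plateau between the knots, and an
#' accelerating loss past the second knot once the compensatory reserve is
#' exhausted. Added to the cohort's natural flow trend, it produces the
#' inverse-S global-flow curve with regime changes at the knots.
#'
#' @param tss Total stenosis scores.
#' @param compensation Parameter list (see [cohort_config()]); `NULL` means
#'   no compensation (returns zeros).
#' @return Compensation adjustment in mL/min.
#' @export
compensation_curve <- function(tss, compensation = cohort_config()$compensation) {
  if (is.null(compensation)) return(rep(0, length(tss)))
  # knots name the integer scores bounding the plateau regime (scores k1..k2
  # inclusive); on the continuous axis the regime changes between adjacent
  # integer scores, i.e. at k1 - 0.5 and k2 + 0.5
  a <- compensation$knots[1] - 0.5
  b <- compensation$knots[2] + 0.5
  u2 <- pmin(pmax(tss - a, 0), b - a)
  u3 <- pmax(tss - b, 0)
  compensation$plateau_rescue * u2 -
    compensation$post_collapse * u3 - compensation$post_quad * u3^2
}

#' Calibrate a logistic event model to an incidence and a design AUC
#'
#' The event model is `P(event) = plogis(intercept + slope * tss)`. The
#' slope is set from the binormal approximation: for a rare event the case
#' score distribution is shifted by about `slope * var(tss)`, giving
#' `AUC ~= pnorm(slope * sd(tss) / sqrt(2))`, hence
#' `slope = qnorm(design_auc) * sqrt(2) / sd(tss)`. The intercept is then
#' solved by root-finding so the expected incidence over the supplied score
#' distribution matches the target to within 1e-6.
#'
#' @param target_incidence Target event probability in (0, 1).
#' @param design_auc Target AUC in \[0.5, 1); 0.5 gives slope 0.
#' @param tss Empirical total-stenosis-score distribution to calibrate
#'   against.
#' @return Named numeric `c(intercept, slope)`.
#' @export
calibrate_event_model <- function(target_incidence, design_auc, tss) {
  if (target_incidence <= 0 || target_incidence >= 1) {
    abort_domain("`target_incidence` must lie strictly in (0, 1).")
  }
  if (design_auc < 0.5 || design_auc >= 1) {
    abort_domain("`design_auc` must lie in [0.5, 1).")
  }
  s <- stats::sd(tss)
  if (design_auc == 0.5) {
    slope <- 0
  } else if (is.na(s) || s == 0) {
    rlang::warn("Scores are constant; no discrimination is achievable (slope 0).")
    slope <- 0
  } else {
    slope <- stats::qnorm(design_auc) * sqrt(2) / s
  }
  f <- function(a) mean(stats::plogis(a + slope * tss)) - target_incidence
  root <- tryCatch(
    stats::uniroot(f, interval = c(-60, 60), tol = 1e-10),
    error = function(e) abort_computation(sprintf(
      "Event-model calibration failed for incidence %.4g (design AUC %.3g): %s",
      target_incidence, design_auc, conditionMessage(e)))
  )
  if (abs(f(root$root)) > 1e-6) {
    abort_computation("Calibrated incidence misses the target by more than 1e-6.")
  }
  c(intercept = root$root, slope = slope)
}

sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) + 1000003L * k) %% 2147483647L
}

#' Generate a synthetic stroke cohort
#'
#' Draws a full cohort with the statistical structure the scoring and
#' prognostic pipeline assumes: per-vessel stenosis grades, per-grade Normal
#' flows (truncated at zero; occlusion forces zero flow) whose vessel-grade
#' means track the flow chart while a whole-brain compensation term —
#' centred within each vessel-grade cell so the chart means stay the
#' marginal truth — shapes the global flow into the inverse-S curve;
#' angiographic re-grades with occasional one-category disagreement; and
#' 180-day endpoint events from logistic models in the total stenosis score
#' calibrated to the target incidences and design AUC. Deaths terminate the
#' record; losses to follow-up censor it.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the run is fully reproducible given
#'   (config, seed). Module-level sub-streams are derived from it.
#' @return A `casus_cohort` list: `$vessels` (12 rows per patient:
#'   ultrasound + angiography), `$endpoints`, and `$truth` (the generating
#'   parameters, for parameter-recovery checks).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "casus_cohort_config"))
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  chart <- config$flow_chart

  # -- grades ----------------------------------------------------------------
  set.seed(sub_seed(seed, 1L))
  frame <- tidyr::expand_grid(patient_id = ids,
                              vessel = c("CCA", "ICA", "VA"),
                              side = c("left", "right"))
  frame$grade <- NA_character_
  for (v in c("CCA", "ICA", "VA")) {
    rows <- frame$vessel == v
    frame$grade[rows] <- sample(casus_grade_levels, sum(rows), replace = TRUE,
                                prob = config$grade_probabilities[[v]])
  }
  frame$score <- grade_score(frame$grade)
  tss <- tapply(frame$score, frame$patient_id, sum)[ids]

  # -- angiographic re-grades ------------------------------------------------
  set.seed(sub_seed(seed, 2L))
  shift <- sample(c(-1L, 1L), nrow(frame), replace = TRUE) *
    (stats::runif(nrow(frame)) < config$ri_mismatch_prob)
  ri_score <- pmin(pmax(frame$score + shift, 0L), 4L)

  # -- flows: chart means, regulated toward the set-point curve --------------
  # Each patient's non-occluded flow-contributing vessels are rescaled by
  # f = g(TSS) / (sum of their chart means), so the expected global flow
  # tracks the inverse-S set point; dividing by the mean rescale factor of
  # each vessel-grade cell keeps the chart means the marginal truth.
  set.seed(sub_seed(seed, 3L))
  key <- paste(frame$vessel, frame$grade)
  mu <- chart$bf_mean[match(key, paste(chart$vessel, chart$grade))]
  sdv <- chart$bf_sd[match(key, paste(chart$vessel, chart$grade))]
  is_gbf <- frame$vessel %in% c("ICA", "VA")
  open <- is_gbf & frame$score < 4L
  if (is.null(config$compensation)) {
    mean_flow <- mu
  } else {
    # Each patient's planned flow sum is regulated to T(TSS) = natural
    # linear trend of the grade-implied sum + centred compensation kink.
    # The multiplicative factor f = T / (patient's own grade-implied sum) is
    # close to 1 in every vessel-grade cell, so a small additive centring
    # correction suffices to keep the chart means the marginal truth while
    # each patient's flows track the inverse-S curve.
    denom_p <- tapply(ifelse(open, mu, 0), frame$patient_id, sum)[ids]
    tss_num <- as.numeric(tss)
    # the grade-implied sum declines convexly in TSS (occlusions zero out
    # vessels); a quadratic trend keeps the rescale factor near 1 at every
    # score so only the kink term shapes the flow-score curve
    trend <- if (length(unique(tss_num)) >= 3) {
      stats::fitted(stats::lm(denom_p ~ tss_num + I(tss_num^2)))
    } else if (stats::sd(tss_num) > 0) {
      stats::fitted(stats::lm(denom_p ~ tss_num))
    } else {
      rep(mean(denom_p), n)
    }
    kap <- compensation_curve(tss_num, config$compensation)
    kap <- kap - mean(kap)
    target <- pmax(trend + kap, config$compensation$floor %||% 30)
    f_pat <- ifelse(denom_p > 0, target / denom_p, 1)
    f <- f_pat[match(frame$patient_id, ids)]
    mean_flow <- mu * f
    # alternate small adjustments until the planned means satisfy both
    # margins: every vessel-grade cell mean equals its chart value and every
    # patient's planned sum equals the set point (deterministic, converges in
    # a few sweeps)
    pid <- match(frame$patient_id, ids)
    w <- (mu / pmax(denom_p[pid], 1))[open]
    for (i in 1:15) {
      mean_flow[open] <- mean_flow[open] +
        (mu[open] - stats::ave(mean_flow[open], key[open]))
      sums <- rep(0, n)
      agg <- tapply(mean_flow[open], frame$patient_id[open], sum)
      sums[match(names(agg), ids)] <- agg
      resid <- (target - sums)[pid[open]]
      mean_flow[open] <- mean_flow[open] + resid * w
    }
    mean_flow <- pmax(mean_flow, 0)
  }
  # Within-patient flow fluctuations are negatively equicorrelated
  # (rho = -1/3): autoregulation redistributes flow, so a vessel running
  # below its expected flow is partly offset by the others. Marginal
  # per-vessel SDs are unchanged; the global-flow noise shrinks.
  z <- matrix(stats::rnorm(4L * n), nrow = n)
  z <- (z - rowMeans(z)) / sqrt(0.75)
  noise <- rep(NA_real_, nrow(frame))
  noise[is_gbf] <- t(z)[]  # row-major: patient-blocked, 4 GBF vessels each
  flow <- rep(NA_real_, nrow(frame))
  flow[is_gbf] <- pmax(0, mean_flow[is_gbf] + sdv[is_gbf] * noise[is_gbf])
  flow[is_gbf & frame$score == 4L] <- 0

  vessels <- dplyr::bind_rows(
    tibble::tibble(patient_id = frame$patient_id, vessel = frame$vessel,
                   side = frame$side, modality = "ultrasound",
                   stenosis_percent = NA_real_, grade = frame$grade,
                   blood_flow_ml_min = flow),
    tibble::tibble(patient_id = frame$patient_id, vessel = frame$vessel,
                   side = frame$side, modality = "angiography",
                   stenosis_percent = NA_real_,
                   grade = as.character(grade_from_score(ri_score)),
                   blood_flow_ml_min = NA_real_)
  ) |>
    dplyr::arrange(.data$patient_id, .data$modality, .data$vessel, .data$side)

  # -- endpoint events -------------------------------------------------------
  set.seed(sub_seed(seed, 4L))
  tss_num <- as.numeric(tss)
  models <- lapply(config$incidence, calibrate_event_model,
                   design_auc = config$design_auc, tss = tss_num)
  draw <- function(model) {
    stats::runif(n) < stats::plogis(model["intercept"] + model["slope"] * tss_num)
  }
  has_stroke <- draw(models$recurrent_stroke)
  has_death <- draw(models$all_cause_death)
  has_mi <- draw(models$nonfatal_mi)
  day_stroke <- sample(180L, n, replace = TRUE)
  day_death <- sample(180L, n, replace = TRUE)
  day_mi <- sample(180L, n, replace = TRUE)
  cardiac <- stats::runif(n) < config$cardiac_death_fraction
  lost <- stats::runif(n) < config$loss_to_followup_prob
  censor <- ifelse(lost, sample(179L, n, replace = TRUE), 180L)

  d_death <- ifelse(has_death, day_death, Inf)
  keep_stroke <- has_stroke & day_stroke <= pmin(d_death, censor)
  keep_mi <- has_mi & day_mi <= pmin(d_death, censor)
  keep_death <- has_death & day_death <= censor
  events <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[keep_stroke],
                   event_type = "recurrent_stroke",
                   event_day = as.numeric(day_stroke[keep_stroke])),
    tibble::tibble(patient_id = ids[keep_mi], event_type = "nonfatal_mi",
                   event_day = as.numeric(day_mi[keep_mi])),
    tibble::tibble(patient_id = ids[keep_death],
                   event_type = ifelse(cardiac[keep_death], "cardiac_death",
                                       "noncardiac_death"),
                   event_day = as.numeric(day_death[keep_death]))
  )
  eventless <- setdiff(ids, events$patient_id)
  endpoints <- dplyr::bind_rows(
    events,
    tibble::tibble(patient_id = eventless, event_type = NA_character_,
                   event_day = NA_real_)
  )
  idx <- match(endpoints$patient_id, ids)
  endpoints$followup_end_day <- as.numeric(censor[idx])
  endpoints$lost_to_followup <- lost[idx]
  endpoints <- dplyr::arrange(endpoints, .data$patient_id, .data$event_day)

  structure(
    list(vessels = vessels, endpoints = endpoints,
         truth = list(tss = stats::setNames(as.integer(tss), ids),
                      event_models = models,
                      design_auc = config$design_auc,
                      compensation = config$compensation,
                      incidence = config$incidence),
         config = config, seed = as.integer(seed)),
    class = "casus_cohort"
  )
}

#' @export
print.casus_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients (seed %d), %d vessel rows, %d endpoint rows\n",
    x$config$n_patients, x$seed, nrow(x$vessels), nrow(x$endpoints)))
  invisible(x)
}
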
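endpoints_row <- function(patient_id, event_type = NA_character_,
                          event_day = NA_real_, end_day = 180, lost = FALSE) {
  tibble::tibble(patient_id = patient_id, event_type = event_type,
                 event_day = event_day, followup_end_day = end_day,
                 lost_to_followup = lost)
}

test_that("endpoint flags follow the composite and horizon definitions", {
  e <- dplyr::bind_rows(
    endpoints_row("a", "recurrent_stroke", 45),
    endpoints_row("b", "noncardiac_death", 20),
    endpoints_row("c", end_day = 100, lost = TRUE),
    endpoints_row("d", "cardiac_death", 150),
    endpoints_row("e", "recurrent_stroke", 120)
  )
  f <- classify_endpoints(e, horizon_day = 180)
  f <- f[order(f$patient_id), ]
  expect_true(f$primary[f$patient_id == "a"])
  expect_true(f$composite_cv[f$patient_id == "a"])
  # non-cardiac death: all-cause yes, cardiovascular / composite no
  expect_true(f$all_cause_death[f$patient_id == "b"])
  expect_false(f$cardiovascular_death[f$patient_id == "b"])
  expect_false(f$composite_cv[f$patient_id == "b"])
  # lost early with no event: all flags false, marked censored
  expect_false(any(unlist(f[f$patient_id == "c",
                            c("primary", "composite_cv", "all_cause_death")])))
  expect_true(f$censored_early[f$patient_id == "c"])
  # cardiac death enters both death endpoints and the composite
  expect_true(f$cardiovascular_death[f$patient_id == "d"])
  expect_true(f$composite_cv[f$patient_id == "d"])
  # a day-120 event vanishes at the 90-day horizon
  f90 <- classify_endpoints(e, horizon_day = 90)
  expect_false(f90$primary[f90$patient_id == "e"])
  expect_error(classify_endpoints(e, horizon_day = 60),
               class = "casus_domain_error")
})

test_that("inconsistent records are rejected", {
  after_death <- dplyr::bind_rows(
    endpoints_row("a", "cardiac_death", 30),
    endpoints_row("a", "recurrent_stroke", 60)
  )
  expect_error(classify_endpoints(after_death),
               class = "casus_validation_error")
  late <- endpoints_row("b", "recurrent_stroke", 120, end_day = 90)
  expect_error(validate_endpoints(late), class = "casus_validation_error")
  expect_error(validate_endpoints(endpoints_row("c", "rapture", 10)),
               class = "casus_validation_error")
})

test_that("dropping early-censored patients never removes counted events", {
  co <- generate_cohort(cohort_config(n_patients = 400), seed = 13)
  f <- classify_endpoints(co$endpoints, 180)
  kept <- f[!f$censored_early, ]
  for (ep in c("recurrent_stroke", "all_cause_death", "composite_cv")) {
    expect_equal(sum(kept[[ep]]), sum(f[[ep]]))
  }
})

test_that("rank AUC equals brute-force pair counting and the trapezoid area", {
  expect_equal(auc_mann_whitney(c(3, 5), c(1, 4))$auc, 0.75)
  expect_equal(auc_mann_whitney(c(10, 11), c(1, 2))$auc, 1)
  expect_equal(auc_mann_whitney(rep(2, 5), rep(2, 7))$auc, 0.5)
  expect_error(auc_mann_whitney(numeric(0), 1:3),
               class = "casus_validation_error")
  set.seed(20200103)
  for (i in 1:50) {
    pos <- sample(0:6, sample(2:8, 1), replace = TRUE)
    neg <- sample(0:6, sample(2:8, 1), replace = TRUE)
    a <- auc_mann_whitney(pos, neg)$auc
    expect_equal(a, brute_auc(pos, neg))
    expect_equal(a, trapezoid_auc(pos, neg))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  pos <- rnorm(30, 1); neg <- rnorm(40)
  a0 <- auc_mann_whitney(pos, neg)$auc
  expect_equal(auc_mann_whitney(exp(pos), exp(neg))$auc, a0)
  expect_equal(auc_mann_whitney(2 * pos - 7, 2 * neg - 7)$auc, a0)
})

test_that("Hanley-McNeil and DeLong uncertainty estimates agree broadly", {
  set.seed(20200103)
  lab <- rep(c(TRUE, FALSE), c(120, 180))
  scores <- rnorm(300, mean = ifelse(lab, 0.8, 0))
  hm <- auc_mann_whitney(scores[lab], scores[!lab])$se
  dl <- delong_se(scores, lab)
  expect_lt(abs(hm - dl) / dl, 0.2)
})

test_that("DeLong comparison matches pROC and handles degenerate pairs", {
  set.seed(6)
  for (i in 1:15) {
    lab <- rep(c(TRUE, FALSE), c(12, 15))
    a <- rnorm(27, ifelse(lab, 0.8, 0))
    b <- 0.5 * a + rnorm(27, sd = 0.7)
    mine <- compare_auc_delong(a, b, lab)
    ra <- pROC::roc(lab, a, direction = "<", quiet = TRUE)
    rb <- pROC::roc(lab, b, direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(mine$auc_a, as.numeric(ra$auc))
  }
  s <- c(5, 4, 3, 2, 1, 0)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  same <- compare_auc_delong(s, s, lab)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)
  mono <- compare_auc_delong(s, exp(s), lab)
  expect_equal(mono$auc_diff, 0)
  expect_equal(mono$p_value, 1)
  expect_error(compare_auc_delong(s, s[-1], lab),
               class = "casus_validation_error")
  expect_error(compare_auc_delong(s, s, rep(TRUE, 6)),
               class = "casus_validation_error")
})

test_that("asymptotic DeLong p agrees with the permutation law at moderate n", {
  set.seed(20200103)
  n <- 40
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  a <- rnorm(n, mean = ifelse(lab, 1, 0))
  b <- 0.6 * a + rnorm(n, mean = ifelse(lab, 0.4, 0), sd = 0.8)
  p_dl <- compare_auc_delong(a, b, lab)$p_value
  p_perm <- perm_delong_p(a, b, lab, n_resamples = 2000, seed = 99)
  expect_lt(abs(p_dl - p_perm), 0.05)
})

test_that("the best prediction point maximises Youden's J", {
  b <- best_prediction_point(c(8, 9, 10, 1, 2, 3),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(b$threshold, 8)
  expect_equal(b$youden_j, 1)
  expect_equal(best_prediction_point(c(10, 1), c(TRUE, FALSE))$threshold, 10)
  # exhaustive check against a grid search
  set.seed(12)
  for (i in 1:20) {
    scores <- sample(0:12, 30, replace = TRUE)
    lab <- runif(30) < plogis(scores - 6)
    if (all(lab) || !any(lab)) next
    b <- suppressWarnings(best_prediction_point(scores, lab))
    js <- vapply(sort(unique(scores)), function(t) {
      mean(scores[lab] >= t) + mean(scores[!lab] < t) - 1
    }, numeric(1))
    expect_equal(b$youden_j, max(js))
  }
  # perfectly mixed scores cannot beat chance
  expect_warning(
    mixed <- best_prediction_point(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
    "chance"
  )
  expect_equal(mixed$threshold, 1)
  # protective direction: low flow flags risk
  b_less <- best_prediction_point(c(300, 400, 900, 1000),
                                  c(TRUE, TRUE, FALSE, FALSE),
                                  direction = "less")
  expect_equal(b_less$youden_j, 1)
  expect_lt(b_less$threshold, 900)
  expect_error(best_prediction_point(1:4, rep(FALSE, 4)),
               class = "casus_validation_error")
})

test_that("the predictor report covers endpoints, flags accuracy, compares AUCs", {
  co <- generate_cohort(cohort_config(n_patients = 400), seed = 17)
  scores <- score_patients(co$vessels)
  rep_ <- evaluate_predictors(scores, co$endpoints)
  expect_s3_class(rep_, "casus_roc_report")
  expect_setequal(unique(rep_$roc$predictor), c("tss", "ri_tss", "gbf_ml_min"))
  expect_true(all(rep_$roc$ci_low <= rep_$roc$auc & rep_$roc$auc <= rep_$roc$ci_high))
  expect_equal(rep_$roc$accurate, rep_$roc$auc >= 0.7)
  expect_equal(nrow(unique(rep_$comparisons[c("predictor_a", "predictor_b")])), 3)
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_s3_class(autoplot(rep_), "ggplot")
})

test_that("a flow predictor collinear with the score has identical AUC", {
  set.seed(21)
  n <- 200
  scores <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:n),
    tss = sample(0:15, n, replace = TRUE),
    ri_tss = NA_integer_
  )
  scores$gbf_ml_min <- 1500 - 80 * scores$tss
  e <- endpoints_row(scores$patient_id)
  hit <- runif(n) < plogis(0.4 * scores$tss - 4)
  e$event_type[hit] <- "recurrent_stroke"
  e$event_day[hit] <- 30
  rep_ <- suppressWarnings(evaluate_predictors(scores, e))
  rs <- rep_$roc[rep_$roc$endpoint == "recurrent_stroke", ]
  expect_equal(rs$auc[rs$predictor == "tss"],
               rs$auc[rs$predictor == "gbf_ml_min"])
  cmp <- rep_$comparisons
  tg <- cmp[cmp$endpoint == "recurrent_stroke" &
              cmp$predictor_a == "tss" & cmp$predictor_b == "gbf_ml_min", ]
  expect_equal(tg$p_value, 1)
})

test_that("endpoints with no events are skipped with a warning", {
  n <- 60
  scores <- tibble::tibble(patient_id = sprintf("p%02d", 1:n),
                           tss = sample(0:10, n, replace = TRUE),
                           ri_tss = NA_integer_, gbf_ml_min = rnorm(n, 800, 50))
  e <- endpoints_row(scores$patient_id)
  e$event_type[1:5] <- "recurrent_stroke"
  e$event_day[1:5] <- 10
  w <- testthat::capture_warnings(rep_ <- evaluate_predictors(scores, e))
  expect_true(any(grepl("no events", w)))
  expect_setequal(unique(rep_$roc$endpoint),
                  c("recurrent_stroke", "composite_cv"))
})

test_that("scores unrelated to outcome give chance-level AUC", {
  set.seed(20200103)
  n <- 4000
  pos <- sample(0:20, 400, replace = TRUE)
  neg <- sample(0:20, n - 400, replace = TRUE)
  expect_lt(abs(auc_mann_whitney(pos, neg)$auc - 0.5), 0.05)
})
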
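test_that("generation is reproducible for a fixed seed and varies across seeds", {
  a <- generate_cohort(cohort_config(n_patients = 60), seed = 31)
  b <- generate_cohort(cohort_config(n_patients = 60), seed = 31)
  c <- generate_cohort(cohort_config(n_patients = 60), seed = 32)
  expect_identical(a$vessels, b$vessels)
  expect_identical(a$endpoints, b$endpoints)
  expect_false(identical(a$vessels, c$vessels))
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n_patients = 0), class = "casus_validation_error")
  bad_probs <- default_probs <- cohort_config()$grade_probabilities
  bad_probs$ICA <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(cohort_config(grade_probabilities = bad_probs),
               class = "casus_validation_error")
  expect_error(cohort_config(design_auc = 1.2), class = "casus_domain_error")
  expect_error(
    cohort_config(compensation = list(knots = c(10, 5), plateau_rescue = 56)),
    class = "casus_validation_error"
  )
})

test_that("an all-healthy cohort has zero scores and baseline global flow", {
  gp <- lapply(cohort_config()$grade_probabilities, function(p) {
    c(none = 1, mild = 0, moderate = 0, severe = 0, occlusion = 0)
  })
  co <- suppressWarnings(
    generate_cohort(cohort_config(n_patients = 300, grade_probabilities = gp,
                                  ri_mismatch_prob = 0),
                    seed = 5)
  )
  scores <- score_patients(co$vessels)
  expect_true(all(scores$tss == 0))
  expect_true(all(scores$ri_tss == 0))
  # mean GBF near the four-vessel no-stenosis sum; negative equicorrelation
  # shrinks the patient-level spread well below the raw vessel-sum SD
  expect_lt(abs(mean(scores$gbf_ml_min) - 1181.2), 10)
})

test_that("event-model calibration hits the target incidence and design AUC", {
  set.seed(77)
  tss <- sample(0:18, 5000, replace = TRUE, prob = dpois(0:18, 7.5))
  m <- calibrate_event_model(0.077, 0.75, tss)
  expect_equal(mean(plogis(m["intercept"] + m["slope"] * tss)), 0.077,
               tolerance = 1e-6)
  expect_equal(unname(calibrate_event_model(0.1, 0.5, tss)["slope"]), 0)
  # larger design AUC needs a steeper slope
  slopes <- vapply(c(0.55, 0.65, 0.75, 0.85),
                   function(a) calibrate_event_model(0.077, a, tss)["slope"],
                   numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_error(calibrate_event_model(0, 0.75, tss),
               class = "casus_domain_error")
  expect_error(calibrate_event_model(0.077, 1, tss),
               class = "casus_domain_error")
  expect_warning(calibrate_event_model(0.077, 0.75, rep(5, 100)), "constant")
})

test_that("observed incidences converge to their targets at large n", {
  co <- generate_cohort(cohort_config(n_patients = 20000), seed = 7)
  f <- classify_endpoints(co$endpoints)
  expect_lt(abs(mean(f$recurrent_stroke) - 0.077), 0.01)
  expect_lt(abs(mean(f$all_cause_death) - 0.052), 0.01)
  expect_lt(abs(mean(f$nonfatal_mi) - 0.034), 0.01)
  # design AUC recovered tightly at this size
  s <- score_patients(co$vessels)
  d <- merge(s, f, by = "patient_id")
  d <- d[!d$censored_early, ]
  a <- auc_mann_whitney(d$tss[d$recurrent_stroke], d$tss[!d$recurrent_stroke])
  expect_lt(abs(a$auc - 0.75), 0.02)
})

test_that("a zero-slope event model carries no prognostic signal", {
  co <- generate_cohort(cohort_config(n_patients = 4000, design_auc = 0.5),
                        seed = 23)
  s <- score_patients(co$vessels)
  f <- classify_endpoints(co$endpoints)
  d <- merge(s, f, by = "patient_id")
  a <- auc_mann_whitney(d$tss[d$recurrent_stroke], d$tss[!d$recurrent_stroke])
  expect_lt(abs(a$auc - 0.5), 0.05)
})

test_that("per-grade vessel flows track the reference chart means", {
  co <- generate_cohort(cohort_config(), seed = 20200103)
  v <- co$vessels[co$vessels$modality == "ultrasound", ]
  v <- merge(v, casus_flow_chart, by = c("vessel", "grade"))
  v <- v[v$vessel %in% c("ICA", "VA") & v$grade != "occlusion", ]
  by_cell <- split(v, paste(v$vessel, v$grade))
  for (cell in by_cell) {
    n_c <- nrow(cell)
    expect_lt(abs(mean(cell$blood_flow_ml_min) - cell$bf_mean[1]),
              3 * cell$bf_sd[1] / sqrt(n_c) + 1e-9)
  }
  # occlusion always zero flow
  occl <- co$vessels[co$vessels$modality == "ultrasound" &
                       co$vessels$vessel %in% c("ICA", "VA") &
                       co$vessels$grade == "occlusion", ]
  expect_true(all(occl$blood_flow_ml_min == 0))
})

test_that("the breakpoint search finds the compensation knots when flows are deterministic", {
  co <- generate_cohort(noise_free_config(), seed = 20200103)
  s <- score_patients(co$vessels)
  seg <- suppressWarnings(fit_segmented(s))
  expect_equal(seg$breakpoints, c(5, 10))
})

test_that("angiographic re-grades disagree at about the configured rate", {
  co <- generate_cohort(cohort_config(n_patients = 500), seed = 3)
  us <- co$vessels[co$vessels$modality == "ultrasound", ]
  ang <- co$vessels[co$vessels$modality == "angiography", ]
  key <- function(d) paste(d$patient_id, d$vessel, d$side)
  ang <- ang[match(key(us), key(ang)), ]
  rate <- mean(us$grade != ang$grade)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
  expect_true(all(abs(grade_score(us$grade) - grade_score(ang$grade)) <= 1))
})
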
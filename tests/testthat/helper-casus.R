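# Shared fixtures and independent oracles, all built in code.

# one patient's six-vessel ultrasound table from named grades, e.g.
# make_vessels(ica_l = "severe", va_r = "mild")
make_vessels <- function(..., patient_id = "p1", modality = "ultrasound",
                         flows = NULL) {
  slots <- c(cca_l = "none", cca_r = "none", ica_l = "none", ica_r = "none",
             va_l = "none", va_r = "none")
  override <- list(...)
  slots[names(override)] <- unlist(override)
  v <- tibble::tibble(
    patient_id = patient_id,
    vessel = rep(c("CCA", "ICA", "VA"), each = 2),
    side = rep(c("left", "right"), 3),
    modality = modality,
    grade = unname(slots)
  )
  if (!is.null(flows)) v$blood_flow_ml_min <- flows
  v
}

# brute-force AUC oracle: explicit pair counting
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# studentized sign-swap permutation oracle for the paired AUC comparison
perm_delong_p <- function(a, b, labels, n_resamples = 10000, seed = 1) {
  z_obs <- abs(suppressWarnings(compare_auc_delong(a, b, labels)$z))
  set.seed(seed)
  n <- length(labels)
  cnt <- 0
  for (i in seq_len(n_resamples)) {
    sw <- stats::runif(n) < 0.5
    ap <- ifelse(sw, b, a)
    bp <- ifelse(sw, a, b)
    z <- suppressWarnings(compare_auc_delong(ap, bp, labels)$z)
    if (!is.finite(z)) z <- 0
    if (abs(z) >= z_obs - 1e-12) cnt <- cnt + 1
  }
  cnt / n_resamples
}

# noiseless three-regime polynomial with level jumps at the breakpoints, so
# the generating pair is the unique zero-error segmentation
piecewise_data <- function(t1 = 5, t2 = 10, reps = 3) {
  x <- rep(0:16, each = reps)
  y <- ifelse(
    x < t1, 1200 - 60 * x + 2 * x^2,
    ifelse(x <= t2, 820 - 8 * (x - t1) + 1.5 * (x - t1)^2,
           520 - 90 * (x - t2) - 4 * (x - t2)^2)
  )
  tibble::tibble(tss = x, gbf_ml_min = y)
}

# deterministic-flow, occlusion-light generator configuration: every planned
# flow is realised exactly, so the inverse-S curve is observed without noise
noise_free_config <- function(n_patients = 750) {
  chart0 <- casus_flow_chart
  chart0$bf_sd <- 0
  gp <- list(
    ICA = c(none = 0.15, mild = 0.47, moderate = 0.26, severe = 0.10,
            occlusion = 0.02),
    VA = c(none = 0.15, mild = 0.47, moderate = 0.26, severe = 0.10,
           occlusion = 0.02),
    CCA = c(none = 0.55, mild = 0.33, moderate = 0.10, severe = 0.02,
            occlusion = 0.00)
  )
  cohort_config(n_patients = n_patients, flow_chart = chart0,
                grade_probabilities = gp)
}
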
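# Independent oracles and small fixtures used across the suite.

# Naive fold-by-fold LOOCV with stats::glm — the reference the C++ engine is
# checked against. No standardization: classification is invariant to it.
naive_loocv_oracle <- function(table, variables, threshold = 0.5) {
  y <- as.integer(table$group == "stroke")
  X <- as.data.frame(table[, variables, drop = FALSE])
  n <- length(y)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    dat <- cbind(.y = y[-i], X[-i, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    prob[i] <- suppressWarnings(
      stats::predict(fit, newdata = X[i, , drop = FALSE], type = "response"))
  }
  pred <- as.integer(prob > threshold)
  list(prob = prob, pred = pred, mr = mean(pred != y))
}

# deterministic 8-subject fixture with an informative and a noise variable
eight_subject_fixture <- function() {
  tibble::tibble(
    subject_id = sprintf("F%02d", 1:8),
    group = factor(rep(c("stroke", "control"), each = 4),
                   levels = c("control", "stroke")),
    x_info = c(2.1, 1.7, 2.6, 0.9, 0.4, 1.1, -0.2, 0.7),
    x_noise = c(0.3, -1.2, 0.8, 0.4, -0.5, 1.4, 0.2, -0.9))
}

# tiny cohort spec (few variables) for fast end-to-end tests
small_cohort_spec <- function(n_stroke = 31, n_control = 41) {
  vars <- tibble::tribble(
    ~variable,            ~class,           ~mean_control, ~sd_control, ~shift, ~sd_stroke, ~loading,
    "gait_speed",         "spatiotemporal", 1.30, 0.10, -4.0, 0.30,  0.9,
    "single_support_pct", "spatiotemporal", 40.0, 1.7,  -3.5, 5.0,   0.8,
    "pelvis_sag_rom",     "rom",            3.0,  0.8,   1.9, 1.7,  -0.2,
    "aps",                "deviation",      4.5,  1.2,   2.5, 2.8,  -0.35,
    "noise_a",            "rom",            10,   2,     0,   2,     0.0,
    "noise_b",            "rom",            5,    1,     0,   1,     0.0,
  )
  cohort_spec(n_stroke = n_stroke, n_control = n_control, variables = vars)
}

# all-null spec: no group effects, independent variables
null_cohort_spec <- function(p = 10, n_stroke = 31, n_control = 41) {
  vars <- tibble::tibble(
    variable = sprintf("v%02d", seq_len(p)), class = "rom",
    mean_control = 10, sd_control = 2, shift = 0, sd_stroke = 2, loading = 0)
  cohort_spec(n_stroke = n_stroke, n_control = n_control, variables = vars)
}
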
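# a noise-free cohort in which all controls (and optionally strokes) equal the
# group template curves exactly
noiseless_cohort <- function(n_stroke = 4, n_control = 12, seed = 3,
                             stroke_too = FALSE) {
  cs <- default_curve_specs()
  cs$curves$noise_sd <- 0
  if (stroke_too) cs$curves$subject_sd <- 0
  simulate_curves(cohort_spec(n_stroke = n_stroke, n_control = n_control),
                  cs, seed = seed)
}

test_that("a subject identical to the reference mean scores zero GPS/APS", {
  cs <- default_curve_specs()
  cs$curves$noise_sd <- 0
  cs$curves$subject_sd <- 0
  cc <- simulate_curves(cohort_spec(n_stroke = 4, n_control = 12), cs, seed = 3)
  # with all between-subject variation off, the GDI log-distance is undefined
  expect_error(fit_reference_bands(cc), "degenerate|coincides")
  cc2 <- noiseless_cohort(seed = 3)
  ref2 <- fit_reference_bands(cc2)
  mean_trial <- cc2$trials[[cc2$subjects$subject_id[cc2$subjects$group == "control"][1]]]
  # replace each curve with the reference mean -> deviation must be exactly 0
  mean_curves <- dplyr::rename(ref2$bands, angle_deg = mean)
  trial0 <- trial_kinematics(
    curves = dplyr::select(mean_curves, side, joint, plane, cycle_pct, angle_deg),
    events = mean_trial$events, stride_time = mean_trial$stride_time,
    spatial = mean_trial$spatial, tracks = mean_trial$tracks)
  gps <- rms_deviation_score(trial0, ref2, ref2$gps_set)
  aps <- rms_deviation_score(trial0, ref2, ref2$aps_set)
  expect_equal(gps$score, 0)
  expect_equal(aps$score, 0)
  expect_true(all(gps$sub_scores$rms == 0))
})

test_that("a constant offset on one curve yields that sub-score exactly", {
  cc <- noiseless_cohort(seed = 4)
  ref <- fit_reference_bands(cc)
  mean_curves <- dplyr::rename(ref$bands, angle_deg = mean)
  any_trial <- cc$trials[[1]]
  base <- dplyr::select(mean_curves, side, joint, plane, cycle_pct, angle_deg)
  d <- 3.5
  shifted <- dplyr::mutate(base, angle_deg = ifelse(
    side == "affected" & joint == "knee" & plane == "X", angle_deg + d, angle_deg))
  trial <- trial_kinematics(shifted, any_trial$events, any_trial$stride_time,
                            any_trial$spatial, any_trial$tracks)
  res <- rms_deviation_score(trial, ref, ref$gps_set)
  knee <- dplyr::filter(res$sub_scores, joint == "knee", side == "affected")
  expect_equal(knee$rms, d, tolerance = 1e-10)
  # overall is the RMS of the sub-scores (one nonzero out of 13)
  expect_equal(res$score, sqrt(d^2 / nrow(ref$gps_set)), tolerance = 1e-10)
})

test_that("nested RMS combines sub-scores as sqrt(mean of squares)", {
  cc <- noiseless_cohort(seed = 5)
  ref <- fit_reference_bands(cc)
  base <- dplyr::select(dplyr::rename(ref$bands, angle_deg = mean),
                        side, joint, plane, cycle_pct, angle_deg)
  any_trial <- cc$trials[[1]]
  shifted <- dplyr::mutate(base, angle_deg = dplyr::case_when(
    side == "affected" & joint == "knee" & plane == "X" ~ angle_deg + 3,
    side == "affected" & joint == "ankle" & plane == "X" ~ angle_deg + 4,
    TRUE ~ angle_deg))
  trial <- trial_kinematics(shifted, any_trial$events, any_trial$stride_time,
                            any_trial$spatial, any_trial$tracks)
  res <- rms_deviation_score(trial, ref, ref$gps_set)
  expect_equal(res$score, sqrt((9 + 16) / nrow(ref$gps_set)), tolerance = 1e-10)
})

test_that("missing curves are reported by name", {
  cc <- noiseless_cohort(seed = 6)
  ref <- fit_reference_bands(cc)
  tr <- cc$trials[[1]]
  crippled <- trial_kinematics(
    dplyr::filter(tr$curves, !(joint == "ankle" & side == "affected")),
    tr$events, tr$stride_time, tr$spatial, tr$tracks)
  expect_error(rms_deviation_score(crippled, ref, ref$gps_set),
               "affected/ankle/X")
})

test_that("GDI construction gives controls mean 100 and SD 10", {
  cc <- simulate_curves(cohort_spec(n_stroke = 10, n_control = 20), seed = 8)
  ref <- fit_reference_bands(cc)
  # basis orthonormality
  B <- ref$gdi$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-8)
  ctrl <- cc$subjects$subject_id[cc$subjects$group == "control"]
  scores <- vapply(ctrl, function(id) gait_deviation_index(cc$trials[[id]], ref),
                   numeric(1))
  expect_equal(mean(scores), 100, tolerance = 1e-6)
  expect_equal(sd(scores), 10, tolerance = 1e-6)
  # stroke trials deviate more from control gait, so score below the control mean
  strk <- cc$subjects$subject_id[cc$subjects$group == "stroke"]
  sscores <- vapply(strk, function(id) gait_deviation_index(cc$trials[[id]], ref),
                    numeric(1))
  expect_lt(mean(sscores), mean(scores))
})

test_that("reference fitting demands at least 10 controls", {
  cc <- simulate_curves(cohort_spec(n_stroke = 4, n_control = 5), seed = 9)
  expect_error(fit_reference_bands(cc), ">= 10 control")
})

test_that("batch extraction equals subject-by-subject extraction", {
  cc <- simulate_curves(cohort_spec(n_stroke = 3, n_control = 11), seed = 10)
  ref <- fit_reference_bands(cc)
  batch <- extract_features(cc, ref)
  cat_n <- nrow(default_feature_catalog())
  expect_equal(ncol(batch), 5 + cat_n)  # id, group, 3 covariates + features
  for (id in c(cc$subjects$subject_id[1], cc$subjects$subject_id[14])) {
    single <- extract_features(cc$trials[[id]], ref)
    expect_equal(unlist(single),
                 unlist(batch[batch$subject_id == id, names(single)]))
  }
})
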
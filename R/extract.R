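#' Default kinematic feature catalog
#'
#' The catalog of variables extracted from a trial: spatiotemporal parameters,
#' ROM and MAX joint angles, side-to-side ROM indices, body-inclination
#' angles, control-referenced deviation scores, and event-windowed
#' stroke-specific angles. Unilateral outcomes use the affected
#' (stroke) / non-dominant (control) side, except hip abduction in the
#' non-affected side during stance. Phase windows are derived from the gait
#' events: swing `(foot_off, 100]`, terminal stance
#' `(opp_foot_contact, foot_off]`, single stance
#' `(opp_foot_off, opp_foot_contact]`, stance `[0, foot_off]`.
#'
#' @return A tibble with columns `variable`, `class`, `side`, `joint`,
#'   `plane`, `window`, `direction`, `param`.
#' @export
default_feature_catalog <- function() {
  tibble::tribble(
    ~variable,                          ~class,           ~side,         ~joint,     ~plane, ~window,          ~direction, ~param,
    "step_length",                      "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "step_length",
    "stride_length",                    "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "stride_length",
    "step_width",                       "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "step_width",
    "gait_speed",                       "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "gait_speed",
    "cadence",                          "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "cadence",
    "stance_duration_pct",              "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "stance_duration_pct",
    "ds1_duration_pct",                 "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "ds1_duration_pct",
    "ds2_duration_pct",                 "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "ds2_duration_pct",
    "single_support_pct",               "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "single_support_pct",
    "step_time",                        "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "step_time",
    "stride_time",                      "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "stride_time_s",
    "swing_time",                       "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "swing_time",
    "temporal_symmetry",                "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "temporal_symmetry",
    "spatial_symmetry",                 "spatiotemporal", "affected",    NA,         NA,     NA,               NA,         "spatial_symmetry",
    "pelvis_sag_rom",                   "rom",            "affected",    "pelvis",   "X",    NA,               NA,         NA,
    "pelvis_frontal_rom",               "rom",            "affected",    "pelvis",   "Y",    NA,               NA,         NA,
    "pelvis_trans_rom",                 "rom",            "affected",    "pelvis",   "Z",    NA,               NA,         NA,
    "hip_sag_rom",                      "rom",            "affected",    "hip",      "X",    NA,               NA,         NA,
    "hip_frontal_rom",                  "rom",            "affected",    "hip",      "Y",    NA,               NA,         NA,
    "hip_trans_rom",                    "rom",            "affected",    "hip",      "Z",    NA,               NA,         NA,
    "knee_sag_rom",                     "rom",            "affected",    "knee",     "X",    NA,               NA,         NA,
    "ankle_sag_rom",                    "rom",            "affected",    "ankle",    "X",    NA,               NA,         NA,
    "thorax_frontal_rom",               "rom",            "affected",    "thorax",   "Y",    NA,               NA,         NA,
    "thorax_trans_rom",                 "rom",            "affected",    "thorax",   "Z",    NA,               NA,         NA,
    "shoulder_sag_rom",                 "rom",            "affected",    "shoulder", "X",    NA,               NA,         NA,
    "shoulder_frontal_rom",             "rom",            "affected",    "shoulder", "Y",    NA,               NA,         NA,
    "shoulder_trans_rom",               "rom",            "affected",    "shoulder", "Z",    NA,               NA,         NA,
    "elbow_sag_rom",                    "rom",            "affected",    "elbow",    "X",    NA,               NA,         NA,
    "hip_trans_max",                    "max",            "affected",    "hip",      "Z",    NA,               "positive", NA,
    "knee_flexion_max",                 "max",            "affected",    "knee",     "X",    NA,               "positive", NA,
    "shoulder_abduction_max",           "max",            "affected",    "shoulder", "Y",    NA,               "positive", NA,
    "elbow_flexion_max",                "max",            "affected",    "elbow",    "X",    NA,               "positive", NA,
    "hip_sag_romi",                     "romi",           NA,            "hip",      "X",    NA,               NA,         NA,
    "hip_frontal_romi",                 "romi",           NA,            "hip",      "Y",    NA,               NA,         NA,
    "knee_sag_romi",                    "romi",           NA,            "knee",     "X",    NA,               NA,         NA,
    "ankle_sag_romi",                   "romi",           NA,            "ankle",    "X",    NA,               NA,         NA,
    "shoulder_sag_romi",                "romi",           NA,            "shoulder", "X",    NA,               NA,         NA,
    "acomia_stance_max",                "inclination",    "affected",    NA,         NA,     "stance",         NA,         "ankle",
    "acomia_swing_max",                 "inclination",    "affected",    NA,         NA,     "swing",          NA,         "ankle",
    "hcomia_swing_max",                 "inclination",    "affected",    NA,         NA,     "swing",          NA,         "head",
    "gps",                              "deviation",      NA,            NA,         NA,     NA,               NA,         "gps",
    "gdi",                              "deviation",      NA,            NA,         NA,     NA,               NA,         "gdi",
    "aps",                              "deviation",      NA,            NA,         NA,     NA,               NA,         "aps",
    "hip_extension_swing_max",          "windowed",       "affected",    "hip",      "X",    "swing",          "negative", NA,
    "knee_flexion_swing_max",           "windowed",       "affected",    "knee",     "X",    "swing",          "positive", NA,
    "ankle_plantarflexion_push_off",    "windowed",       "affected",    "ankle",    "X",    "terminal_stance","negative", NA,
    "hip_abduction_nonaffected_stance", "windowed",       "nonaffected", "hip",      "Y",    "stance",         "negative", NA,
  )
}

phase_window <- function(window_name, events_row) {
  e <- events_row
  switch(window_name,
         full = list(w = c(0, 100), open = FALSE),
         stance = list(w = c(0, e$foot_off), open = FALSE),
         swing = list(w = c(e$foot_off, 100), open = TRUE),
         terminal_stance = list(w = c(e$opp_foot_contact, e$foot_off), open = TRUE),
         single_stance = list(w = c(e$opp_foot_off, e$opp_foot_contact), open = TRUE),
         abort(sprintf("unknown phase window \"%s\".", window_name)))
}

extract_one <- function(trial, reference, catalog) {
  st <- spatiotemporal_params(trial$events, trial$stride_time, trial$spatial)
  vals <- purrr::pmap_dbl(catalog, function(variable, class, side, joint, plane,
                                            window, direction, param) {
    tryCatch({
      switch(class,
        spatiotemporal = {
          row <- st[st$side == side, ]
          as.numeric(row[[param]])
        },
        rom = rom(curve_vector(trial, side, joint, plane)),
        max = max_angle(curve_vector(trial, side, joint, plane),
                        direction = direction %||% "positive"),
        romi = rom_index(rom(curve_vector(trial, "affected", joint, plane)),
                         rom(curve_vector(trial, "nonaffected", joint, plane))),
        inclination = {
          ev <- trial$events[trial$events$side == side, ]
          win <- phase_window(window, ev)
          land <- dplyr::filter(trial$tracks, .data$track == !!param)
          com <- dplyr::filter(trial$tracks, .data$track == "com")
          inclination_angle_max(land, com, window = win$w, open_lower = win$open)
        },
        deviation = switch(param,
          gps = rms_deviation_score(trial, reference, reference$gps_set)$score,
          aps = rms_deviation_score(trial, reference, reference$aps_set)$score,
          gdi = gait_deviation_index(trial, reference)),
        windowed = {
          ev <- trial$events[trial$events$side == side, ]
          win <- phase_window(window, ev)
          max_angle(curve_vector(trial, side, joint, plane), window = win$w,
                    direction = direction, open_lower = win$open)
        },
        abort(sprintf("unknown feature class \"%s\".", class)))
    }, error = function(e) {
      abort(sprintf("failed to extract `%s`: %s", variable, conditionMessage(e)))
    })
  })
  tibble::as_tibble(as.list(setNames(vals, catalog$variable)))
}

#' Extract the kinematic feature vector(s) from trial kinematics
#'
#' Computes every catalog variable for one trial or for a whole curve-level
#' cohort. For a cohort the result is a subject variable table (one row per
#' subject, covariates included) ready for [screen_all()] and
#' [search_coresets()].
#'
#' @param x A [trial_kinematics()] or a `curve_cohort` from
#'   [simulate_curves()].
#' @param reference A [fit_reference_bands()] object (needed for the
#'   deviation scores).
#' @param catalog Feature catalog tibble; default [default_feature_catalog()].
#' @return A one-row tibble of features (single trial) or a subject variable
#'   table with `subject_id`, `group`, covariates, then features (cohort).
#' @export
extract_features <- function(x, reference, catalog = default_feature_catalog()) {
  if (inherits(x, "trial_kinematics")) {
    return(extract_one(x, reference, catalog))
  }
  if (inherits(x, "curve_cohort")) {
    feats <- dplyr::bind_rows(purrr::map(x$trials, extract_one,
                                         reference = reference, catalog = catalog))
    return(dplyr::bind_cols(x$subjects, feats))
  }
  abort("`x` must be a trial_kinematics or curve_cohort.")
}
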
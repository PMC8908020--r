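
# Fourier series on the unit cycle: a0 + sum_k a_k cos(2*pi*k*t) + b_k sin(2*pi*k*t)
fourier_eval <- function(a0, a, b, t) {
  out <- rep(a0, length(t))
  for (k in seq_along(a)) {
    out <- out + a[k] * cos(2 * pi * k * t) + b[k] * sin(2 * pi * k * t)
  }
  out
}

#' Default curve-level simulation templates
#'
#' Template mean curves (as Fourier coefficients, at most 8 harmonics) for the
#' joint/plane combinations the feature catalog consumes, with stroke-side
#' amplitude scalings and offsets at magnitudes reported for hemiparetic gait
#' (reduced knee/ankle sagittal excursion, increased pelvic sagittal tilt
#' range, reduced arm swing with elevated elbow flexion); per-curve
#' between-subject amplitude SD and within-curve measurement noise SD in
#' degrees; and group-wise gait-event and spatial parameters.
#'
#' @return A list with elements `curves` (tibble: `joint`, `plane`, `a0`, `a`,
#'   `b` (list-columns of harmonic coefficients), `stroke_scale`,
#'   `stroke_offset`, `subject_sd`, `noise_sd`), `events` (tibble: `group`,
#'   `side`, `event`, `mean`, `sd`, in % of cycle) and `gait` (tibble:
#'   `group`, `param`, `mean`, `sd`, for stride time and spatial parameters).
#' @export
default_curve_specs <- function() {
  curves <- tibble::tribble(
    ~joint,     ~plane, ~a0,  ~a,             ~b,             ~stroke_scale, ~stroke_offset, ~subject_sd, ~noise_sd,
    "pelvis",   "X",    12,   c(0, 0),        c(0, 1.5),      1.6,            1.0,           0.8,  0.3,
    "pelvis",   "Y",    0,    c(2.0, 0),      c(3.0, 0),      0.8,            0.0,           0.8,  0.3,
    "pelvis",   "Z",    0,    c(3.5, 0),      c(2.5, 0),      1.2,            0.0,           1.0,  0.3,
    "hip",      "X",    10,   c(18, 0),       c(6, 0),        0.85,           0.0,           2.0,  0.3,
    "hip",      "Y",    0,    c(4, 0),        c(0, 2),        0.8,            0.0,           1.0,  0.3,
    "hip",      "Z",    0,    c(3, 0),        c(2, 0),        0.9,            0.0,           1.0,  0.3,
    "knee",     "X",    25,   c(-10, -8),     c(-15, 6),      0.75,          -2.0,           2.5,  0.3,
    "ankle",    "X",    -2,   c(5, -6),       c(8, -7),       0.65,           1.0,           1.5,  0.3,
    "thorax",   "Y",    0,    c(0, 0),        c(2.5, 0),      1.2,            0.0,           0.8,  0.3,
    "thorax",   "Z",    0,    c(3, 0),        c(0, 0),        1.2,            0.0,           0.8,  0.3,
    "shoulder", "X",    -5,   c(-12, 0),      c(-4, 0),       0.6,            2.0,           3.0,  0.3,
    "shoulder", "Y",    6,    c(0, 0),        c(2, 0),        1.3,            3.0,           1.5,  0.3,
    "shoulder", "Z",    0,    c(3, 0),        c(0, 0),        1.0,            0.0,           1.5,  0.3,
    "elbow",    "X",    25,   c(5, 0),        c(3, 0),        0.8,           10.0,           3.0,  0.3,
  )
  events <- tibble::tribble(
    ~group,    ~side,         ~event,             ~mean, ~sd,
    "control", "affected",    "opp_foot_off",     10,    1.0,
    "control", "affected",    "opp_foot_contact", 50,    1.0,
    "control", "affected",    "foot_off",         60,    1.5,
    "control", "nonaffected", "opp_foot_off",     10,    1.0,
    "control", "nonaffected", "opp_foot_contact", 50,    1.0,
    "control", "nonaffected", "foot_off",         60,    1.5,
    "stroke",  "affected",    "opp_foot_off",     15,    2.5,
    "stroke",  "affected",    "opp_foot_contact", 47,    3.0,
    "stroke",  "affected",    "foot_off",         65,    3.0,
    "stroke",  "nonaffected", "opp_foot_off",     12,    2.0,
    "stroke",  "nonaffected", "opp_foot_contact", 52,    2.5,
    "stroke",  "nonaffected", "foot_off",         64,    3.0,
  )
  gait <- tibble::tribble(
    ~group,    ~param,                    ~mean, ~sd,
    "control", "stride_time",             1.05,  0.08,
    "control", "step_length_affected",    0.68,  0.06,
    "control", "step_length_nonaffected", 0.68,  0.06,
    "control", "step_width",              0.12,  0.03,
    "stroke",  "stride_time",             1.25,  0.20,
    "stroke",  "step_length_affected",    0.55,  0.10,
    "stroke",  "step_length_nonaffected", 0.46,  0.10,
    "stroke",  "step_width",              0.15,  0.05,
  )
  list(curves = curves, events = events, gait = gait)
}

validate_curve_specs <- function(cs) {
  assert_that(all(c("curves", "events", "gait") %in% names(cs)),
              "curve specs need elements `curves`, `events`, `gait`.")
  assert_that(all(lengths(cs$curves$a) <= 8) && all(lengths(cs$curves$b) <= 8),
              "at most 8 harmonics per curve template.")
  assert_that(all(cs$curves$subject_sd >= 0) && all(cs$curves$noise_sd >= 0) &&
                all(cs$events$sd >= 0), "SDs must be >= 0.")
  invisible(cs)
}

# draw one side's events respecting the strict ordering; rejection-sample
draw_events <- function(ev, max_tries = 1000) {
  m <- setNames(ev$mean, ev$event)
  s <- setNames(ev$sd, ev$event)
  for (i in seq_len(max_tries)) {
    ofo <- rnorm(1, m[["opp_foot_off"]], s[["opp_foot_off"]])
    ofc <- rnorm(1, m[["opp_foot_contact"]], s[["opp_foot_contact"]])
    fo <- rnorm(1, m[["foot_off"]], s[["foot_off"]])
    if (0 < ofo && ofo < ofc && ofc < fo && fo < 100) {
      return(c(opp_foot_off = ofo, opp_foot_contact = ofc, foot_off = fo))
    }
  }
  abort("could not draw ordered gait events; check event means/SDs.")
}

#' Simulate per-subject cycle-normalized joint-angle curves
#'
#' Generates a two-group cohort at the curve level: every subject receives
#' 101-sample joint-angle curves for both sides built from group template
#' curves (Fourier means), a subject-specific amplitude deviation, and
#' pointwise measurement noise; gait events, stride time, spatial parameters,
#' and planar centre-of-mass/ankle/head tracks consistent with the subject's
#' step length. Stroke-group templates on the affected side are the control
#' template scaled by `stroke_scale` and shifted by `stroke_offset`.
#'
#' @param spec A [cohort_spec()] (group sizes and covariates are used).
#' @param curve_specs Templates as from [default_curve_specs()].
#' @param seed Integer seed.
#' @return A `curve_cohort`: list with `subjects` (tibble: subject_id, group,
#'   age, sex, bmi) and `trials` (named list of [trial_kinematics()]).
#' @export
simulate_curves <- function(spec, curve_specs = default_curve_specs(), seed) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec.")
  validate_curve_specs(curve_specs)
  with_local_seed(substream_seed(seed, "curves"), {
    groups <- c(rep("stroke", spec$n_stroke), rep("control", spec$n_control))
    ids <- sprintf("S%03d", seq_along(groups))
    covs <- dplyr::bind_rows(
      draw_covariates(spec$covariates, "stroke", spec$n_stroke),
      draw_covariates(spec$covariates, "control", spec$n_control))
    subjects <- dplyr::bind_cols(
      tibble::tibble(subject_id = ids, group = as_group_factor(groups)), covs)
    trials <- purrr::map(seq_along(ids), function(i) {
      simulate_one_trial(groups[i], curve_specs)
    })
    names(trials) <- ids
    structure(list(subjects = subjects, trials = trials), class = "curve_cohort")
  })
}

simulate_one_trial <- function(group, cs) {
  t <- seq(0, 1, length.out = 101)
  gaitp <- function(p) {
    r <- cs$gait[cs$gait$group == group & cs$gait$param == p, ]
    max(rnorm(1, r$mean, r$sd), 0.05)
  }
  stride_time <- gaitp("stride_time")
  sl_aff <- gaitp("step_length_affected")
  sl_non <- gaitp("step_length_nonaffected")
  width <- gaitp("step_width")
  spatial <- tibble::tibble(
    side = c("affected", "nonaffected"),
    step_length = c(sl_aff, sl_non),
    stride_length = sl_aff + sl_non,
    step_width = width)

  curves <- purrr::pmap(cs$curves, function(joint, plane, a0, a, b, stroke_scale,
                                            stroke_offset, subject_sd, noise_sd) {
    purrr::map(c("affected", "nonaffected"), function(side) {
      scale <- 1; offset <- 0
      if (group == "stroke" && side == "affected") {
        scale <- stroke_scale; offset <- stroke_offset
      }
      m <- a0 + offset + scale * (fourier_eval(0, a, b, t))
      # subject-level amplitude deviation, scaled so its SD (deg) applies at
      # the template's peak deviation from its own mean
      amp <- max(abs(m - mean(m)))
      dev <- if (amp > 1e-12 && subject_sd > 0) rnorm(1, 0, subject_sd / amp) else 0
      y <- mean(m) + (1 + dev) * (m - mean(m)) + rnorm(101, 0, noise_sd)
      tibble::tibble(side = side, joint = joint, plane = plane,
                     cycle_pct = 0:100, angle_deg = y)
    })
  })
  curves <- dplyr::bind_rows(purrr::flatten(curves))

  ev <- purrr::map(c("affected", "nonaffected"), function(side) {
    e <- draw_events(cs$events[cs$events$group == group & cs$events$side == side, ])
    tibble::tibble(side = side, foot_off = e[["foot_off"]],
                   opp_foot_off = e[["opp_foot_off"]],
                   opp_foot_contact = e[["opp_foot_contact"]])
  })
  events <- dplyr::bind_rows(ev)

  # planar tracks in the CoM frame: the ankle leads the CoM by about 45% of
  # the subject's step length at foot contact and trails it in late stance
  com_vert <- 0.95 + 0.015 * cos(4 * pi * t)
  tracks <- dplyr::bind_rows(
    tibble::tibble(track = "com", cycle_pct = 0:100, horiz = 0, vert = com_vert),
    tibble::tibble(track = "ankle", cycle_pct = 0:100,
                   horiz = 0.45 * sl_aff * cos(2 * pi * t),
                   vert = 0.08 + 0.04 * pmax(0, -sin(2 * pi * t))),
    tibble::tibble(track = "head", cycle_pct = 0:100,
                   horiz = 0.02 * sin(4 * pi * t), vert = com_vert + 0.65))

  trial_kinematics(curves = curves, events = events,
                   stride_time = c(affected = stride_time, nonaffected = stride_time),
                   spatial = spatial, tracks = tracks)
}

#' @export
print.curve_cohort <- function(x, ...) {
  cat("<curve_cohort>\n")
  cat(sprintf("  subjects: %d (%s)\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            as.integer(table(x$subjects$group))), collapse = ", ")))
  invisible(x)
}
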
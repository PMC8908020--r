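#' Range of motion of a joint-angle curve
#'
#' The difference between the highest and lowest value of the angular motion
#' curve over the gait cycle.
#'
#' @param curve Numeric vector of angle samples (deg), typically 101 points.
#' @return Non-negative range (deg).
#' @export
rom <- function(curve) {
  assert_that(is.numeric(curve) && all(is.finite(curve)), "`curve` must be finite numeric.")
  max(curve) - min(curve)
}

#' Maximal (windowed, signed) joint angle
#'
#' The highest value of the angular motion curve, optionally restricted to a
#' phase window of the gait cycle and optionally of the negated curve, so that
#' extrema in the opposite anatomical direction (e.g. plantarflexion on a
#' dorsiflexion-positive curve, extension on a flexion-positive curve) are
#' extracted as positive magnitudes.
#'
#' @param curve Numeric vector of angle samples on the 0--100% grid
#'   (length 101 for the standard grid).
#' @param window Optional `c(lo, hi)` in % of the gait cycle; default the full
#'   cycle. The window is closed (`[lo, hi]`) unless `open_lower = TRUE`, in
#'   which case it is `(lo, hi]` (used for event-bounded phases).
#' @param direction `"positive"` (default) takes the maximum of the curve;
#'   `"negative"` the maximum of the negated curve.
#' @param open_lower Exclude the lower window bound.
#' @return Extremum value (deg).
#' @export
max_angle <- function(curve, window = NULL, direction = c("positive", "negative"),
                      open_lower = FALSE) {
  direction <- match.arg(direction)
  assert_that(is.numeric(curve) && all(is.finite(curve)), "`curve` must be finite numeric.")
  pct <- seq(0, 100, length.out = length(curve))
  if (is.null(window)) {
    idx <- seq_along(curve)
  } else {
    assert_that(length(window) == 2 && window[1] <= window[2] &&
                  window[1] >= 0 && window[2] <= 100,
                "`window` must be c(lo, hi) within [0, 100].")
    idx <- if (open_lower) which(pct > window[1] & pct <= window[2])
           else which(pct >= window[1] & pct <= window[2])
    if (length(idx) == 0) {
      abort(sprintf("window [%g, %g]%% contains no samples after discretization.",
                    window[1], window[2]))
    }
  }
  v <- if (direction == "negative") -curve[idx] else curve[idx]
  max(v)
}

#' Range-of-motion index (side-to-side ROM ratio)
#'
#' Ratio of the affected-side ROM to the non-affected-side ROM in persons
#' post-stroke, or of the non-dominant to the dominant side in controls.
#'
#' @param affected_rom ROM of the affected / non-dominant side (deg).
#' @param reference_rom ROM of the non-affected / dominant side (deg); must be
#'   strictly positive.
#' @return Dimensionless ratio.
#' @export
rom_index <- function(affected_rom, reference_rom) {
  if (!is.numeric(reference_rom) || reference_rom <= 0) {
    abort("`reference_rom` must be > 0: the reference side has degenerate (zero) motion.")
  }
  affected_rom / reference_rom
}

#' Maximal body-inclination angle over a phase window
#'
#' The angle from the vertical of the segment joining a body landmark (ankle
#' or head vertex) to the body's centre of mass, maximized over a window of
#' the gait cycle.
#'
#' @param landmark_track,com_track Tibbles (or data frames) with columns
#'   `cycle_pct`, `horiz`, `vert` (planar positions in m), aligned sample for
#'   sample on the cycle grid.
#' @param window `c(lo, hi)` in % of the gait cycle; default full cycle.
#' @param open_lower Exclude the lower window bound (event-bounded phases).
#' @return Maximal inclination angle (deg).
#' @export
inclination_angle_max <- function(landmark_track, com_track, window = c(0, 100),
                                  open_lower = FALSE) {
  l <- dplyr::arrange(tibble::as_tibble(landmark_track), .data$cycle_pct)
  c_ <- dplyr::arrange(tibble::as_tibble(com_track), .data$cycle_pct)
  assert_that(nrow(l) == nrow(c_) && all(l$cycle_pct == c_$cycle_pct),
              "landmark and CoM tracks must be aligned sample-for-sample.")
  dx <- c_$horiz - l$horiz
  dy <- c_$vert - l$vert
  if (any(abs(dx) < 1e-12 & abs(dy) < 1e-12)) {
    abort("landmark and CoM coincide at one or more samples; inclination undefined.")
  }
  ang <- atan2(abs(dx), dy) * 180 / pi
  idx <- if (open_lower) which(l$cycle_pct > window[1] & l$cycle_pct <= window[2])
         else which(l$cycle_pct >= window[1] & l$cycle_pct <= window[2])
  if (length(idx) == 0) abort("inclination window contains no samples.")
  max(ang[idx])
}

#' Spatiotemporal gait parameters from events and spatial measures
#'
#' Phase durations in % of the gait cycle (stance, swing, 1st double-support,
#' single-support, 2nd double-support), absolute times (s), cadence
#' (steps/min), gait speed (m/s) and the temporal/spatial symmetry ratios
#' (affected over non-affected swing time and step length).
#'
#' The cycle of a side starts at that side's foot contact; `foot_off`,
#' `opp_foot_off`, and `opp_foot_contact` are percentages of that cycle, so
#' the phase partition 1st double-support + single-support + 2nd
#' double-support + swing equals 100% identically.
#'
#' @param events Tibble with columns `side`, `foot_off`, `opp_foot_off`,
#'   `opp_foot_contact` (% of cycle), one row per side.
#' @param stride_time Named numeric (s) per side.
#' @param spatial Tibble with `side`, `step_length`, `stride_length`,
#'   `step_width` (m).
#' @return A tibble with one row per side: phase percentages, times,
#'   `cadence`, `gait_speed`, and (identical across rows)
#'   `temporal_symmetry`, `spatial_symmetry`.
#' @export
spatiotemporal_params <- function(events, stride_time, spatial) {
  events <- tibble::as_tibble(events)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (!(0 < e$opp_foot_off && e$opp_foot_off < e$opp_foot_contact &&
          e$opp_foot_contact < e$foot_off && e$foot_off < 100)) {
      abort(sprintf("event ordering violated on side \"%s\": opp_foot_off=%.2f, opp_foot_contact=%.2f, foot_off=%.2f.",
                    e$side, e$opp_foot_off, e$opp_foot_contact, e$foot_off))
    }
  }
  out <- dplyr::mutate(
    events,
    stride_time_s = unname(stride_time[.data$side]),
    stance_duration_pct = .data$foot_off,
    swing_pct = 100 - .data$foot_off,
    ds1_duration_pct = .data$opp_foot_off,
    single_support_pct = .data$opp_foot_contact - .data$opp_foot_off,
    ds2_duration_pct = .data$foot_off - .data$opp_foot_contact,
    stance_time = .data$foot_off / 100 * .data$stride_time_s,
    swing_time = (100 - .data$foot_off) / 100 * .data$stride_time_s,
    step_time = (100 - .data$opp_foot_contact) / 100 * .data$stride_time_s,
    cadence = 120 / .data$stride_time_s)
  out <- dplyr::left_join(out, tibble::as_tibble(spatial), by = "side")
  out <- dplyr::mutate(out, gait_speed = .data$stride_length / .data$stride_time_s)
  aff <- out[out$side == "affected", ]
  non <- out[out$side == "nonaffected", ]
  if (nrow(aff) == 1 && nrow(non) == 1) {
    out$temporal_symmetry <- aff$swing_time / non$swing_time
    out$spatial_symmetry <- aff$step_length / non$step_length
  } else {
    out$temporal_symmetry <- NA_real_
    out$spatial_symmetry <- NA_real_
  }
  out
}
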
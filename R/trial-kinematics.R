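#' Cycle-normalized trial kinematics for one subject
#'
#' Container for one subject's gait-cycle-normalized joint-angle curves,
#' gait events, stride timing, spatial parameters, and planar landmark tracks.
#' All curves and tracks live on the standard 101-point grid (0--100% of the
#' gait cycle, inclusive). Sides are labelled `affected` (the paretic side
#' post-stroke, the non-dominant side in controls) and `nonaffected`
#' (non-paretic / dominant).
#'
#' @param curves Long tibble with columns `side`, `joint`, `plane`
#'   (`X` sagittal, `Y` frontal, `Z` transversal), `cycle_pct` (0..100) and
#'   `angle_deg`; exactly 101 samples per (side, joint, plane).
#' @param events Tibble with columns `side`, `foot_off`, `opp_foot_off`,
#'   `opp_foot_contact` (% of that side's cycle); must satisfy
#'   0 < opp_foot_off < opp_foot_contact < foot_off < 100.
#' @param stride_time Named numeric (s) per side; > 0.
#' @param spatial Tibble with columns `side`, `step_length`, `stride_length`,
#'   `step_width` (m).
#' @param tracks Optional long tibble of planar positions (m) with columns
#'   `track` (`com`, `ankle`, `head`), `cycle_pct`, `horiz`, `vert`, aligned
#'   with the cycle grid; needed only for inclination angles.
#' @return An object of class `trial_kinematics`.
#' @export
trial_kinematics <- function(curves, events, stride_time, spatial, tracks = NULL) {
  curves <- tibble::as_tibble(curves)
  events <- tibble::as_tibble(events)
  spatial <- tibble::as_tibble(spatial)
  x <- structure(list(curves = curves, events = events,
                      stride_time = stride_time, spatial = spatial,
                      tracks = if (!is.null(tracks)) tibble::as_tibble(tracks)),
                 class = "trial_kinematics")
  validate_trial_kinematics(x)
}

validate_trial_kinematics <- function(x) {
  cnt <- dplyr::count(x$curves, .data$side, .data$joint, .data$plane)
  bad <- dplyr::filter(cnt, .data$n != 101L)
  if (nrow(bad) > 0) {
    abort(sprintf("curves must have exactly 101 samples; offending: %s",
                  paste(sprintf("%s/%s/%s (%d)", bad$side, bad$joint, bad$plane, bad$n),
                        collapse = ", ")))
  }
  for (i in seq_len(nrow(x$events))) {
    e <- x$events[i, ]
    ord <- c(0, e$opp_foot_off, e$opp_foot_contact, e$foot_off, 100)
    if (any(diff(ord) <= 0)) {
      nm <- c("opp_foot_off", "opp_foot_contact", "foot_off")
      viol <- nm[which(diff(ord) <= 0)[1]]
      abort(sprintf(
        "event ordering violated on side \"%s\" at `%s`: need 0 < opp_foot_off < opp_foot_contact < foot_off < 100 (got %.2f, %.2f, %.2f).",
        e$side, viol %||% "foot_off", e$opp_foot_off, e$opp_foot_contact, e$foot_off))
    }
  }
  assert_that(all(x$stride_time > 0), "stride_time must be > 0.")
  x
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat("<trial_kinematics>\n")
  cat(sprintf("  curves: %d (side x joint x plane), 101-sample grid\n",
              nrow(dplyr::distinct(x$curves, .data$side, .data$joint, .data$plane))))
  cat(sprintf("  sides: %s\n", paste(unique(x$events$side), collapse = ", ")))
  cat(sprintf("  stride time: %s s\n",
              paste(sprintf("%s=%.2f", names(x$stride_time), x$stride_time), collapse = ", ")))
  invisible(x)
}

# pull one curve as a numeric vector of length 101 (ordered by cycle_pct)
curve_vector <- function(trial, side, joint, plane) {
  cv <- dplyr::filter(trial$curves, .data$side == !!side, .data$joint == !!joint,
                      .data$plane == !!plane)
  if (nrow(cv) == 0) {
    abort(sprintf("curve not found: side=%s joint=%s plane=%s", side, joint, plane))
  }
  cv$angle_deg[order(cv$cycle_pct)]
}

#' Write / read per-subject curves as long-format CSV
#'
#' Columns: `subject_id`, `side`, `joint`, `plane`, `cycle_pct`, `angle_deg`.
#'
#' @param trials Named list of [trial_kinematics()] objects (names are
#'   subject ids), or a `curve_cohort` as returned by [simulate_curves()].
#' @param path CSV path.
#' @return `write_curves_csv` returns `path` invisibly; `read_curves_csv`
#'   returns the long tibble.
#' @export
write_curves_csv <- function(trials, path) {
  if (inherits(trials, "curve_cohort")) trials <- trials$trials
  long <- dplyr::bind_rows(
    purrr::imap(trials, ~ dplyr::mutate(.x$curves, subject_id = .y, .before = 1)))
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}
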
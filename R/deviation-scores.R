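#' Default curve sets for the deviation scores
#'
#' `gps_curve_set()`: the lower-body set for the Gait Profile Score — pelvis
#' sagittal/frontal/transversal once plus hip (three planes), knee sagittal
#' and ankle sagittal for both sides (13 curves; the classic 15-curve set also
#' carries bilateral foot progression, which this container does not track).
#' `aps_curve_set()`: the upper-body analog for the Arm Posture Score —
#' thorax frontal/transversal plus affected-side shoulder (three planes) and
#' elbow sagittal. `gdi_curve_set()`: affected-side pelvis/hip (three planes
#' each), knee and ankle sagittal, concatenated for the Gait Deviation Index
#' feature space.
#'
#' @return A tibble with columns `side`, `joint`, `plane`.
#' @export
gps_curve_set <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(side = "affected", joint = "pelvis", plane = c("X", "Y", "Z")),
    tidyr::expand_grid(side = c("affected", "nonaffected"), joint = "hip",
                       plane = c("X", "Y", "Z")),
    tidyr::expand_grid(side = c("affected", "nonaffected"), joint = c("knee", "ankle"),
                       plane = "X"))
}

#' @rdname gps_curve_set
#' @export
aps_curve_set <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(side = "affected", joint = "thorax", plane = c("Y", "Z")),
    tidyr::expand_grid(side = "affected", joint = "shoulder", plane = c("X", "Y", "Z")),
    tidyr::expand_grid(side = "affected", joint = "elbow", plane = "X"))
}

#' @rdname gps_curve_set
#' @export
gdi_curve_set <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(side = "affected", joint = c("pelvis", "hip"),
                       plane = c("X", "Y", "Z")),
    tidyr::expand_grid(side = "affected", joint = c("knee", "ankle"), plane = "X"))
}

concat_curves <- function(trial, set) {
  unlist(purrr::pmap(set, function(side, joint, plane) {
    curve_vector(trial, side, joint, plane)
  }))
}

#' Fit control-group reference bands and the GDI feature basis
#'
#' From the control subjects of a curve-level cohort, computes the pointwise
#' mean and SD band of every available curve (the reference the deviation
#' scores are measured against) and fits the Gait Deviation Index feature
#' space: the concatenated GDI curve set of each control is centred on the
#' control mean and decomposed by SVD; the leading orthonormal components
#' covering at least `var_target` of control variance are retained, and the
#' control distribution of the log feature-space distance is stored for
#' z-scoring.
#'
#' @param cohort A `curve_cohort` from [simulate_curves()], or a named list of
#'   [trial_kinematics()] together with `groups`.
#' @param groups Optional factor/character of group labels parallel to the
#'   trials (needed when `cohort` is a bare list).
#' @param gdi_set,gps_set,aps_set Curve sets (tibbles `side`, `joint`,
#'   `plane`); defaults [gdi_curve_set()], [gps_curve_set()], [aps_curve_set()].
#' @param var_target Fraction of control variance the retained GDI components
#'   must cover; default 0.98.
#' @return An object of class `reference_bands`.
#' @export
fit_reference_bands <- function(cohort, groups = NULL,
                                gdi_set = gdi_curve_set(),
                                gps_set = gps_curve_set(),
                                aps_set = aps_curve_set(),
                                var_target = 0.98) {
  if (inherits(cohort, "curve_cohort")) {
    groups <- cohort$subjects$group
    trials <- cohort$trials
  } else {
    trials <- cohort
    assert_that(!is.null(groups) && length(groups) == length(trials),
                "`groups` must be given and parallel to the trials.")
  }
  ctrl <- trials[as.character(groups) == "control"]
  n_control <- length(ctrl)
  if (n_control < 10) {
    abort(sprintf("reference bands require >= 10 control subjects, got %d.", n_control))
  }

  all_curves <- dplyr::bind_rows(purrr::imap(
    ctrl, ~ dplyr::mutate(.x$curves, subject_id = .y)))
  bands <- dplyr::summarise(
    dplyr::group_by(all_curves, .data$side, .data$joint, .data$plane, .data$cycle_pct),
    mean = mean(.data$angle_deg), sd = stats::sd(.data$angle_deg), .groups = "drop")

  # GDI feature space from the control matrix (subjects x concatenated samples)
  M <- do.call(rbind, purrr::map(ctrl, concat_curves, set = gdi_set))
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  sv <- svd(Mc)
  var_comp <- sv$d^2 / max(sum(sv$d^2), .Machine$double.eps)
  k <- which(cumsum(var_comp) >= var_target)[1]
  if (is.na(k)) k <- length(sv$d)
  k <- min(k, n_control - 1)
  basis <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Mc %*% basis
  dist <- sqrt(rowSums(scores^2))
  if (any(dist <= 0)) {
    abort("a control subject coincides with the control mean in GDI feature space; log-distance undefined (degenerate, e.g. noise-free, reference cohort).")
  }
  ln <- log(dist)

  structure(list(
    bands = bands, n_control = n_control,
    gps_set = gps_set, aps_set = aps_set,
    gdi = list(set = gdi_set, center = center, basis = basis, k = k,
               var_explained = sum(var_comp[seq_len(k)]),
               ln_mu = mean(ln), ln_sd = stats::sd(ln))),
    class = "reference_bands")
}

#' @export
print.reference_bands <- function(x, ...) {
  cat("<reference_bands>\n")
  cat(sprintf("  fitted on %d controls; %d curves banded\n", x$n_control,
              nrow(dplyr::distinct(x$bands, .data$side, .data$joint, .data$plane))))
  cat(sprintf("  GDI basis: %d components (%.1f%% control variance)\n",
              x$gdi$k, 100 * x$gdi$var_explained))
  invisible(x)
}

reference_mean_curve <- function(reference, side, joint, plane) {
  b <- dplyr::filter(reference$bands, .data$side == !!side, .data$joint == !!joint,
                     .data$plane == !!plane)
  if (nrow(b) == 0) return(NULL)
  b$mean[order(b$cycle_pct)]
}

#' Root-mean-square deviation score over a curve set
#'
#' For each curve in the set, the RMS over the 101-point cycle of the
#' difference between the subject's curve and the control mean curve
#' (the per-variable sub-score); the overall score is the RMS of the
#' sub-scores. With the lower-body set this is the Gait Profile Score (GPS);
#' with the upper-body set, the Arm Posture Score (APS).
#'
#' @param trial A [trial_kinematics()].
#' @param reference A [fit_reference_bands()] object.
#' @param set Curve-set tibble (`side`, `joint`, `plane`); default the GPS set
#'   stored in `reference`.
#' @return A list with `score` (deg) and `sub_scores`
#'   (tibble `side`, `joint`, `plane`, `rms`).
#' @export
rms_deviation_score <- function(trial, reference, set = reference$gps_set) {
  missing <- character()
  subs <- purrr::pmap_dbl(set, function(side, joint, plane) {
    ref <- reference_mean_curve(reference, side, joint, plane)
    cv <- tryCatch(curve_vector(trial, side, joint, plane), error = function(e) NULL)
    if (is.null(ref) || is.null(cv)) {
      missing <<- c(missing, sprintf("%s/%s/%s", side, joint, plane))
      return(NA_real_)
    }
    sqrt(mean((cv - ref)^2))
  })
  if (length(missing) > 0) {
    abort(paste0("curves missing from subject or reference: ",
                 paste(missing, collapse = ", ")))
  }
  list(score = sqrt(mean(subs^2)),
       sub_scores = dplyr::mutate(tibble::as_tibble(set), rms = subs))
}

#' Gait Deviation Index
#'
#' Concatenates the subject's GDI curve set into one vector, projects it onto
#' the control-derived orthonormal basis, takes the natural log of the
#' Euclidean distance to the control mean in feature space, z-scores it
#' against the control distribution of the same quantity, and returns
#' `100 - 10 * z`. By construction the controls used to fit the reference
#' score 100 on average with SD 10; higher is closer to control gait.
#'
#' @param trial A [trial_kinematics()].
#' @param reference A [fit_reference_bands()] object.
#' @return A single finite score.
#' @export
gait_deviation_index <- function(trial, reference) {
  g <- reference$gdi
  x <- concat_curves(trial, g$set)
  s <- drop(crossprod(g$basis, x - g$center))
  dist <- sqrt(sum(s^2))
  if (dist <= 0) {
    abort("subject coincides with the control mean in GDI feature space; log-distance undefined.")
  }
  z <- (log(dist) - g$ln_mu) / g$ln_sd
  100 - 10 * z
}
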
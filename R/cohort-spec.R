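#' Default covariate parameters for a simulated two-group gait cohort
#'
#' Group-wise distributions for the three background covariates used
#' throughout (age in years, body-mass index in kg/m^2, and the proportion of
#' males), at the magnitudes typical of a chronic-phase stroke cohort with
#' non-disabled controls of similar age.
#'
#' @return A tibble with one row per covariate and group, columns
#'   `covariate`, `group`, `mean`, `sd` (NA for `sex`), `prop_male`
#'   (NA except for `sex`).
#' @export
default_covariate_params <- function() {
  tibble::tribble(
    ~covariate, ~group,    ~mean, ~sd,  ~prop_male,
    "age",      "stroke",  67.3,  10.5, NA,
    "age",      "control", 64.9,  11.5, NA,
    "bmi",      "stroke",  27.6,  3.9,  NA,
    "bmi",      "control", 24.9,  2.3,  NA,
    "sex",      "stroke",  NA,    NA,   18 / 31,
    "sex",      "control", NA,    NA,   21 / 41
  )
}

#' Default kinematic variable specifications
#'
#' An illustrative catalog of 29 kinematic gait variables spanning the classes
#' a whole-body gait analysis produces: spatiotemporal parameters, joint-angle
#' ranges of motion (ROM), maximal angles, the side-to-side ROM index,
#' body-inclination angles, and control-referenced deviation scores.
#' Control-group means/SDs and stroke-group mean shifts (in control-SD units)
#' are set to magnitudes reported for chronic hemiparetic gait; gait speed
#' uses the published cohort values 1.3 (0.1) m/s for controls and
#' 0.9 (0.3) m/s post-stroke. The headline discriminative variables are the
#' single-support and 2nd double-support durations, stride length, and pelvis
#' sagittal ROM.
#'
#' `loading` parameterizes the default within-group correlation structure (see
#' [default_correlation()]): spatiotemporal variables load strongly on a
#' common gait-speed factor, joint-angle variables moderately.
#'
#' @return A tibble with columns `variable`, `class`, `mean_control`,
#'   `sd_control`, `shift` (stroke mean shift in control-SD units),
#'   `sd_stroke`, `loading`.
#' @export
default_variable_specs <- function() {
  tibble::tribble(
    ~variable,                      ~class,            ~mean_control, ~sd_control, ~shift, ~sd_stroke, ~loading,
    "gait_speed",                   "spatiotemporal",  1.30,  0.10, -4.0,  0.30,  0.90,
    "stride_length",                "spatiotemporal",  1.35,  0.12, -2.9,  0.25,  0.88,
    "step_length",                  "spatiotemporal",  0.68,  0.06, -2.8,  0.13,  0.85,
    "step_width",                   "spatiotemporal",  0.12,  0.03,  1.0,  0.05, -0.25,
    "cadence",                      "spatiotemporal",  115,   8,    -1.9,  15,    0.70,
    "stride_time",                  "spatiotemporal",  1.05,  0.08,  2.5,  0.20, -0.75,
    "step_time",                    "spatiotemporal",  0.53,  0.04,  2.5,  0.10, -0.72,
    "swing_time",                   "spatiotemporal",  0.42,  0.03,  1.7,  0.08, -0.55,
    "stance_duration_pct",          "spatiotemporal",  61.0,  1.5,   2.7,  4.0,  -0.75,
    "ds1_duration_pct",             "spatiotemporal",  10.5,  1.3,   2.3,  3.0,  -0.70,
    "ds2_duration_pct",             "spatiotemporal",  10.5,  1.4,   3.2,  4.0,  -0.80,
    "single_support_pct",           "spatiotemporal",  40.0,  1.7,  -3.5,  5.0,   0.82,
    "temporal_symmetry",            "spatiotemporal",  1.00,  0.04,  2.0,  0.10, -0.45,
    "spatial_symmetry",             "spatiotemporal",  1.00,  0.04,  1.2,  0.10, -0.30,
    "pelvis_sag_rom",               "rom",             3.0,   0.8,   1.9,  1.7,  -0.20,
    "hip_sag_rom",                  "rom",             45,    4,    -1.2,  6,     0.45,
    "knee_sag_rom",                 "rom",             60,    5,    -2.0,  9,     0.50,
    "ankle_sag_rom",                "rom",             28,    4,    -1.7,  6,     0.40,
    "thorax_frontal_rom",           "rom",             7,     2.5,   0.6,  3.5,  -0.15,
    "shoulder_sag_rom",             "rom",             20,    7,    -0.5,  10,    0.20,
    "knee_flexion_max",             "max",             62,    5,    -1.4,  8,     0.45,
    "shoulder_abduction_max",       "max",             8,     4,     1.2,  7,    -0.15,
    "shoulder_sag_romi",            "romi",            1.00,  0.25, -1.2,  0.40,  0.10,
    "ankle_plantarflexion_push_off","stroke_specific", 15,    4,    -1.5,  5,     0.35,
    "knee_flexion_swing_max",       "stroke_specific", 60,    5,    -1.5,  8,     0.45,
    "acomia_stance_max",            "inclination",     28,    2.5,  -1.0,  4,     0.55,
    "hcomia_swing_max",             "inclination",     2.5,   0.8,   0.3,  1.0,  -0.10,
    "gps",                          "deviation",       4.0,   0.9,   3.3,  2.2,  -0.40,
    "aps",                          "deviation",       4.5,   1.2,   2.5,  2.8,  -0.35,
  )
}

#' Default within-group correlation matrix
#'
#' A single-factor (rank-one loading) correlation model
#' \eqn{R_{ij} = \lambda_i \lambda_j} (for \eqn{i \ne j}), which is positive
#' semi-definite by construction for loadings in \eqn{[-1, 1]}. The common
#' factor is interpretable as overall gait speed/ability: spatiotemporal
#' variables load at |0.7--0.9|, emulating the strong inter-correlation of
#' spatiotemporal parameters seen in real gait data, while joint-angle and
#' deviation-score variables load weakly to moderately.
#'
#' @param variables A variable-spec tibble as returned by
#'   [default_variable_specs()] (must contain `variable` and `loading`).
#' @return A named correlation matrix.
#' @export
default_correlation <- function(variables = default_variable_specs()) {
  lam <- variables$loading
  R <- outer(lam, lam)
  diag(R) <- 1
  dimnames(R) <- list(variables$variable, variables$variable)
  R
}

#' Specify a two-group synthetic gait cohort
#'
#' Bundles group sizes, covariate distributions, per-variable control-group
#' means/SDs with stroke-group mean shifts, and a within-group correlation
#' matrix into a validated specification for [simulate_cohort()].
#'
#' @param n_stroke,n_control Group sizes (each at least 2); defaults 31 and 41.
#' @param covariates Covariate parameter tibble, see
#'   [default_covariate_params()].
#' @param variables Variable-spec tibble, see [default_variable_specs()].
#'   `sd_stroke` may be omitted, in which case the control SD is reused.
#' @param correlation Within-group correlation matrix over the variables (same
#'   order as `variables`). Default: [default_correlation()] on `variables`.
#'   Must be symmetric with unit diagonal and eigenvalues >= -1e-8.
#' @param confounded If `TRUE`, variable means additionally depend on age,
#'   BMI and sex (0.3 control-SD per covariate SD), so that unadjusted and
#'   covariate-adjusted group contrasts differ; used to exercise the
#'   screening stage's covariate adjustment.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stroke = 31, n_control = 41,
                        covariates = default_covariate_params(),
                        variables = default_variable_specs(),
                        correlation = NULL,
                        confounded = FALSE) {
  assert_that(is_count(n_stroke) && n_stroke >= 2, "`n_stroke` must be an integer >= 2.")
  assert_that(is_count(n_control) && n_control >= 2, "`n_control` must be an integer >= 2.")
  variables <- tibble::as_tibble(variables)
  req <- c("variable", "mean_control", "sd_control", "shift")
  assert_that(all(req %in% names(variables)),
              paste0("`variables` must contain columns: ", paste(req, collapse = ", "), "."))
  assert_that(!anyDuplicated(variables$variable), "duplicated variable names in `variables`.")
  if (!"sd_stroke" %in% names(variables)) variables$sd_stroke <- variables$sd_control
  variables$sd_stroke <- dplyr::coalesce(variables$sd_stroke, variables$sd_control)
  if (!"class" %in% names(variables)) variables$class <- "unspecified"
  assert_that(all(variables$sd_control > 0) && all(variables$sd_stroke > 0),
              "all variable SDs must be > 0.")
  if (is.null(correlation)) {
    if (!"loading" %in% names(variables)) {
      correlation <- diag(nrow(variables))
      dimnames(correlation) <- list(variables$variable, variables$variable)
    } else {
      correlation <- default_correlation(variables)
    }
  }
  validate_correlation(correlation, variables$variable)
  spec <- structure(
    list(n_stroke = as.integer(n_stroke), n_control = as.integer(n_control),
         covariates = tibble::as_tibble(covariates), variables = variables,
         correlation = correlation, confounded = isTRUE(confounded)),
    class = "cohort_spec")
  spec
}

# correlation matrix invariants; the PSD failure names the offending eigenvalue
validate_correlation <- function(R, variable_names) {
  assert_that(is.matrix(R) && nrow(R) == ncol(R), "`correlation` must be a square matrix.")
  assert_that(nrow(R) == length(variable_names),
              "`correlation` dimension must match the number of variables.")
  assert_that(max(abs(R - t(R))) < 1e-10, "`correlation` must be symmetric.")
  assert_that(max(abs(diag(R) - 1)) < 1e-10, "`correlation` must have unit diagonal.")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "`correlation` is not positive semi-definite: smallest eigenvalue %.3e < -1e-8.",
      min(ev)))
  }
  invisible(TRUE)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  groups: %d stroke / %d control\n", x$n_stroke, x$n_control))
  cat(sprintf("  variables: %d (%s)\n", nrow(x$variables),
              paste(unique(x$variables$class), collapse = ", ")))
  cat(sprintf("  confounded covariates: %s\n", x$confounded))
  invisible(x)
}

#' Read a cohort specification from a YAML file
#'
#' The YAML mirrors the [cohort_spec()] arguments: scalar `n_stroke`,
#' `n_control`, optional `confounded`, a `variables` list of records
#' (`variable`, `mean_control`, `sd_control`, `shift`, optional `sd_stroke`,
#' `loading`, `class`), and optionally either `correlation: identity` or a
#' full numeric matrix (list of rows).
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- if (!is.null(y$variables)) {
    dplyr::bind_rows(lapply(y$variables, tibble::as_tibble))
  } else default_variable_specs()
  corr <- NULL
  if (!is.null(y$correlation)) {
    if (identical(y$correlation, "identity")) {
      corr <- diag(nrow(vars))
      dimnames(corr) <- list(vars$variable, vars$variable)
    } else {
      corr <- do.call(rbind, lapply(y$correlation, as.numeric))
      dimnames(corr) <- list(vars$variable, vars$variable)
    }
  }
  cohort_spec(n_stroke = y$n_stroke %||% 31, n_control = y$n_control %||% 41,
              variables = vars, correlation = corr,
              confounded = y$confounded %||% FALSE)
}
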
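
# run code under a local RNG state so simulation never disturbs the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a subject-level gait variable table
#'
#' Draws a two-group cohort from a specification: within each group the
#' kinematic variables follow a multivariate normal with the group means/SDs
#' and the shared within-group correlation matrix (a Gaussian copula with
#' normal margins), while covariates (age, BMI, sex) are drawn independently
#' from their group distributions. In confounded mode each variable's mean
#' additionally shifts with the subject's standardized age, BMI and sex.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same spec and seed reproduce the table exactly.
#' @return A tibble with columns `subject_id`, `group` (factor,
#'   control/stroke), `age`, `sex` (0/1, 1 = male), `bmi`, then one column per
#'   kinematic variable.
#' @examples
#' tab <- simulate_cohort(cohort_spec(), seed = 1)
#' dplyr::count(tab, group)
#' @export
simulate_cohort <- function(spec, seed) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec.")
  assert_that(is_count(seed) || (is.numeric(seed) && seed == round(seed)),
              "`seed` must be an integer.")
  with_local_seed(seed, {
    groups <- list(stroke = spec$n_stroke, control = spec$n_control)
    tabs <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      sds <- if (g == "stroke") spec$variables$sd_stroke else spec$variables$sd_control
      mus <- spec$variables$mean_control +
        if (g == "stroke") spec$variables$shift * spec$variables$sd_control else 0
      Sigma <- diag(sds, nrow = length(sds)) %*% spec$correlation %*% diag(sds, nrow = length(sds))
      X <- MASS::mvrnorm(n, mu = mus, Sigma = Sigma)
      X <- matrix(X, nrow = n)  # mvrnorm drops dims when n == 1 columns edge cases
      colnames(X) <- spec$variables$variable
      cov <- draw_covariates(spec$covariates, g, n)
      if (spec$confounded) {
        # 0.3 control-SD shift per covariate SD (standardized against the
        # control reference, so group covariate imbalance biases the
        # unadjusted contrast and Step-I adjustment has work to do)
        zage <- (cov$age - mean_param(spec$covariates, "age", "control")) /
          sd_param(spec$covariates, "age", "control")
        zbmi <- (cov$bmi - mean_param(spec$covariates, "bmi", "control")) /
          sd_param(spec$covariates, "bmi", "control")
        zsex <- cov$sex - 0.5
        shift <- outer(zage + zbmi + zsex, 0.3 * spec$variables$sd_control)
        X <- X + shift
      }
      dplyr::bind_cols(tibble::tibble(group = g), cov, tibble::as_tibble(X))
    })
    out <- dplyr::bind_rows(tabs)
    out <- dplyr::mutate(out,
                         subject_id = sprintf("S%03d", dplyr::row_number()),
                         group = as_group_factor(.data$group),
                         .before = 1)
    dplyr::relocate(out, "subject_id", "group", "age", "sex", "bmi")
  })
}

mean_param <- function(cov, covariate, group) {
  cov$mean[cov$covariate == covariate & cov$group == group]
}
sd_param <- function(cov, covariate, group) {
  cov$sd[cov$covariate == covariate & cov$group == group]
}

draw_covariates <- function(cov_params, group, n) {
  tibble::tibble(
    age = rnorm(n, mean_param(cov_params, "age", group), sd_param(cov_params, "age", group)),
    sex = rbinom(n, 1, cov_params$prop_male[cov_params$covariate == "sex" &
                                              cov_params$group == group]),
    bmi = rnorm(n, mean_param(cov_params, "bmi", group), sd_param(cov_params, "bmi", group))
  )
}

#' Write / read a subject variable table as CSV
#'
#' Plain CSV with `.` as decimal separator regardless of locale; the group
#' column round-trips as a control/stroke factor.
#'
#' @param table Subject variable table (as from [simulate_cohort()]).
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the tibble.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           fileEncoding = "UTF-8"))
  if ("group" %in% names(out)) out$group <- as_group_factor(out$group)
  out
}
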
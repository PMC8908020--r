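#' Screen one variable for a covariate-adjusted group difference
#'
#' Ordinary least squares of the variable on an intercept, the group indicator
#' (1 = stroke) and the covariates, with a two-sided t test on the group
#' coefficient. The coefficient reads as the stroke-minus-control difference
#' adjusted for the covariates. Missing values are dropped listwise and the
#' number of subjects used is reported.
#'
#' @param table Subject variable table with a `group` column
#'   (control/stroke) and the variable and covariate columns.
#' @param variable Name of the outcome variable.
#' @param covariates Character vector of covariate column names; default
#'   `c("age", "sex", "bmi")`.
#' @param alpha Two-sided significance level for the include flag;
#'   default 0.05 (unadjusted for multiplicity).
#' @return A one-row tibble: `variable`, `estimate` (group coefficient),
#'   `std_error`, `statistic`, `p_value`, `n_used`, `n_missing`, `included`.
#' @export
screen_variable <- function(table, variable, covariates = c("age", "sex", "bmi"),
                            alpha = 0.05) {
  assert_that(variable %in% names(table), sprintf("variable `%s` not in table.", variable))
  assert_that(all(covariates %in% names(table)),
              paste0("missing covariate columns: ",
                     paste(setdiff(covariates, names(table)), collapse = ", ")))
  dat <- dplyr::transmute(
    tibble::as_tibble(table),
    .y = .data[[variable]],
    .group = group_indicator(.data$group),
    !!!rlang::syms(setNames(covariates, covariates)))
  n0 <- nrow(dat)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_missing <- n0 - nrow(dat)
  assert_that(sum(dat$.group == 1) >= 2 && sum(dat$.group == 0) >= 2,
              "need at least 2 subjects per group after listwise deletion.")
  rhs <- paste(c(".group", covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  if (anyNA(coef(fit))) {
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".group", "Estimate"]
  se <- sm[".group", "Std. Error"]
  tval <- sm[".group", "t value"]
  pval <- sm[".group", "Pr(>|t|)"]
  tibble::tibble(variable = variable, estimate = est, std_error = se,
                 statistic = tval, p_value = pval, n_used = nrow(dat),
                 n_missing = n_missing, included = pval < alpha)
}

#' Screen a catalog of variables (Step I)
#'
#' Runs [screen_variable()] for every catalog variable and partitions the
#' catalog into the included set (significant covariate-adjusted group
#' difference at `alpha`) and the excluded set. No multiplicity adjustment is
#' applied. Per-variable failures are collected, not fatal.
#'
#' @param table Subject variable table.
#' @param catalog Character vector of variable names; default every numeric
#'   column that is not a covariate or identifier.
#' @param covariates,alpha Passed to [screen_variable()].
#' @return An object of class `gait_screen`: a tibble of per-variable results
#'   in catalog order with attributes `alpha`, `covariates`, `errors`.
#' @examples
#' tab <- simulate_cohort(cohort_spec(), seed = 7)
#' scr <- screen_all(tab)
#' included_variables(scr)
#' @export
screen_all <- function(table, catalog = NULL, covariates = c("age", "sex", "bmi"),
                       alpha = 0.05) {
  if (is.null(catalog)) {
    skip <- c("subject_id", "group", covariates)
    catalog <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], skip)
  }
  assert_that(all(catalog %in% names(table)),
              paste0("catalog variables not in table: ",
                     paste(setdiff(catalog, names(table)), collapse = ", ")))
  errors <- list()
  rows <- purrr::map(catalog, function(v) {
    tryCatch(screen_variable(table, v, covariates, alpha),
             error = function(e) {
               errors[[v]] <<- conditionMessage(e)
               tibble::tibble(variable = v, estimate = NA_real_,
                              std_error = NA_real_, statistic = NA_real_,
                              p_value = NA_real_, n_used = NA_integer_,
                              n_missing = NA_integer_, included = FALSE)
             })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, alpha = alpha, covariates = covariates, errors = errors,
            class = c("gait_screen", class(out)))
}

#' @rdname screen_all
#' @param screen A `gait_screen` result.
#' @export
included_variables <- function(screen) {
  screen$variable[screen$included]
}

#' Welch two-sample t test from summary statistics
#'
#' The unequal-variance t test computed directly from printed group means,
#' SDs and sizes — the form used for descriptive group comparisons of
#' background variables (age, BMI, gait speed) in cohort tables.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return A tibble: `estimate` (mean1 - mean2), `statistic`, `df`, `p_value`.
#' @examples
#' welch_from_summary(67.3, 10.5, 31, 64.9, 11.5, 41)
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(estimate = mean1 - mean2, statistic = tval, df = df,
                 p_value = 2 * pt(-abs(tval), df))
}

#' Group descriptive comparisons (background-characteristics table)
#'
#' Means (SD) per group with Welch t-test p-values for continuous covariates
#' and counts with a continuity-corrected chi-squared p-value for sex,
#' mirroring the conventional participant-characteristics table.
#'
#' @param table Subject variable table with `group`, continuous covariates and
#'   a 0/1 `sex` column.
#' @param continuous Character vector of continuous covariate names.
#' @return A tibble with one row per covariate: group summaries and `p_value`.
#' @export
group_descriptives <- function(table, continuous = c("age", "bmi")) {
  g <- as_group_factor(table$group)
  rows <- purrr::map(continuous, function(v) {
    x <- split(table[[v]], g)
    w <- welch_from_summary(mean(x$stroke), sd(x$stroke), length(x$stroke),
                            mean(x$control), sd(x$control), length(x$control))
    tibble::tibble(covariate = v,
                   stroke = sprintf("%.1f (%.1f)", mean(x$stroke), sd(x$stroke)),
                   control = sprintf("%.1f (%.1f)", mean(x$control), sd(x$control)),
                   p_value = w$p_value)
  })
  out <- dplyr::bind_rows(rows)
  if ("sex" %in% names(table)) {
    cnt <- table(g, factor(table$sex, levels = c(0, 1)))
    p <- suppressWarnings(stats::chisq.test(cnt, correct = TRUE)$p.value)
    out <- dplyr::bind_rows(out, tibble::tibble(
      covariate = "sex",
      stroke = sprintf("%d/%d", cnt["stroke", "1"], cnt["stroke", "0"]),
      control = sprintf("%d/%d", cnt["control", "1"], cnt["control", "0"]),
      p_value = p))
  }
  out
}
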
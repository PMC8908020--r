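#' Spearman rank correlation matrix, pooled or per group
#'
#' Pairwise Spearman correlations over the variables of interest: rho is the
#' Pearson correlation of mid-ranks (average ranks for ties) on
#' pairwise-complete observations, with the two-sided p-value from the t
#' approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}. Computed on the
#' pooled cohort or within one group; comparing the pooled matrix with the
#' per-group matrices separates correlation that is genuinely within-group
#' from correlation induced by the group mean difference.
#'
#' @param table Subject variable table with `group` and the variables.
#' @param variables Character vector of variable names; default all numeric
#'   non-covariate columns.
#' @param grouping `"pooled"` (default), `"stroke"`, or `"control"`.
#' @return An object of class `gait_corr`: tibble in long format (`var1`,
#'   `var2`, `rho`, `p_value`, `n`, `reason` for undefined pairs) with
#'   attributes `grouping` and `variables`. `rho` for a variable constant
#'   within the grouping is `NA` with the reason recorded, never 0.
#' @examples
#' tab <- simulate_cohort(cohort_spec(), seed = 5)
#' cm <- spearman_matrix(tab, c("gait_speed", "stride_length", "cadence"))
#' corr_wide(cm)
#' @export
spearman_matrix <- function(table, variables = NULL,
                            grouping = c("pooled", "stroke", "control")) {
  grouping <- match.arg(grouping)
  tab <- tibble::as_tibble(table)
  if (is.null(variables)) {
    skip <- c("subject_id", "group", "age", "sex", "bmi")
    variables <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], skip)
  }
  assert_that(all(variables %in% names(tab)),
              paste0("variables not in table: ",
                     paste(setdiff(variables, names(tab)), collapse = ", ")))
  if (grouping != "pooled") {
    tab <- tab[as.character(as_group_factor(tab$group)) == grouping, , drop = FALSE]
  }
  assert_that(nrow(tab) >= 4, "need at least 4 subjects in the selected grouping.")

  pairs <- tidyr::expand_grid(var1 = variables, var2 = variables)
  res <- purrr::pmap(pairs, function(var1, var2) {
    x <- tab[[var1]]
    y <- tab[[var2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) {
      return(tibble::tibble(var1 = var1, var2 = var2, rho = NA_real_,
                            p_value = NA_real_, n = n,
                            reason = "fewer than 4 complete pairs"))
    }
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(var1 = var1, var2 = var2, rho = NA_real_,
                            p_value = NA_real_, n = n,
                            reason = sprintf("`%s` constant within grouping",
                                             if (sd(x) == 0) var1 else var2)))
    }
    rho <- stats::cor(rank(x), rank(y))
    p <- if (var1 == var2) 0 else spearman_p_t(rho, n)
    tibble::tibble(var1 = var1, var2 = var2, rho = rho, p_value = p, n = n,
                   reason = NA_character_)
  })
  out <- dplyr::bind_rows(res)
  structure(out, grouping = grouping, variables = variables,
            class = c("gait_corr", class(out)))
}

spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), n - 2)
}

#' Reshape a correlation result to a wide rho matrix
#'
#' @param corr A `gait_corr` from [spearman_matrix()].
#' @param value Which entry to spread: `"rho"` (default) or `"p_value"`.
#' @return A named numeric matrix.
#' @export
corr_wide <- function(corr, value = c("rho", "p_value")) {
  value <- match.arg(value)
  vars <- attr(corr, "variables")
  M <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  M[cbind(match(corr$var1, vars), match(corr$var2, vars))] <- corr[[value]]
  M
}

#' @export
tidy.gait_corr <- function(x, ...) {
  dplyr::filter(tibble::as_tibble(x), .data$var1 < .data$var2)
}

#' @export
glance.gait_corr <- function(x, ...) {
  off <- dplyr::filter(tibble::as_tibble(x), .data$var1 < .data$var2)
  tibble::tibble(grouping = attr(x, "grouping"),
                 n_pairs = nrow(off),
                 n_significant = sum(off$p_value < 0.05, na.rm = TRUE),
                 mean_abs_rho = mean(abs(off$rho), na.rm = TRUE))
}
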
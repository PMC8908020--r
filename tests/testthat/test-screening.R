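test_that("a perfect group effect screens in with a vanishing p-value", {
  set.seed(1)
  tab <- tibble::tibble(
    group = factor(rep(c("stroke", "control"), c(10, 10)), levels = c("control", "stroke")),
    age = rnorm(20, 65, 10), sex = rbinom(20, 1, 0.5), bmi = rnorm(20, 26, 3),
    v = as.integer(rep(c(1, 0), c(10, 10))) + rnorm(20, 0, 1e-6))
  res <- screen_variable(tab, "v")
  expect_lt(res$p_value, 1e-10)
  expect_true(res$included)
  expect_equal(res$estimate, 1, tolerance = 1e-4)
})

test_that("the group coefficient matches the normal-equations oracle", {
  set.seed(2)
  n <- 10
  tab <- tibble::tibble(
    group = factor(rep(c("stroke", "control"), each = 5), levels = c("control", "stroke")),
    age = rnorm(n, 65, 10), sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 26, 3),
    v = rnorm(n, 12, 3))
  res <- screen_variable(tab, "v")
  X <- cbind(1, as.integer(tab$group == "stroke"), tab$age, tab$sex, tab$bmi)
  beta <- solve(t(X) %*% X, t(X) %*% tab$v)
  expect_equal(res$estimate, beta[2, 1], tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear column named", {
  set.seed(3)
  tab <- tibble::tibble(
    group = factor(rep(c("stroke", "control"), each = 6), levels = c("control", "stroke")),
    age = rnorm(12, 65, 10), sex = rbinom(12, 1, 0.5), bmi = NA_real_,
    v = rnorm(12))
  tab$bmi <- 2 * tab$age + 1  # exactly collinear
  expect_error(screen_variable(tab, "v"), "collinear.*bmi")
})

test_that("missing values are dropped listwise and counted", {
  set.seed(4)
  tab <- tibble::tibble(
    group = factor(rep(c("stroke", "control"), each = 10), levels = c("control", "stroke")),
    age = rnorm(20, 65, 10), sex = rbinom(20, 1, 0.5), bmi = rnorm(20, 26, 3),
    v = rnorm(20))
  tab$v[c(1, 15)] <- NA
  res <- screen_variable(tab, "v")
  expect_equal(res$n_used, 18L)
  expect_equal(res$n_missing, 2L)
})

test_that("null p-values are uniform (KS) and the batch partitions by alpha", {
  set.seed(5)
  spec <- null_cohort_spec(p = 10)
  pvals <- c()
  for (s in 1:50) {
    tab <- simulate_cohort(spec, seed = 5000 + s)
    scr <- screen_all(tab)
    pvals <- c(pvals, scr$p_value)
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
  tab <- simulate_cohort(spec, seed = 99)
  scr <- screen_all(tab)
  expect_identical(scr$included, scr$p_value < attr(scr, "alpha"))
  expect_identical(included_variables(scr), scr$variable[scr$included])
})

test_that("planted effects of >= 1.5 SD are recovered with high power at 31/41", {
  spec <- small_cohort_spec()
  effects <- spec$variables$variable[abs(spec$variables$shift) >= 1.5]
  all_in <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    tab <- simulate_cohort(spec, seed = 7000 + s)
    inc <- included_variables(screen_all(tab))
    all_in <- all_in + as.integer(all(effects %in% inc))
  }
  expect_gte(all_in / n_seeds, 0.95)
})

test_that("covariate adjustment removes confounding-induced differences", {
  vars <- null_cohort_spec(p = 8)$variables
  spec <- cohort_spec(variables = vars, confounded = TRUE)
  inc_adj <- 0L; inc_raw <- 0L; total <- 0L
  for (s in 1:30) {
    tab <- simulate_cohort(spec, seed = 8000 + s)
    adj <- screen_all(tab)
    raw <- screen_all(tab, covariates = character(0))
    inc_adj <- inc_adj + sum(adj$included)
    inc_raw <- inc_raw + sum(raw$included)
    total <- total + nrow(adj)
  }
  # BMI differs between groups and drives the variables: unadjusted screening
  # flags spurious group differences, adjusted screening stays near alpha
  expect_gt(inc_raw / total, 0.25)
  expect_lt(inc_adj / total, 0.12)
})

test_that("Welch test from summary statistics matches t.test on raw data", {
  set.seed(6)
  x <- rnorm(31, 67, 10); y <- rnorm(41, 65, 11)
  w <- welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  tt <- t.test(x, y)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-10)
})

test_that("group descriptives produce Welch and chi-squared comparisons", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 17)
  d <- group_descriptives(tab)
  expect_setequal(d$covariate, c("age", "bmi", "sex"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})
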
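test_that("cohort simulation is reproducible and respects group sizes", {
  spec <- small_cohort_spec()
  a <- simulate_cohort(spec, seed = 42)
  b <- simulate_cohort(spec, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 72)
  expect_equal(sum(a$group == "stroke"), 31)
  expect_equal(sum(a$group == "control"), 41)
  c2 <- simulate_cohort(spec, seed = 43)
  expect_false(identical(a$gait_speed, c2$gait_speed))
})

test_that("group means land near their specification (gait speed 0.9 / 1.3)", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 7)
  ms <- mean(tab$gait_speed[tab$group == "stroke"])
  mc <- mean(tab$gait_speed[tab$group == "control"])
  expect_lt(abs(ms - 0.9), 3 * 0.3 / sqrt(31))
  expect_lt(abs(mc - 1.3), 3 * 0.1 / sqrt(41))
})

test_that("sample moments converge at large n", {
  spec <- small_cohort_spec(n_stroke = 10000, n_control = 10000)
  tab <- simulate_cohort(spec, seed = 11)
  v <- spec$variables
  for (i in seq_len(nrow(v))) {
    x <- tab[[v$variable[i]]]
    m_ctrl <- mean(x[tab$group == "control"])
    m_str <- mean(x[tab$group == "stroke"])
    expect_lt(abs(m_ctrl - v$mean_control[i]), 0.05 * v$sd_control[i])
    expect_lt(abs(m_str - (v$mean_control[i] + v$shift[i] * v$sd_control[i])),
              0.05 * v$sd_stroke[i])
  }
})

test_that("empirical Spearman correlations match the Gaussian-copula expectation", {
  spec <- small_cohort_spec(n_stroke = 10000, n_control = 10000)
  tab <- simulate_cohort(spec, seed = 13)
  ctrl <- tab[tab$group == "control", ]
  R <- spec$correlation
  for (pair in list(c("gait_speed", "single_support_pct"),
                    c("gait_speed", "pelvis_sag_rom"),
                    c("single_support_pct", "aps"))) {
    rho_pearson <- R[pair[1], pair[2]]
    expected_rho_s <- (6 / pi) * asin(rho_pearson / 2)
    got <- cor(ctrl[[pair[1]]], ctrl[[pair[2]]], method = "spearman")
    expect_lt(abs(got - expected_rho_s), 0.05)
  }
})

test_that("null generator is calibrated: ~5% significant two-sample tests", {
  spec <- null_cohort_spec(p = 25)
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    tab <- simulate_cohort(spec, seed = 1000 + s)
    for (v in spec$variables$variable) {
      p <- t.test(tab[[v]] ~ tab$group)$p.value
      hits <- hits + (p < 0.05); total <- total + 1L
    }
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.09)
})

test_that("a non-PSD correlation matrix is rejected with its eigenvalue named", {
  vars <- null_cohort_spec(p = 3)$variables
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  dimnames(R) <- list(vars$variable, vars$variable)
  expect_error(cohort_spec(variables = vars, correlation = R),
               "positive semi-definite.*eigenvalue")
  R2 <- diag(0.5, 3)
  dimnames(R2) <- list(vars$variable, vars$variable)
  expect_error(cohort_spec(variables = vars, correlation = R2), "unit diagonal")
})

test_that("zero-noise curve generation reproduces the Fourier template exactly", {
  cs <- default_curve_specs()
  cs$curves$subject_sd <- 0
  cs$curves$noise_sd <- 0
  cs$events$sd <- 0
  cc <- simulate_curves(cohort_spec(n_stroke = 3, n_control = 3), cs, seed = 5)
  t <- seq(0, 1, length.out = 101)
  row <- cs$curves[cs$curves$joint == "hip" & cs$curves$plane == "X", ]
  ks <- seq_along(row$a[[1]])
  template <- row$a0 +
    sapply(t, function(tt) sum(row$a[[1]] * cos(2 * pi * ks * tt) +
                                 row$b[[1]] * sin(2 * pi * ks * tt)))
  ctrl_id <- cc$subjects$subject_id[cc$subjects$group == "control"][1]
  got <- dplyr::filter(cc$trials[[ctrl_id]]$curves, joint == "hip", plane == "X",
                       side == "affected")$angle_deg
  expect_equal(got, unname(template), tolerance = 1e-10)
  # events with SD 0: all subjects share identical phase durations
  ev <- dplyr::bind_rows(lapply(cc$trials, function(tr) tr$events))
  ctrl_ev <- ev[rep(cc$subjects$group == "control", each = 2), ]
  expect_equal(length(unique(ctrl_ev$foot_off[ctrl_ev$side == "affected"])), 1L)
})

test_that("a configured stroke-side amplitude increase shifts extracted ROM upward", {
  cc <- simulate_curves(cohort_spec(n_stroke = 15, n_control = 15), seed = 21)
  roms <- vapply(cc$trials, function(tr)
    rom(dplyr::filter(tr$curves, joint == "pelvis", plane == "X",
                      side == "affected")$angle_deg), numeric(1))
  g <- cc$subjects$group
  # pelvis sagittal template is scaled by 1.6 on the affected stroke side
  expect_gt(mean(roms[g == "stroke"]), mean(roms[g == "control"]))
})

test_that("cohort specs round-trip through YAML", {
  spec <- small_cohort_spec()
  path <- tempfile(fileext = ".yaml")
  y <- list(n_stroke = 31, n_control = 41,
            variables = purrr::pmap(spec$variables, list),
            correlation = "identity")
  yaml::write_yaml(y, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(spec2$n_stroke, 31)
  expect_equal(spec2$variables$variable, spec$variables$variable)
  expect_equal(unname(spec2$correlation), diag(6))
  # the shipped example config loads and simulates
  shipped <- read_cohort_spec(system.file("extdata", "example_cohort.yaml",
                                          package = "gaitcoreset"))
  tab <- simulate_cohort(shipped, seed = 1)
  expect_equal(nrow(tab), 72)
  expect_true("gait_speed" %in% names(tab))
})
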
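test_that("LOOCV matches the naive fold-by-fold glm oracle", {
  tab <- eight_subject_fixture()
  for (vars in list("x_info", "x_noise", c("x_info", "x_noise"))) {
    got <- loocv_mr(tab, vars)
    oracle <- naive_loocv_oracle(tab, vars)
    expect_equal(got$per_subject$prob_stroke, oracle$prob, tolerance = 1e-5)
    expect_equal(got$mr, oracle$mr)
  }
  # and on a larger simulated cohort
  big <- simulate_cohort(small_cohort_spec(), seed = 31)
  got <- loocv_mr(big, c("gait_speed", "pelvis_sag_rom"))
  oracle <- naive_loocv_oracle(big, c("gait_speed", "pelvis_sag_rom"))
  expect_equal(got$mr, oracle$mr)
  expect_equal(got$per_subject$prob_stroke, oracle$prob, tolerance = 1e-4)
})

test_that("a cleanly separating variable yields MR 0 with an empty error off-diagonal", {
  tab <- tibble::tibble(
    group = factor(rep(c("stroke", "control"), c(10, 12)), levels = c("control", "stroke")),
    v = c(rnorm(10, 20, 0.5), rnorm(12, 0, 0.5)))
  res <- loocv_mr(tab, "v")
  expect_equal(res$mr, 0)
  pr <- setNames(res$confusion$proportion, res$confusion$outcome)
  expect_equal(unname(pr["false_positive"]), 0)
  expect_equal(unname(pr["false_negative"]), 0)
  expect_equal(unname(pr["true_positive"]), 10 / 22)
  expect_gt(res$n_flagged_folds, 0)  # folds separate; flagged, not discarded
})

test_that("a probability exactly at the threshold classifies as control", {
  # strict "above threshold": re-running with the threshold set to a
  # subject's achieved probability must flip that subject to control
  tab <- simulate_cohort(small_cohort_spec(), seed = 29)
  base <- loocv_mr(tab, "pelvis_sag_rom")
  i <- which.max(base$per_subject$prob_stroke *
                   (base$per_subject$classified == "stroke"))
  thr <- base$per_subject$prob_stroke[i]
  res <- loocv_mr(tab, "pelvis_sag_rom", threshold = thr)
  expect_equal(as.character(res$per_subject$classified[i]), "control")
})

test_that("confusion rates are proportions of n that sum to one with MR = FP + FN", {
  rep_ <- confusion_report(tp = 28, tn = 41, fp = 0, fn = 3)
  r <- setNames(rep_$rate, rep_$outcome)
  expect_equal(unname(r["true_positive"]), 0.39)
  expect_equal(unname(r["true_negative"]), 0.57)
  expect_equal(unname(r["false_positive"]), 0.00)
  expect_equal(unname(r["false_negative"]), 0.04)
  expect_equal(sum(rep_$proportion), 1)
  tab <- simulate_cohort(small_cohort_spec(), seed = 37)
  res <- loocv_mr(tab, "single_support_pct")
  pr <- setNames(res$confusion$proportion, res$confusion$outcome)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(res$mr, unname(pr["false_positive"] + pr["false_negative"]),
               tolerance = 1e-12)
})

test_that("core-set enumeration matches binomial sums and a bitmask oracle", {
  expect_length(enumerate_coresets(sprintf("v%02d", 1:25), 4), 15275)
  expect_length(enumerate_coresets(c("a", "b", "c"), 3), 7)
  expect_error(enumerate_coresets(c("a", "b"), 3), "exceeds")
  expect_error(enumerate_coresets(c("a", "a"), 1), "distinct")
  # bitmask oracle on 10 variables, sizes 1..3
  vars <- sort(sprintf("w%02d", 1:10))
  got <- enumerate_coresets(vars, 3)
  oracle <- list()
  for (m in 1:(2^10 - 1)) {
    bits <- which(bitwAnd(m, 2^(0:9)) > 0)
    if (length(bits) <= 3) oracle[[length(oracle) + 1]] <- vars[bits]
  }
  key <- function(s) paste(sort(s), collapse = "|")
  expect_setequal(vapply(got, key, character(1)), vapply(oracle, key, character(1)))
  # deterministic order: by size then lexicographic
  sizes <- lengths(got)
  expect_true(all(diff(sizes) >= 0))
  labs <- vapply(got, paste, character(1), collapse = "|")
  for (k in 1:3) expect_false(is.unsorted(labs[sizes == k]))
})

test_that("MR is invariant to predictor rescaling and row order", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 41)
  base <- loocv_mr(tab, c("gait_speed", "aps"))
  scaled <- dplyr::mutate(tab, gait_speed = gait_speed * 1000, aps = aps / 1000)
  expect_equal(loocv_mr(scaled, c("gait_speed", "aps"))$mr, base$mr)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(loocv_mr(shuffled, c("gait_speed", "aps"))$mr, base$mr)
})

test_that("search results equal direct loocv_mr on the same subsets", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 43)
  cands <- c("gait_speed", "single_support_pct", "pelvis_sag_rom", "aps")
  sr <- search_coresets(tab, cands, max_size = 2)
  expect_equal(nrow(sr$results), 4 + 6)
  for (i in seq_len(nrow(sr$results))) {
    direct <- loocv_mr(tab, sr$results$variables[[i]])
    expect_equal(sr$results$mr[i], direct$mr)
  }
  # ranked by (mr, size, label)
  expect_false(is.unsorted(sr$results$mr))
})

test_that("constrained searches never admit out-of-class variables", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 47)
  st_vars <- c("gait_speed", "single_support_pct")
  sr <- search_coresets(tab, c(st_vars, "pelvis_sag_rom", "aps"), max_size = 2,
                        constraint = st_vars)
  expect_true(all(vapply(sr$results$variables,
                         function(s) all(s %in% st_vars), logical(1))))
  expect_equal(nrow(sr$results), 3)
  # predicate form behaves identically
  sr2 <- search_coresets(tab, c(st_vars, "pelvis_sag_rom", "aps"), max_size = 2,
                         constraint = function(s) all(s %in% st_vars))
  expect_equal(sr$results$mr, sr2$results$mr)
})

test_that("pooled best MR is non-increasing in set size", {
  tab <- simulate_cohort(small_cohort_spec(), seed = 53)
  sr <- search_coresets(tab, small_cohort_spec()$variables$variable, max_size = 3)
  bm <- best_mr_by_size(sr)
  expect_true(all(diff(bm$best_mr_pooled) <= 0))
})

test_that("minimising over many noise subsets is optimistically biased", {
  # selection effect: the minimum MR over hundreds of all-noise subsets falls
  # below the average single-subset MR, which is why searched MRs are
  # in-sample-selected estimates
  tab <- simulate_cohort(null_cohort_spec(p = 32), seed = 59)
  sr <- search_coresets(tab, null_cohort_spec(p = 32)$variables$variable,
                        max_size = 2)
  expect_gte(nrow(sr$results), 500)
  singles <- sr$results$mr[sr$results$size == 1]
  expect_lt(min(sr$results$mr), mean(singles))
})
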
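test_that("rom is max minus min and behaves under translation and scaling", {
  expect_equal(rom(c(-10, 5, 20, 5)), 30)
  expect_equal(rom(rep(4.2, 101)), 0)
  t <- seq(0, 1, length.out = 101)
  A <- 7.3
  expect_equal(rom(A * sin(2 * pi * t)), 2 * A, tolerance = 1e-3)
  set.seed(1)
  for (i in 1:20) {
    cv <- rnorm(101)
    c0 <- runif(1, -50, 50)
    k <- runif(1, 0.1, 10)
    expect_equal(rom(cv + c0), rom(cv))
    expect_equal(rom(k * cv), k * rom(cv))
  }
})

test_that("windowed extrema equal brute-force scans over window samples", {
  ramp <- seq(0, 50, length.out = 101)
  expect_equal(max_angle(ramp), 50)
  expect_equal(max_angle(ramp, window = c(0, 50)), 25)
  set.seed(2)
  pct <- 0:100
  for (i in 1:25) {
    cv <- cumsum(rnorm(101))
    w <- sort(runif(2, 0, 100))
    if (diff(w) < 2) next
    idx <- which(pct >= w[1] & pct <= w[2])
    expect_equal(max_angle(cv, window = w), max(cv[idx]))
    expect_equal(max_angle(cv, window = w, direction = "negative"), max(-cv[idx]))
    oidx <- which(pct > w[1] & pct <= w[2])
    if (length(oidx) > 0)
      expect_equal(max_angle(cv, window = w, open_lower = TRUE), max(cv[oidx]))
  }
  expect_error(max_angle(ramp, window = c(30.2, 30.8)), "no samples")
})

test_that("rom_index is a guarded ratio", {
  expect_equal(rom_index(30, 30), 1.0)
  expect_equal(rom_index(15, 30), 0.5)
  expect_error(rom_index(30, 0), "reference")
})

test_that("inclination angle follows planar trigonometry and window monotonicity", {
  pct <- 0:100
  com <- tibble::tibble(cycle_pct = pct, horiz = 0, vert = 1)
  below <- tibble::tibble(cycle_pct = pct, horiz = 0, vert = 0)
  expect_equal(inclination_angle_max(below, com), 0)
  ank <- tibble::tibble(cycle_pct = pct,
                        horiz = 0.5 * cos(2 * pi * pct / 100), vert = 0)
  # maximizing sample: ankle at (0.5, 0), CoM at (0, 1) -> atan2(0.5, 1)
  expect_equal(inclination_angle_max(ank, com), atan2(0.5, 1) * 180 / pi,
               tolerance = 1e-6)
  expect_lte(inclination_angle_max(ank, com, window = c(0, 60)),
             inclination_angle_max(ank, com))
  expect_error(inclination_angle_max(com, com), "coincide")
})

test_that("spatiotemporal parameters partition the gait cycle exactly", {
  events <- tibble::tibble(side = c("affected", "nonaffected"),
                           foot_off = c(60, 62), opp_foot_off = c(10, 12),
                           opp_foot_contact = c(50, 52))
  spatial <- tibble::tibble(side = c("affected", "nonaffected"),
                            step_length = c(0.6, 0.7), stride_length = 1.3,
                            step_width = 0.12)
  st <- spatiotemporal_params(events, c(affected = 1.0, nonaffected = 1.0), spatial)
  aff <- st[st$side == "affected", ]
  expect_equal(aff$stance_duration_pct, 60)
  expect_equal(aff$swing_pct, 40)
  expect_equal(aff$ds1_duration_pct, 10)
  expect_equal(aff$single_support_pct, 40)
  expect_equal(aff$ds2_duration_pct, 10)
  expect_equal(aff$ds1_duration_pct + aff$single_support_pct +
                 aff$ds2_duration_pct + aff$swing_pct, 100)
  expect_equal(aff$cadence, 120)
  expect_equal(aff$gait_speed, 1.3)
  expect_equal(aff$spatial_symmetry, 0.6 / 0.7)
  bad <- events
  bad$opp_foot_contact[1] <- 5
  expect_error(spatiotemporal_params(bad, c(affected = 1, nonaffected = 1), spatial),
               "ordering.*affected")
})

test_that("the cycle partition holds for every simulated subject", {
  cc <- simulate_curves(cohort_spec(n_stroke = 6, n_control = 6), seed = 9)
  for (tr in cc$trials) {
    st <- spatiotemporal_params(tr$events, tr$stride_time, tr$spatial)
    expect_equal(st$ds1_duration_pct + st$single_support_pct +
                   st$ds2_duration_pct + st$swing_pct, c(100, 100))
  }
})
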
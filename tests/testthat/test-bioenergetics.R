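test_that("closed-form ATP decay matches its analytic anchor points", {
  expect_identical(relative_atp_closed_form(0, 0.0065, 0.11), 1)
  # steady state 1 / (1 + gamma_1 / gamma_b)
  expect_equal(steady_state_atp(0.0065, 0.11), 1 / (1 + 0.11 / 0.0065))
  expect_equal(relative_atp_closed_form(1e6, 0.0065, 0.11),
               steady_state_atp(0.0065, 0.11), tolerance = 1e-12)
  expect_equal(relative_atp_closed_form(30, 0.0065, 0.11), 0.0844,
               tolerance = 1e-3)
  expect_error(relative_atp_closed_form(-1, 0.0065, 0.11), "t must")
  expect_error(relative_atp_closed_form(1, 0, 0.11), "gamma_b")
})

test_that("sigmoidal consumption rate hits onset, midpoint and asymptote", {
  tc <- train_consumption(2L, gamma_max = 0.15, h_t = 4, K_t = 75,
                          atp0_rel = 0.1)
  expect_equal(consumption_rate_sigmoid(0, 0.11, tc), 0.11)
  expect_equal(consumption_rate_sigmoid(75, 0.11, tc), (0.11 + 0.15) / 2)
  expect_equal(consumption_rate_sigmoid(100 * 75, 0.11, tc), 0.15,
               tolerance = 1e-6)
  expect_error(consumption_rate_sigmoid(-1, 0.11, tc), "t must")
})

test_that("numeric ODE agrees with the closed form for constant consumption", {
  b <- ref_base()
  traj <- simulate_relative_atp(b, first_train_consumption(b), 300, 0.5)
  cf <- relative_atp_closed_form(traj$time_s, b$gamma_b, b$gamma_1)
  expect_lt(max(abs(traj$atp_rel - cf) / cf), 1e-6)
  expect_true(all(diff(traj$atp_rel) < 0)) # monotone decay from basal
})

test_that("without stimulation the ATP level relaxes to basal at rate gamma_b", {
  b <- base_params(gamma_b = 0.01, gamma_1 = 0, h = 6, K_rel = 0.046)
  tc <- train_consumption(1L, gamma_max = 0, atp0_rel = 0.5)
  traj <- simulate_relative_atp(b, tc, 400, 1)
  expect_true(all(diff(traj$atp_rel) > 0))
  expect_equal(traj$atp_rel[traj$time_s == 400], 1 - 0.5 * exp(-0.01 * 400),
               tolerance = 1e-6)
})

test_that("a depleted second train stays below the first-train trajectory", {
  b <- ref_base()
  tc2 <- train_consumption(2L, gamma_max = 1.26 * b$gamma_1, h_t = 4,
                           K_t = 75, atp0_rel = 0.10, base = b)
  t1 <- simulate_relative_atp(b, first_train_consumption(b), 150, 0.5)
  t2 <- simulate_relative_atp(b, tc2, 150, 0.5)
  expect_true(all(t2$atp_rel < t1$atp_rel))
})

test_that("Hill failure link is exact at K, ~0 at basal, strictly decreasing", {
  expect_equal(failure_rate_from_atp(0.046, 0.046, 6), 50)
  expect_lt(failure_rate_from_atp(1, 0.046, 6), 1e-5)
  expect_equal(failure_rate_from_atp(0.047, 0.046, 6), 46.8,
               tolerance = 1e-3)
  expect_error(failure_rate_from_atp(0, 0.046, 6), "atp_rel")
  # monotone decrease for random parameter draws (strict wherever the
  # result is above double-precision underflow of the Hill tail)
  set.seed(42)
  for (i in 1:20) {
    h <- runif(1, 0.5, 20)
    K <- runif(1, 0.01, 0.5)
    atp <- sort(runif(50, 1e-3, 1))
    fr <- failure_rate_from_atp(atp, K, h)
    expect_true(all(diff(fr) <= 0))
    pos <- fr > 1e-12 & fr < 100 - 1e-12
    expect_true(all(diff(fr[pos]) < 0))
  }
})

test_that("failure rate is invariant to a common rescaling of ATP and K", {
  set.seed(7)
  atp <- runif(20, 0.01, 1)
  for (s in c(0.1, 3, 42)) {
    expect_equal(failure_rate_from_atp(s * atp, s * 0.046, 6),
                 failure_rate_from_atp(atp, 0.046, 6))
  }
})

test_that("predicted first-train failure curve matches composition values", {
  b <- ref_base()
  fc <- predict_failure_curve(b, first_train_consumption(b), 150, 0.5)
  expect_lt(fc$failure_pct[fc$time_s == 0], 1e-3)
  expect_equal(fc$failure_pct[fc$time_s == 30],
               failure_rate_from_atp(
                 relative_atp_closed_form(30, b$gamma_b, b$gamma_1),
                 b$K_rel, b$h),
               tolerance = 1e-6)
  # ~2.5% half a minute in, plateauing near 24%
  expect_equal(fc$failure_pct[fc$time_s == 30], 2.5, tolerance = 0.05)
  plateau <- failure_rate_from_atp(steady_state_atp(b$gamma_b, b$gamma_1),
                                   b$K_rel, b$h)
  expect_equal(plateau, 23.9, tolerance = 1e-2)
  expect_true(all(diff(fc$failure_pct) >= 0))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(base_params(0.0065, 0.11, 6, 1.2), "K_rel")
  expect_error(base_params(-1, 0.11, 6, 0.046), "gamma_b")
  b <- ref_base()
  expect_error(train_consumption(2L, gamma_max = 0.05, base = b),
               "gamma_max")
  expect_error(train_consumption(1L, gamma_max = 0.2, base = b), "train 1")
  expect_error(train_consumption(2L, gamma_max = 0.2, atp0_rel = 1.5),
               "atp0_rel")
})
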
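test_that("protocol presets reproduce the stated stimulus counts", {
  p100 <- build_protocol("HFS100")
  expect_equal(nrow(p100), 20)
  expect_equal(range(p100$time_s), c(0, 0.19))
  expect_equal(nrow(build_protocol("HFS300")), 45)
  pm <- build_protocol("sustained_mature")
  sus <- pm[pm$role == "sustained", ]
  expect_equal(as.vector(table(sus$train_index)), rep(15000L, 3))
  # trains separated by 120 s rest
  expect_equal(min(sus$abs_time_s[sus$train_index == 2]) -
                 max(sus$abs_time_s[sus$train_index == 1]), 120 + 0.01)
  expect_equal(sort(unique(pm$time_s[pm$role == "test_pulse"])) - 150,
               c(0.1, 1, 4, 9, 19))
  pr <- build_protocol("recovery_pairs")
  expect_equal(length(unique(pr$pair_index)), 9)
  expect_equal(sum(pr$role == "depletion"), 9 * 20)
  gap <- with(pr, min(abs_time_s[pair_index == 1 & role == "recovery"]) -
                (max(abs_time_s[pair_index == 1 & role == "depletion"]) +
                   0.01))
  expect_equal(gap, 0.01, tolerance = 1e-9) # first interval is 10 ms
  expect_error(build_protocol("nope"), "arg")
})

test_that("simulated trains are deterministic and honour the failure model", {
  p <- build_protocol("sustained_mature")
  cl <- cell_params()
  a <- simulate_epsc_train(p, cl, "minus_oxphos", seed = 9)
  b <- simulate_epsc_train(p, cl, "minus_oxphos", seed = 9)
  expect_identical(a, b)
  # control condition: failure rate ~0, all successes
  ctrl <- simulate_epsc_train(build_protocol("HFS100"), cl, "control",
                              seed = 1)
  expect_true(all(attr(ctrl$train1, "success")))
})

test_that("late first-train failure fraction matches the model plateau", {
  cl <- cell_params()
  p <- build_protocol("sustained_mature")
  fail_frac <- vapply(1:10, function(s) {
    tr <- simulate_epsc_train(p, cl, "minus_oxphos", seed = 100 + s)$train1
    late <- tr$stim_times > 100
    mean(!attr(tr, "success")[late])
  }, numeric(1))
  # failure probability over t > 100 s spans ~20-24%
  expect_gt(mean(fail_frac), 0.18)
  expect_lt(mean(fail_frac), 0.26)
})

test_that("classification of simulated failures matches the ground truth", {
  cl <- cell_params()
  tr <- simulate_epsc_train(build_protocol("sustained_mature"), cl,
                            "minus_oxphos", seed = 2)$train3
  s <- classify_successes(tr, baseline_amp = cl$baseline_amp)
  expect_equal(s, attr(tr, "success"))
})

test_that("sweep simulation stores the analytic charge and scales linearly", {
  tr <- depression_train(ss = 0.3, tau = 0.05)
  sw <- simulate_sweep_trace(tr, noise_sd = 1e-4, seed = 4)
  q <- rrp_from_integral(sw, c(0.1, 0.1 + 0.19 + 0.04))
  expect_equal(q, attr(sw, "charge_true"), tolerance = 0.05)
  tr2 <- tr
  tr2$amplitudes <- 2 * tr$amplitudes
  sw2 <- simulate_sweep_trace(tr2, noise_sd = 1e-4, seed = 4)
  expect_equal(attr(sw2, "charge_true"), 2 * attr(sw, "charge_true"))
  # zero amplitudes leave artifacts + noise only: negligible charge
  tr0 <- tr
  tr0$amplitudes <- rep(0, length(tr$amplitudes))
  sw0 <- simulate_sweep_trace(tr0, noise_sd = 1e-4, seed = 4)
  expect_lt(abs(rrp_from_integral(sw0, c(0.1, 0.33))),
            0.01 * attr(sw, "charge_true"))
})

test_that("cohorts reproduce the requested between-cell dispersion", {
  spec <- cohort_spec(n_cells = 200, cv = list(baseline_amp = 0.3),
                      seed = 5)
  co <- simulate_cohort(spec, cell_params(), build_protocol("HFS100"),
                        "control")
  amps <- vapply(co$cells, function(cl) cl$baseline_amp, numeric(1))
  expect_equal(sd(amps) / mean(amps), 0.3, tolerance = 0.05)
  # CV 0 gives identical cells; fixed master seed gives identical cohorts
  co0 <- simulate_cohort(cohort_spec(5, cv = list(baseline_amp = 0),
                                     seed = 1),
                         cell_params(), build_protocol("HFS100"), "control")
  expect_true(all(vapply(co0$cells, function(cl)
    cl$baseline_amp == co0$cells[[1]]$baseline_amp, logical(1))))
  co1 <- simulate_cohort(spec, cell_params(), build_protocol("HFS100"),
                         "control")
  expect_identical(co, co1)
})

test_that("stationary success fraction converges to 1 - failure rate", {
  # constant-rate train already at steady state: Bernoulli successes over
  # a stationary window must match the model probability within binomial
  # error
  b <- ref_base()
  set.seed(8)
  sim <- bernoulli_failure_successes(b)
  late <- sim$t > 120
  p_model <- mean(sim$p[late])
  p_hat <- mean(!sim$success[late])
  se <- sqrt(p_model * (1 - p_model) / sum(late))
  expect_lt(abs(p_hat - p_model), 4 * se)
})
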
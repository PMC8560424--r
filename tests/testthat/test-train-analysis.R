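test_that("success classification applies the fractional threshold with >= ties", {
  tr <- epsc_train(c(0, 0.01, 0.02), c(10, 0.4, 6), frequency = 100)
  expect_equal(classify_successes(tr, 0.05, baseline_amp = 10),
               c(TRUE, FALSE, TRUE))
  tr2 <- epsc_train(c(0, 0.01, 0.02), c(10, 10, 10), frequency = 100)
  expect_true(all(classify_successes(tr2, 0.05, baseline_amp = 10)))
  tr3 <- epsc_train(c(0, 0.01), c(10, 0.5), frequency = 100)
  expect_equal(classify_successes(tr3, 0.05, baseline_amp = 10)[2], TRUE)
  expect_error(classify_successes(tr, 0.05, baseline_amp = 0), "baseline")
})

test_that("trailing rolling success average behaves on known sequences", {
  expect_equal(rolling_success(rep(TRUE, 25)), 100)
  expect_equal(rolling_success(c(rep(TRUE, 20), rep(FALSE, 5))), 80)
  alt <- rep(c(TRUE, FALSE), length.out = 40)
  expect_equal(rolling_success(alt, 25)[1], 52) # 13 successes of 25
  expect_true(all(rolling_success(alt, 25) >= 0 &
                    rolling_success(alt, 25) <= 100))
  expect_error(rolling_success(rep(TRUE, 10), 25), "shorter")
})

test_that("time to first failure needs two consecutive misses", {
  st <- seq(0, by = 0.01, length.out = 7)
  s <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(time_to_first_failure(s, st), 0.04)
  expect_true(is.na(time_to_first_failure(rep(TRUE, 7), st)))
  iso <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_true(is.na(time_to_first_failure(iso, st)))
  # events after the first qualifying pair do not move the result
  s2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(time_to_first_failure(s2, st), 0.02)
})

test_that("paired-pulse ratio covers depression, flat and facilitation", {
  mk <- function(a) epsc_train(c(0, 0.01), a, frequency = 100)
  expect_equal(paired_pulse_ratio(mk(c(10, 8))), 0.8)
  expect_equal(paired_pulse_ratio(mk(c(10, 10))), 1)
  expect_equal(paired_pulse_ratio(mk(c(5, 6))), 1.2)
  expect_error(paired_pulse_ratio(mk(c(0, 6))), "undefined")
})

test_that("depression fit recovers tau and is scale invariant", {
  tr <- depression_train(ss = 0.3, tau = 0.05)
  fit <- fit_depression(tr)
  expect_true(fit$converged)
  expect_equal(fit$tau, 0.05, tolerance = 0.01)
  expect_equal(fit$steady_state_frac, 0.3, tolerance = 0.01)
  expect_equal(fit$fit_window, c(3, 20))
  # scaling all amplitudes leaves tau unchanged (internal normalisation)
  tr_scaled <- depression_train(ss = 0.3, tau = 0.05, baseline = 137)
  expect_equal(fit_depression(tr_scaled)$tau, fit$tau, tolerance = 1e-9)
  # 300 Hz uses pulses 3-46
  tr300 <- depression_train(ss = 0.3, tau = 0.02, frequency = 300,
                            duration = 46 / 300)
  f300 <- fit_depression(tr300)
  expect_equal(f300$fit_window, c(3, 46))
  expect_equal(f300$tau, 0.02, tolerance = 0.01)
  # constant train is flagged degenerate with ss = 1
  flat <- epsc_train(seq(0, 0.19, by = 0.01), rep(4, 20), frequency = 100)
  fd <- fit_depression(flat)
  expect_false(fd$converged)
  expect_equal(fd$flag, "degenerate")
  expect_equal(fd$steady_state_frac, 1)
  expect_error(fit_depression(depression_train(duration = 0.1)), "window")
})

test_that("steady-state depression averages normalised tail amplitudes", {
  st <- seq(0, 0.19, by = 0.01)
  tr <- epsc_train(st, c(10, rep(4, 19)), frequency = 100)
  expect_equal(steady_state_depression(tr, tau = 0.02), 0.4)
  # pure exponential: compare against the generating curve's tail mean
  tr2 <- depression_train(ss = 0.3, tau = 0.05)
  tail_mean <- mean(0.3 + 0.7 * exp(-st[st > 0.15] / 0.05))
  expect_equal(steady_state_depression(tr2, tau = 0.05), tail_mean,
               tolerance = 1e-9)
  expect_equal(tail_mean, 0.32, tolerance = 0.01)
  flat <- epsc_train(st, rep(7, 20), frequency = 100)
  expect_equal(steady_state_depression(flat, tau = 0.02), 1)
  expect_error(steady_state_depression(tr, tau = 1), "3\\*tau|beyond")
})

test_that("RRP charge integral is exact, linear and artifact-insensitive", {
  sr <- 1e4
  n <- 3001 # 0.3 s
  tt <- (seq_len(n) - 1) / sr
  rect <- as.numeric(tt >= 0.05 & tt < 0.25)
  sw <- sweep_trace(rect, sr)
  expect_equal(rrp_from_integral(sw, c(0.05, 0.25)), 0.2, tolerance = 1e-2)
  sw3 <- sweep_trace(3 * rect, sr)
  expect_equal(rrp_from_integral(sw3, c(0.05, 0.25)),
               3 * rrp_from_integral(sw, c(0.05, 0.25)))
  # additivity over disjoint windows (fixed baseline)
  expect_equal(rrp_from_integral(sw, c(0.05, 0.15), baseline = 0) +
                 rrp_from_integral(sw, c(0.15, 0.25), baseline = 0),
               rrp_from_integral(sw, c(0.05, 0.25), baseline = 0),
               tolerance = 1e-3)
  # artifact spikes inside blank windows do not move the integral
  stim <- seq(0.05, 0.24, by = 0.01)
  spiky <- rect
  idx <- round(stim * sr) + 1
  spiky[idx] <- spiky[idx] + 50
  sw_art <- sweep_trace(spiky, sr, stim_times = stim,
                        artifact_window = 3 / sr)
  clean <- rrp_from_integral(sw, c(0.05, 0.25))
  expect_lt(abs(rrp_from_integral(sw_art, c(0.05, 0.25)) - clean) / clean,
            0.01)
  expect_error(rrp_from_integral(sw, c(0.2, 0.5)), "outside")
})

test_that("recovery time-course fit recovers tau and respects exclusions", {
  dt <- c(0.1, 0.4, 1, 2, 4, 8, 13)
  f <- 1 - (1 - 0.2) * exp(-dt / 2)
  rec <- recovery_measurement(dt, f)
  fit <- fit_recovery_time_course(rec)
  expect_true(fit$converged)
  expect_equal(fit$tau, 2, tolerance = 0.02)
  # facilitation point below 400 ms is excluded before fitting
  f_fac <- replace(f, 1, 1.4)
  fit2 <- fit_recovery_time_course(recovery_measurement(dt, f_fac),
                                   exclude_before = 0.4)
  expect_equal(fit2$n_used, 6)
  expect_equal(fit2$tau, 2, tolerance = 0.02)
  # full recovery everywhere is degenerate, flagged not dropped
  full <- fit_recovery_time_course(recovery_measurement(dt, rep(1, 7)))
  expect_false(full$converged)
  expect_match(full$flag, "degenerate")
  expect_error(fit_recovery_time_course(recovery_measurement(c(1, 2),
                                                             c(0.5, 0.8))),
               "at least 3")
})

test_that("fractional recovery is the post/pre ratio", {
  expect_equal(fractional_recovery(10, 8), 0.8)
  expect_equal(fractional_recovery(10, 10), 1)
  expect_equal(fractional_recovery(10, 12), 1.2)
  expect_error(fractional_recovery(0, 5), "pre_amp")
})

test_that("spontaneous-event detection counts injected events", {
  sr <- 1e4
  dur <- 20
  set.seed(3)
  x <- rnorm(dur * sr, 0, 5)
  ev_times <- c(2, 5, 9, 13, 17)
  amps <- c(100, 90, 80, 70, 110)
  for (k in seq_along(ev_times)) {
    i <- round(ev_times[k] * sr) + 1
    x[i:(i + 9)] <- x[i:(i + 9)] + amps[k]
  }
  sw <- sweep_trace(x, sr)
  det <- detect_spontaneous_events(sw, amp_threshold = 25,
                                   min_interval = 0.01)
  expect_equal(length(det$times), 5)
  expect_equal(det$frequency, 0.25, tolerance = 1e-6)
  expect_equal(det$median_amplitude, 90, tolerance = 0.2)
  empty <- detect_spontaneous_events(sweep_trace(rep(0, sr), sr),
                                     amp_threshold = 25)
  expect_equal(length(empty$times), 0)
  expect_equal(empty$frequency, 0)
})

test_that("cohort summary computes mean, SE and CV with guards", {
  expect_equal(cohort_summary(c(1, 1, 1))$cv, 0)
  s <- cohort_summary(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$cv, sqrt(2) / 3)
  expect_equal(cohort_summary(c(2, 4) * 10)$cv, s$cv)
  expect_error(cohort_summary(1), "at least 2")
  expect_error(cohort_summary(c(-1, 1)), "mean is zero")
})
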
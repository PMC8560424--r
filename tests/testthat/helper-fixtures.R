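# Shared fixtures for the suite: the mature OxPhos-blockade reference
# parameters and small generator helpers.

ref_base <- function() mature_oxphos_params()

# An EPSC train following exact exponential depression (no noise).
depression_train <- function(ss = 0.3, tau = 0.05, frequency = 100,
                             duration = 0.2, baseline = 10, ...) {
  n <- round(frequency * duration)
  t <- (seq_len(n) - 1) / frequency
  epsc_train(t, baseline * (ss + (1 - ss) * exp(-t / tau)),
             frequency = frequency, ...)
}

# Per-stimulus Bernoulli failure simulation for one first-train cell under
# the bioenergetic model; independent of the package's cohort machinery so
# it can serve as an oracle for it.
bernoulli_failure_successes <- function(base, frequency = 100,
                                        duration = 150) {
  n <- round(frequency * duration)
  t <- (seq_len(n) - 1) / frequency
  p <- failure_rate_from_atp(
    relative_atp_closed_form(t, base$gamma_b, base$gamma_1),
    base$K_rel, base$h) / 100
  list(t = t, success = stats::runif(n) >= p, p = p)
}
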
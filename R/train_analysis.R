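#' Stimulus-aligned EPSC amplitude series for one train
#'
#' @param stim_times Stimulus times (s), ascending, spacing consistent
#'   with `frequency` within 1%.
#' @param amplitudes EPSC peak magnitude per stimulus (>= 0; values below
#'   the success threshold are failure candidates).
#' @param frequency Stimulation frequency (Hz). Inferred from the median
#'   inter-stimulus interval when missing.
#' @param cell_id,condition,run_index,train_role Metadata carried through
#'   the analysis (`train_role` one of "depletion", "recovery",
#'   "sustained").
#' @return An object of class `epsc_train`.
#' @export
epsc_train <- function(stim_times, amplitudes, frequency = NULL,
                       cell_id = "cell1", condition = "control",
                       run_index = 1L, train_role = "sustained") {
  if (length(stim_times) != length(amplitudes))
    stop("stim_times and amplitudes must have equal length")
  if (any(!is.finite(stim_times)) || is.unsorted(stim_times, strictly = TRUE))
    stop("stim_times must be finite and strictly ascending")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop("amplitudes must be finite and >= 0")
  isi <- diff(stim_times)
  if (is.null(frequency)) frequency <- 1 / stats::median(isi)
  if (length(isi) > 0 && any(abs(isi - 1 / frequency) > 0.01 / frequency))
    stop("stimulus spacing inconsistent with frequency ", frequency,
         " Hz (tolerance 1%)")
  structure(
    list(stim_times = as.numeric(stim_times),
         amplitudes = as.numeric(amplitudes),
         frequency = frequency, cell_id = cell_id, condition = condition,
         run_index = as.integer(run_index), train_role = train_role),
    class = "epsc_train"
  )
}

#' Classify each stimulus as transmission success or failure
#'
#' A stimulus is a success when its EPSC amplitude is at least
#' `threshold_frac` of the cell's baseline amplitude (ties count as
#' success). The default threshold is 5% of the initial EPSC; the
#' baseline defaults to the largest amplitude among the first 20 stimuli,
#' a robust proxy for the initial response when the train itself starts
#' with failures.
#'
#' @param train An [epsc_train()].
#' @param threshold_frac Success threshold as a fraction of baseline,
#'   in (0, 1). Default 0.05.
#' @param baseline_amp Baseline EPSC amplitude (> 0).
#' @return Logical vector, one element per stimulus.
#' @export
classify_successes <- function(train, threshold_frac = 0.05,
                               baseline_amp = NULL) {
  stopifnot(inherits(train, "epsc_train"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  if (is.null(baseline_amp))
    baseline_amp <- max(utils::head(train$amplitudes, 20))
  if (!is.finite(baseline_amp) || baseline_amp <= 0)
    stop("baseline_amp must be > 0")
  train$amplitudes >= threshold_frac * baseline_amp
}

#' Trailing rolling success percentage
#'
#' Running average of transmission successes over the previous `window`
#' stimuli (causal window; the value reported at stimulus i covers
#' stimuli i-window+1 .. i), expressed in percent. One value is emitted
#' per stimulus from the `window`-th onward.
#'
#' @param successes Logical (or 0/1) success series.
#' @param window Window length in stimuli (default 25).
#' @return Numeric vector of length `length(successes) - window + 1`.
#' @export
rolling_success <- function(successes, window = 25) {
  n <- length(successes)
  if (window < 1) stop("window must be >= 1")
  if (n < window) stop("series (", n, ") shorter than window (", window, ")")
  cs <- cumsum(as.numeric(successes))
  (cs[window:n] - c(0, cs[seq_len(n - window)])) / window * 100
}

#' Success percentage in consecutive non-overlapping stimulus bins
#'
#' @param successes Logical success series.
#' @param stim_times Stimulus times (s), aligned with `successes`.
#' @param n_per_bin Stimuli per bin (default 25); trailing incomplete bins
#'   are dropped.
#' @return Data frame with `time_s` (bin-centre time) and `success_pct`.
#' @export
success_rate_binned <- function(successes, stim_times, n_per_bin = 25) {
  n <- length(successes)
  if (length(stim_times) != n) stop("successes and stim_times must align")
  nb <- floor(n / n_per_bin)
  if (nb < 1) stop("fewer stimuli than one bin")
  keep <- seq_len(nb * n_per_bin)
  m <- matrix(as.numeric(successes[keep]), nrow = n_per_bin)
  data.frame(time_s = colMeans(matrix(stim_times[keep], nrow = n_per_bin)),
             success_pct = colMeans(m) * 100)
}

#' Time of the first transmission failure (two consecutive misses)
#'
#' A failure event is defined as two subsequent stimuli without a
#' postsynaptic EPSC; the reported time is the stimulus time of the first
#' of the earliest such pair, or `NA` if none occurs.
#'
#' @param successes Logical success series.
#' @param stim_times Stimulus times (s), aligned with `successes`.
#' @return Time (s) or `NA_real_`.
#' @export
time_to_first_failure <- function(successes, stim_times) {
  if (length(successes) != length(stim_times))
    stop("successes and stim_times must align")
  s <- as.logical(successes)
  pair <- which(!s[-length(s)] & !s[-1])
  if (length(pair) == 0) return(NA_real_)
  stim_times[pair[1]]
}

#' Paired-pulse ratio
#'
#' Peak EPSC2 / peak EPSC1 of a train.
#'
#' @param train An [epsc_train()] with at least two stimuli and a nonzero
#'   first amplitude.
#' @return The ratio (dimensionless).
#' @export
paired_pulse_ratio <- function(train) {
  stopifnot(inherits(train, "epsc_train"))
  if (length(train$amplitudes) < 2) stop("need at least two stimuli")
  if (train$amplitudes[1] <= 0)
    stop("paired-pulse ratio undefined: first amplitude is zero")
  train$amplitudes[2] / train$amplitudes[1]
}

# Default 1-based fit window for the depression fit, by frequency.
depression_fit_window <- function(frequency) {
  if (isTRUE(all.equal(frequency, 100, tolerance = 0.01))) return(3:20)
  if (isTRUE(all.equal(frequency, 300, tolerance = 0.01))) return(3:46)
  stop("no default fit window for ", frequency,
       " Hz; supply `window` explicitly")
}

#' Single-exponential fit of short-term depression
#'
#' Amplitudes are normalised to the first pulse and fitted with
#' a(t) = ss + (1 - ss) exp(-t / tau) over a fixed pulse window
#' (pulses 3-20 for 100 Hz trains, 3-46 for 300 Hz, 1-based), with t
#' measured from the first stimulus.
#'
#' @param train An [epsc_train()].
#' @param window Optional integer vector of 1-based pulse indices
#'   overriding the frequency-based default.
#' @return List with `tau` (s), `steady_state_frac`, `fit_window`,
#'   `converged` and `flag` (`NA` or a reason code such as "degenerate").
#' @export
fit_depression <- function(train, window = NULL) {
  stopifnot(inherits(train, "epsc_train"))
  if (is.null(window)) window <- depression_fit_window(train$frequency)
  if (max(window) > length(train$amplitudes))
    stop("fit window (pulses ", min(window), "-", max(window),
         ") exceeds train length ", length(train$amplitudes))
  if (train$amplitudes[1] <= 0) stop("first amplitude must be > 0")
  a <- train$amplitudes / train$amplitudes[1]
  t_rel <- train$stim_times - train$stim_times[1]
  aw <- a[window]; tw <- t_rel[window]
  if (stats::sd(aw) < 1e-12) {
    return(list(tau = NA_real_, steady_state_frac = aw[1],
                fit_window = range(window), converged = FALSE,
                flag = "degenerate"))
  }
  fit <- try(minpack.lm::nlsLM(
    aw ~ ss + (1 - ss) * exp(-tw / tau),
    start = list(ss = max(min(aw), 1e-3), tau = diff(range(tw)) / 5),
    lower = c(ss = 0, tau = 1e-6), upper = c(ss = 2, tau = 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(tau = NA_real_, steady_state_frac = NA_real_,
                fit_window = range(window), converged = FALSE,
                flag = "non-convergence"))
  }
  cf <- stats::coef(fit)
  list(tau = unname(cf["tau"]), steady_state_frac = unname(cf["ss"]),
       fit_window = range(window), converged = TRUE, flag = NA_character_)
}

#' Steady-state depression level
#'
#' Mean normalised EPSC amplitude over all stimuli later than three
#' depression time constants from train onset.
#'
#' @param train An [epsc_train()].
#' @param tau Depression time constant (s), > 0.
#' @return Fraction of the initial amplitude.
#' @export
steady_state_depression <- function(train, tau) {
  stopifnot(inherits(train, "epsc_train"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (train$amplitudes[1] <= 0) stop("first amplitude must be > 0")
  t_rel <- train$stim_times - train$stim_times[1]
  sel <- t_rel > 3 * tau
  if (!any(sel))
    stop("no stimuli beyond 3*tau = ", 3 * tau, " s; train too short")
  mean(train$amplitudes[sel]) / train$amplitudes[1]
}

#' Sampled current sweep around a stimulation train
#'
#' @param samples Current samples (one channel).
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param stim_times Stimulus times (s) within the sweep.
#' @param artifact_window Duration (s) blanked after each stimulus when
#'   integrating, >= 0.
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, sampling_rate, stim_times = numeric(),
                        artifact_window = 0.001) {
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (artifact_window < 0) stop("artifact_window must be >= 0")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stim_times = as.numeric(stim_times),
                 artifact_window = artifact_window),
            class = "sweep_trace")
}

# Sample times of a sweep.
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1) / sweep$sampling_rate
}

#' Readily-releasable-pool charge from the train current integral
#'
#' Integrates the baseline-subtracted current over the train window after
#' blanking stimulation artifacts, capturing both synchronous and
#' asynchronous release. The baseline is the median current over the
#' 50 ms preceding the window (or the first 50 ms of the sweep when no
#' pre-train segment exists); artifact windows
#' `[stim, stim + artifact_window]` are bridged by linear interpolation;
#' the integral is trapezoidal, hence linear in current scaling and
#' additive over disjoint windows.
#'
#' @param sweep A [sweep_trace()].
#' @param train_window `c(start, end)` in seconds, within the sweep.
#' @param baseline Optional explicit baseline current; when `NULL`
#'   (default) the median over the 50 ms preceding the window is used.
#' @return Charge in current units x seconds.
#' @export
rrp_from_integral <- function(sweep, train_window, baseline = NULL) {
  stopifnot(inherits(sweep, "sweep_trace"), length(train_window) == 2L)
  tt <- sweep_times(sweep)
  if (train_window[1] < 0 || train_window[2] > tt[length(tt)] ||
      train_window[1] >= train_window[2])
    stop("train_window [", train_window[1], ", ", train_window[2],
         "] outside sweep [0, ", round(tt[length(tt)], 4), "]")
  if (is.null(baseline)) {
    base_sel <- tt >= train_window[1] - 0.05 & tt < train_window[1]
    if (!any(base_sel)) base_sel <- tt < 0.05
    baseline <- stats::median(sweep$samples[base_sel])
  }
  x <- sweep$samples - baseline
  blank <- rep(FALSE, length(tt))
  half <- 0.5 / sweep$sampling_rate # absorb float jitter in stim times
  for (s in sweep$stim_times) {
    blank <- blank | (tt >= s - half & tt <= s + sweep$artifact_window + half)
  }
  if (any(blank) && !all(blank)) {
    x[blank] <- stats::approx(tt[!blank], x[!blank], xout = tt[blank],
                              rule = 2)$y
  }
  sel <- tt >= train_window[1] & tt <= train_window[2]
  pracma::trapz(tt[sel], x[sel])
}

#' Recovery measurements after pool depletion
#'
#' @param intervals Rest intervals (s) between depletion and recovery
#'   trains, ascending.
#' @param fractional Recovered response / pre-depletion response per
#'   interval, >= 0.
#' @return An object of class `recovery_measurement`.
#' @export
recovery_measurement <- function(intervals, fractional) {
  if (length(intervals) != length(fractional))
    stop("intervals and fractional must have equal length")
  if (is.unsorted(intervals, strictly = TRUE))
    stop("intervals must be strictly ascending")
  if (any(fractional < 0)) stop("fractional recovery must be >= 0")
  structure(list(intervals = as.numeric(intervals),
                 fractional = as.numeric(fractional), tau = NA_real_),
            class = "recovery_measurement")
}

#' Single-exponential fit of the recovery time course
#'
#' Fits f(dt) = 1 - (1 - f0) exp(-dt / tau) to fractional recovery versus
#' rest interval. Intervals shorter than `exclude_before` are dropped
#' before fitting (pool estimates facilitate at short intervals; 0.4 s is
#' the conventional cutoff for pool-integral recovery, 0 for single
#' EPSCs). Series that cannot be fitted are flagged rather than dropped.
#'
#' @param rec A [recovery_measurement()].
#' @param exclude_before Exclude intervals below this value (s).
#' @return List with `tau` (s), `f0`, `n_used`, `converged` and `flag`.
#' @export
fit_recovery_time_course <- function(rec, exclude_before = 0) {
  stopifnot(inherits(rec, "recovery_measurement"))
  keep <- rec$intervals >= exclude_before
  dt <- rec$intervals[keep]; f <- rec$fractional[keep]
  if (length(dt) < 3)
    stop("need at least 3 recovery points after exclusion (have ",
         length(dt), ")")
  if (all(abs(f - 1) < 1e-3)) {
    return(list(tau = NA_real_, f0 = 1, n_used = length(dt),
                converged = FALSE, flag = "degenerate: already recovered"))
  }
  fit <- try(minpack.lm::nlsLM(
    f ~ 1 - (1 - f0) * exp(-dt / tau),
    start = list(f0 = max(min(f[1], 0.99), 0), tau = stats::median(dt)),
    lower = c(f0 = 0, tau = 1e-4), upper = c(f0 = 1, tau = 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(tau = NA_real_, f0 = NA_real_, n_used = length(dt),
                converged = FALSE, flag = "non-convergence"))
  }
  cf <- stats::coef(fit)
  list(tau = unname(cf["tau"]), f0 = unname(cf["f0"]), n_used = length(dt),
       converged = TRUE, flag = NA_character_)
}

#' Fractional recovery of a response
#'
#' @param pre_amp Response before depletion (> 0).
#' @param post_amp_at_t Response at the probed recovery time.
#' @return `post_amp_at_t / pre_amp` (over-recovery > 1 allowed).
#' @export
fractional_recovery <- function(pre_amp, post_amp_at_t) {
  if (!is.finite(pre_amp) || pre_amp <= 0) stop("pre_amp must be > 0")
  post_amp_at_t / pre_amp
}

#' Detect spontaneous synaptic events in a sweep
#'
#' Threshold-crossing detection with a refractory interval: samples
#' exceeding `amp_threshold` above the baseline (median of the analysed
#' samples) start an event; the event amplitude and time are taken at the
#' local peak within the refractory window, and further crossings within
#' `min_interval` are absorbed. Stimulus or test-pulse windows are
#' excluded from both the search and the analysed duration.
#'
#' @param sweep A [sweep_trace()].
#' @param amp_threshold Detection threshold (current units above
#'   baseline), above the noise floor.
#' @param min_interval Refractory interval (s), default 5 ms.
#' @param exclude_windows Optional list of `c(start, end)` windows (s) to
#'   exclude.
#' @return List with `times`, `amplitudes`, `frequency` (Hz, events per
#'   analysed second) and `median_amplitude`.
#' @export
detect_spontaneous_events <- function(sweep, amp_threshold,
                                      min_interval = 0.005,
                                      exclude_windows = NULL) {
  stopifnot(inherits(sweep, "sweep_trace"))
  if (!is.finite(amp_threshold) || amp_threshold <= 0)
    stop("amp_threshold must be > 0")
  tt <- sweep_times(sweep)
  mask <- rep(TRUE, length(tt))
  for (w in exclude_windows) mask[tt >= w[1] & tt <= w[2]] <- FALSE
  analyzed_duration <- sum(mask) / sweep$sampling_rate
  if (analyzed_duration <= 0) stop("zero analysed duration after exclusions")
  x <- sweep$samples - stats::median(sweep$samples[mask])
  above <- which(x > amp_threshold & mask)
  ev_t <- numeric(); ev_a <- numeric()
  refr <- max(1L, round(min_interval * sweep$sampling_rate))
  i <- 1L
  while (i <= length(above)) {
    j <- above[i]
    win <- j:min(j + refr, length(x))
    pk <- win[which.max(x[win])]
    ev_t <- c(ev_t, tt[pk]); ev_a <- c(ev_a, x[pk])
    i <- i + 1L
    while (i <= length(above) && above[i] <= j + refr) i <- i + 1L
  }
  list(times = ev_t, amplitudes = ev_a,
       frequency = length(ev_t) / analyzed_duration,
       median_amplitude = if (length(ev_a)) stats::median(ev_a) else NA_real_)
}

#' Cohort summary statistics
#'
#' @param values One value per cell, length >= 2.
#' @return List with `mean`, `se` (standard error) and `cv`
#'   (sample SD / mean).
#' @export
cohort_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  s <- stats::sd(values)
  list(mean = m, se = s / sqrt(n), cv = s / m, n = n)
}
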
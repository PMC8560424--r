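#' Build a stimulation protocol
#'
#' Resolves a named protocol preset (or an explicit segment table) into a
#' deterministic table of stimulus times. Presets mirror the recording
#' protocols the analysis is designed for:
#'
#' * `"HFS100"`: one 100 Hz x 200 ms train (20 stimuli).
#' * `"HFS300"`: one 300 Hz x 150 ms train (45 stimuli).
#' * `"sustained_mature"`: three 100 Hz x 150 s trains (15,000 stimuli
#'   each) with 120 s rest between trains, each followed by test pulses
#'   0.1, 1, 4, 9 and 19 s after train end.
#' * `"sustained_immature"`: as above with 100 Hz x 30 s trains.
#' * `"recovery_pairs"`: pairs of HFS100 depletion/recovery trains at
#'   increasing rest intervals (default nine intervals log-spaced from
#'   10 ms to 13 s; pass `intervals` for the 20 ms variant), 30 s rest
#'   between pairs.
#'
#' @param preset Preset name, or a data frame with columns `frequency`,
#'   `duration`, `role` describing segments laid out back to back with
#'   `inter_segment_rest` seconds between them.
#' @param intervals Rest intervals (s) for `"recovery_pairs"`.
#' @param inter_segment_rest Rest (s) between explicit segments.
#' @return A data frame (class `protocol`) with columns `train_index`,
#'   `role`, `stim_index`, `time_s` (within segment), `abs_time_s` and
#'   `frequency`.
#' @export
build_protocol <- function(preset = c("HFS100", "HFS300",
                                      "sustained_mature",
                                      "sustained_immature",
                                      "recovery_pairs"),
                           intervals = NULL, inter_segment_rest = 30) {
  seg_rows <- function(train_index, role, frequency, duration, offset,
                       pair_index = NA_integer_) {
    n <- round(frequency * duration)
    t_rel <- (seq_len(n) - 1) / frequency
    data.frame(train_index = train_index, role = role, stim_index = seq_len(n),
               time_s = t_rel, abs_time_s = offset + t_rel,
               frequency = frequency, pair_index = pair_index)
  }
  if (is.data.frame(preset)) {
    stopifnot(all(c("frequency", "duration", "role") %in% names(preset)))
    if (any(preset$frequency <= 0) || any(preset$duration <= 0))
      stop("segment frequencies and durations must be > 0")
    offset <- 0
    out <- do.call(rbind, lapply(seq_len(nrow(preset)), function(i) {
      rows <- seg_rows(i, preset$role[i], preset$frequency[i],
                       preset$duration[i], offset)
      offset <<- offset + preset$duration[i] + inter_segment_rest
      rows
    }))
    return(structure(out, class = c("protocol", "data.frame"),
                     preset = "custom"))
  }
  preset <- match.arg(preset)
  out <- switch(preset,
    HFS100 = seg_rows(1L, "depletion", 100, 0.2, 0),
    HFS300 = seg_rows(1L, "depletion", 300, 0.15, 0),
    sustained_mature = ,
    sustained_immature = {
      dur <- if (preset == "sustained_mature") 150 else 30
      rest <- 120
      test_offsets <- c(0.1, 1, 4, 9, 19)
      do.call(rbind, lapply(1:3, function(i) {
        off <- (i - 1) * (dur + rest)
        train <- seg_rows(i, "sustained", 100, dur, off)
        tests <- data.frame(train_index = i, role = "test_pulse",
                            stim_index = seq_along(test_offsets),
                            time_s = dur + test_offsets,
                            abs_time_s = off + dur + test_offsets,
                            frequency = NA_real_, pair_index = NA_integer_)
        rbind(train, tests)
      }))
    },
    recovery_pairs = {
      if (is.null(intervals))
        intervals <- exp(seq(log(0.01), log(13), length.out = 9))
      offset <- 0
      do.call(rbind, lapply(seq_along(intervals), function(j) {
        dep <- seg_rows(2L * j - 1L, "depletion", 100, 0.2, offset,
                        pair_index = j)
        rec_off <- offset + 0.2 + intervals[j]
        rec <- seg_rows(2L * j, "recovery", 100, 0.2, rec_off,
                        pair_index = j)
        offset <<- rec_off + 0.2 + inter_segment_rest
        rbind(dep, rec)
      }))
    }
  )
  structure(out, class = c("protocol", "data.frame"), preset = preset)
}

#' Per-cell generative parameters
#'
#' Phenomenological description of one cell used by the simulator: the
#' EPSC amplitude follows exponential short-term depression around which
#' multiplicative lognormal quantal noise acts, transmission failures are
#' Bernoulli draws governed by the bioenergetic failure model (condition
#' dependent), and spontaneous events occur as a Poisson process.
#'
#' @param baseline_amp Initial EPSC amplitude (nA), > 0.
#' @param depression_ss Steady-state depression (fraction of initial).
#' @param depression_tau Depression time constant (s).
#' @param recovery_tau Recovery time constant (s).
#' @param recovery_floor Fractional recovery at zero interval.
#' @param noise_cv Multiplicative amplitude noise CV, in \[0, 1).
#' @param base A [base_params()] object (bioenergetics).
#' @param trains List of [train_consumption()], one per sustained train.
#' @param failure_floor_frac Residual amplitude of failures as a fraction
#'   of baseline (failures are small stub responses, not exact zeros).
#' @param sepsc_rate Spontaneous event rate (Hz).
#' @param sepsc_amp_mean Mean spontaneous event amplitude (nA).
#' @param sepsc_amp_cv CV of spontaneous event amplitudes.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(baseline_amp = 5,
                        depression_ss = 0.15, depression_tau = 0.03,
                        recovery_tau = 3, recovery_floor = 0.2,
                        noise_cv = 0.2,
                        base = mature_oxphos_params(),
                        trains = lapply(1:3, mature_train_consumption,
                                        base = base),
                        failure_floor_frac = 0.01,
                        sepsc_rate = 1, sepsc_amp_mean = 0.05,
                        sepsc_amp_cv = 0.3) {
  stopifnot(baseline_amp > 0, depression_ss > 0, depression_tau > 0,
            recovery_tau > 0, recovery_floor >= 0,
            noise_cv >= 0, noise_cv < 1, failure_floor_frac > 0,
            inherits(base, "base_params"))
  structure(list(baseline_amp = baseline_amp, depression_ss = depression_ss,
                 depression_tau = depression_tau, recovery_tau = recovery_tau,
                 recovery_floor = recovery_floor, noise_cv = noise_cv,
                 base = base, trains = trains,
                 failure_floor_frac = failure_floor_frac,
                 sepsc_rate = sepsc_rate, sepsc_amp_mean = sepsc_amp_mean,
                 sepsc_amp_cv = sepsc_amp_cv),
            class = "cell_params")
}

# Lognormal multiplier with unit mean and given CV.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Per-stimulus failure probability for one sustained train under a
# condition. Control and -glycolysis leave transmission intact at the
# mature calyx; -OxPhos engages the bioenergetic failure model.
condition_failure_prob <- function(cell, condition, train_index, t_rel) {
  if (condition != "minus_oxphos") return(rep(0, length(t_rel)))
  if (train_index > length(cell$trains))
    stop("no consumption parameters for train ", train_index)
  tc <- cell$trains[[train_index]]
  atp <- relative_atp_ode(cell$base, tc, t_rel)
  failure_rate_from_atp(atp, cell$base$K_rel, cell$base$h) / 100
}

#' Simulate stimulus-aligned EPSC trains for one cell
#'
#' For each train segment of the protocol, the mean amplitude follows the
#' cell's exponential depression, multiplicative lognormal noise is
#' applied, and each stimulus independently fails with the probability
#' given by the bioenergetic failure model under the chosen condition.
#' Failed stimuli emit a small residual amplitude
#' (`failure_floor_frac * baseline`) so that threshold classification is
#' exercised. Output is a pure function of `(protocol, cell, condition,
#' seed)`.
#'
#' @param protocol A [build_protocol()] table.
#' @param cell A [cell_params()].
#' @param condition One of `"control"`, `"minus_glycolysis"`,
#'   `"minus_oxphos"`.
#' @param seed Integer RNG seed.
#' @return A list of [epsc_train()] objects (one per train segment; test
#'   pulses are skipped), each carrying attributes `success` (ground
#'   truth) and `p_fail`.
#' @export
simulate_epsc_train <- function(protocol, cell,
                                condition = c("control", "minus_glycolysis",
                                              "minus_oxphos"),
                                seed = 1) {
  stopifnot(inherits(protocol, "protocol"), inherits(cell, "cell_params"))
  condition <- match.arg(condition)
  set.seed(seed)
  segs <- unique(protocol$train_index[protocol$role != "test_pulse"])
  out <- lapply(segs, function(i) {
    rows <- protocol[protocol$train_index == i &
                       protocol$role != "test_pulse", ]
    t_rel <- rows$time_s
    n <- length(t_rel)
    p_fail <- condition_failure_prob(cell, condition, i, t_rel)
    success <- stats::runif(n) >= p_fail
    dep <- cell$depression_ss +
      (1 - cell$depression_ss) * exp(-t_rel / cell$depression_tau)
    amp <- cell$baseline_amp * dep * rlnorm_cv(n, cell$noise_cv)
    amp[!success] <- cell$baseline_amp * cell$failure_floor_frac *
      rlnorm_cv(sum(!success), cell$noise_cv)
    tr <- epsc_train(t_rel, amp, frequency = rows$frequency[1],
                     cell_id = "cell1", condition = condition,
                     run_index = i, train_role = rows$role[1])
    attr(tr, "success") <- success
    attr(tr, "p_fail") <- p_fail
    tr
  })
  names(out) <- paste0("train", segs)
  out
}

#' Simulate a sampled current sweep from an EPSC train
#'
#' Sums per-stimulus EPSC kernels (alpha functions peaking at
#' `kernel_tau`) scaled by the train's amplitudes, adds brief biphasic
#' stimulation artifacts at each stimulus time and Gaussian baseline
#' noise. The analytic ground-truth charge
#' `sum(amplitudes) * exp(1) * kernel_tau` is stored in attribute
#' `charge_true` for oracle tests.
#'
#' @param train An [epsc_train()].
#' @param kernel_tau Alpha-kernel time-to-peak (s), default 1 ms.
#' @param noise_sd Gaussian noise SD (current units).
#' @param artifact_amp Artifact spike amplitude (current units).
#' @param sampling_rate Sampling rate (Hz), default 10 kHz.
#' @param pre_s,post_s Padding (s) before the first and after the last
#'   stimulus.
#' @param seed Integer RNG seed.
#' @return A [sweep_trace()]; stimulus times are shifted by `pre_s`.
#' @export
simulate_sweep_trace <- function(train, kernel_tau = 0.001, noise_sd = 0.01,
                                 artifact_amp = 20, sampling_rate = 1e4,
                                 pre_s = 0.1, post_s = 0.05, seed = 1) {
  stopifnot(inherits(train, "epsc_train"))
  set.seed(seed)
  stim <- train$stim_times - train$stim_times[1] + pre_s
  dur <- stim[length(stim)] + post_s
  n <- ceiling(dur * sampling_rate) + 1L
  tt <- (seq_len(n) - 1) / sampling_rate
  x <- stats::rnorm(n, 0, noise_sd)
  for (k in seq_along(stim)) {
    sel <- tt >= stim[k]
    u <- (tt[sel] - stim[k]) / kernel_tau
    x[sel] <- x[sel] + train$amplitudes[k] * u * exp(1 - u)
  }
  # biphasic stimulus artifact: one sample up, one down
  idx <- round(stim * sampling_rate) + 1L
  idx <- idx[idx >= 1 & idx < n]
  x[idx] <- x[idx] + artifact_amp
  x[idx + 1L] <- x[idx + 1L] - artifact_amp
  sw <- sweep_trace(x, sampling_rate, stim_times = stim,
                    artifact_window = 3 / sampling_rate)
  attr(sw, "charge_true") <- sum(train$amplitudes) * exp(1) * kernel_tau
  sw
}

#' Cohort specification
#'
#' @param n_cells Number of cells, >= 1.
#' @param cv Named list of between-cell coefficients of variation applied
#'   as lognormal multipliers to the matching [cell_params()] fields.
#' @param seed Master RNG seed; per-cell seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 14,
                        cv = list(baseline_amp = 0.3, depression_tau = 0.2,
                                  recovery_tau = 0.2),
                        seed = 1) {
  stopifnot(n_cells >= 1, all(unlist(cv) >= 0))
  structure(list(n_cells = as.integer(n_cells), cv = cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of cells under one condition
#'
#' Draws per-cell parameters lognormally around a template cell with the
#' specified between-cell CVs, derives per-cell seeds deterministically
#' from the master seed, and simulates each cell's EPSC trains.
#'
#' @param spec A [cohort_spec()].
#' @param template A [cell_params()] template.
#' @param protocol A [build_protocol()] table.
#' @param condition Condition label passed to [simulate_epsc_train()].
#' @return A list (class `cohort`) with `cells` (per-cell parameters),
#'   `trains` (per-cell list of [epsc_train()]), `spec` and `condition`.
#' @export
simulate_cohort <- function(spec, template = cell_params(),
                            protocol = build_protocol("sustained_mature"),
                            condition = "control") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(template, "cell_params"))
  set.seed(spec$seed)
  mult <- lapply(spec$cv, function(cv) rlnorm_cv(spec$n_cells, cv))
  cell_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_cells)
  cells <- lapply(seq_len(spec$n_cells), function(i) {
    cl <- template
    for (nm in names(mult)) cl[[nm]] <- cl[[nm]] * mult[[nm]][i]
    cl
  })
  trains <- lapply(seq_len(spec$n_cells), function(i) {
    trs <- simulate_epsc_train(protocol, cells[[i]], condition,
                               seed = cell_seeds[i])
    for (j in seq_along(trs)) trs[[j]]$cell_id <- sprintf("cell%02d", i)
    trs
  })
  structure(list(cells = cells, trains = trains, spec = spec,
                 condition = condition, cell_seeds = cell_seeds),
            class = "cohort")
}

#' Flatten a cohort to the long amplitude-table schema
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame with columns `cell_id`, `condition`, `run_index`,
#'   `train_role`, `stim_index`, `time_s`, `amplitude`.
#' @export
as_amplitude_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$trains, function(trs) {
    do.call(rbind, lapply(trs, function(tr) {
      data.frame(cell_id = tr$cell_id, condition = tr$condition,
                 run_index = tr$run_index, train_role = tr$train_role,
                 stim_index = seq_along(tr$stim_times),
                 time_s = tr$stim_times, amplitude = tr$amplitudes)
    }))
  }))
}
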
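#' Shared bioenergetic parameters of the ATP-failure model
#'
#' Bundles the parameters common to every stimulation train: the basal
#' (stimulation-independent) ATP consumption rate, the activity-dependent
#' consumption rate during the first sustained train, and the Hill link
#' between relative ATP level and transmission-failure rate. The model is
#' formulated in relative ATP units: the resting ATP level before the first
#' train is 1 by definition, so the production rate constant equals
#' `gamma_b` and the half-failure level `K_rel` is a fraction of basal.
#'
#' @param gamma_b Basal ATP consumption rate (s^-1), > 0.
#' @param gamma_1 Activity-dependent consumption rate during the first
#'   sustained train (s^-1), >= 0.
#' @param h Hill coefficient of the ATP-to-failure link, > 0.
#' @param K_rel Relative ATP level at which the failure rate is 50%,
#'   in (0, 1).
#' @return An object of class `base_params`.
#' @seealso [failure_rate_from_atp()], [relative_atp_closed_form()]
#' @export
#' @examples
#' base_params(gamma_b = 0.0065, gamma_1 = 0.11, h = 6, K_rel = 0.046)
base_params <- function(gamma_b, gamma_1, h, K_rel) {
  stopifnot(
    is.numeric(gamma_b), length(gamma_b) == 1L, is.finite(gamma_b),
    is.numeric(gamma_1), length(gamma_1) == 1L, is.finite(gamma_1),
    is.numeric(h), length(h) == 1L, is.finite(h),
    is.numeric(K_rel), length(K_rel) == 1L, is.finite(K_rel)
  )
  if (gamma_b <= 0) stop("gamma_b must be > 0")
  if (gamma_1 < 0) stop("gamma_1 must be >= 0")
  if (h <= 0) stop("h must be > 0")
  if (K_rel <= 0 || K_rel >= 1) stop("K_rel must lie in (0, 1)")
  structure(
    list(gamma_b = gamma_b, gamma_1 = gamma_1, h = h, K_rel = K_rel,
         atp1_rel = 1),
    class = "base_params"
  )
}

#' Per-train time-varying ATP consumption parameters
#'
#' Describes the consumption rate during one sustained train. For the first
#' train the rate is constant at `gamma_1` (so `gamma_max == gamma_1` and
#' the train starts from basal ATP). For later trains the rate rises
#' sigmoidally from `gamma_1` at train onset towards `gamma_max`, with
#' half-time `K_t` and steepness `h_t`, and the train starts from a reduced
#' relative ATP level `atp0_rel` left over from earlier activity.
#'
#' @param train_index 1-based train number.
#' @param gamma_max Asymptotic consumption rate (s^-1).
#' @param h_t Sigmoid steepness (dimensionless), > 0.
#' @param K_t Sigmoid half-time (s), > 0.
#' @param atp0_rel Relative ATP at train onset, in (0, 1].
#' @param base Optional [base_params()]; when supplied, cross-invariants
#'   (`gamma_max >= gamma_1`; first-train constraints) are enforced.
#' @return An object of class `train_consumption`.
#' @export
train_consumption <- function(train_index, gamma_max, h_t = 1, K_t = 1,
                              atp0_rel = 1, base = NULL) {
  stopifnot(length(train_index) == 1L, train_index >= 1,
            train_index == as.integer(train_index))
  if (!is.finite(gamma_max) || gamma_max < 0) stop("gamma_max must be >= 0")
  if (!is.finite(h_t) || h_t <= 0) stop("h_t must be > 0")
  if (!is.finite(K_t) || K_t <= 0) stop("K_t must be > 0")
  if (!is.finite(atp0_rel) || atp0_rel <= 0 || atp0_rel > 1)
    stop("atp0_rel must lie in (0, 1]")
  if (!is.null(base)) {
    stopifnot(inherits(base, "base_params"))
    if (gamma_max < base$gamma_1 - 1e-12)
      stop("gamma_max must be >= gamma_1 of the linked base parameters")
    if (train_index == 1L) {
      if (abs(gamma_max - base$gamma_1) > 1e-12)
        stop("train 1 has constant consumption: gamma_max must equal gamma_1")
      if (atp0_rel != 1)
        stop("train 1 starts from basal ATP: atp0_rel must equal 1")
    }
  }
  structure(
    list(train_index = as.integer(train_index), gamma_max = gamma_max,
         h_t = h_t, K_t = K_t, atp0_rel = atp0_rel),
    class = "train_consumption"
  )
}

#' Constant-rate consumption descriptor for the first train
#'
#' @param base A [base_params()] object.
#' @return A `train_consumption` with `gamma_max == gamma_1`, starting from
#'   basal ATP.
#' @export
first_train_consumption <- function(base) {
  stopifnot(inherits(base, "base_params"))
  train_consumption(1L, gamma_max = base$gamma_1, h_t = 1, K_t = 1,
                    atp0_rel = 1, base = base)
}

#' Closed-form relative ATP decay under constant consumption
#'
#' Analytic solution of the relative-ATP balance
#' d\[ATP\]/dt = gamma_b - (gamma_b + gamma_stim) \[ATP\]
#' starting from the basal level 1:
#' \[ATP\](t) = (1 + r e^{-(gamma_stim + gamma_b) t}) / (1 + r),
#' with r = gamma_stim / gamma_b. Applies only to a train with constant
#' consumption that starts from basal ATP (the first sustained train).
#'
#' @param t Time(s) from train onset (s), >= 0. Vectorised.
#' @param gamma_b Basal consumption rate (s^-1), > 0.
#' @param gamma_stim Constant stimulation-dependent consumption rate
#'   (s^-1), >= 0.
#' @return Relative ATP in (steady state, 1]; exactly 1 at `t = 0` and
#'   converging to `1 / (1 + gamma_stim / gamma_b)` as t grows.
#' @export
#' @examples
#' relative_atp_closed_form(30, gamma_b = 0.0065, gamma_stim = 0.11)
relative_atp_closed_form <- function(t, gamma_b, gamma_stim) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (!is.finite(gamma_b) || gamma_b <= 0) stop("gamma_b must be > 0")
  if (!is.finite(gamma_stim) || gamma_stim < 0) stop("gamma_stim must be >= 0")
  r <- gamma_stim / gamma_b
  (1 + r * exp(-(gamma_stim + gamma_b) * t)) / (1 + r)
}

#' Steady-state relative ATP under constant consumption
#'
#' @inheritParams relative_atp_closed_form
#' @return `1 / (1 + gamma_stim / gamma_b)`.
#' @export
steady_state_atp <- function(gamma_b, gamma_stim) {
  if (!is.finite(gamma_b) || gamma_b <= 0) stop("gamma_b must be > 0")
  if (!is.finite(gamma_stim) || gamma_stim < 0) stop("gamma_stim must be >= 0")
  1 / (1 + gamma_stim / gamma_b)
}

#' Sigmoidally rising consumption rate during a later train
#'
#' gamma_i(t) = gamma_1 + (gamma_max - gamma_1) t^{h_t} / (K_t^{h_t} + t^{h_t}).
#' The rate equals `gamma_1` at train onset, the midpoint
#' `(gamma_1 + gamma_max) / 2` at `t = K_t`, and approaches `gamma_max` for
#' large t.
#'
#' @param t Time(s) from train onset (s), >= 0. Vectorised.
#' @param gamma_1 Consumption rate at train onset (s^-1).
#' @param tc A [train_consumption()] object.
#' @return Consumption rate (s^-1) at each `t`.
#' @export
consumption_rate_sigmoid <- function(t, gamma_1, tc) {
  stopifnot(inherits(tc, "train_consumption"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  th <- t^tc$h_t
  gamma_1 + (tc$gamma_max - gamma_1) * th / (tc$K_t^tc$h_t + th)
}

#' Numerically integrate the relative-ATP balance for one train
#'
#' Solves d\[ATP\]/dt = gamma_b - (gamma_b + gamma_i(t)) \[ATP\] from the
#' train's initial level `tc$atp0_rel` on a uniform grid, with gamma_i(t)
#' the (possibly time-varying) consumption rate of `tc`. Uses an adaptive
#' stiff-capable solver at tight tolerances so that for a constant-rate
#' first train the result matches [relative_atp_closed_form()] to solver
#' accuracy.
#'
#' @param base A [base_params()] object.
#' @param tc A [train_consumption()] object.
#' @param duration Train duration (s), > 0.
#' @param dt Output grid spacing (s), > 0 and <= duration.
#' @param rtol,atol Solver relative / absolute tolerances.
#' @return A data frame (class `atp_trajectory`) with columns `time_s` and
#'   `atp_rel`.
#' @export
simulate_relative_atp <- function(base, tc, duration, dt,
                                  rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(base, "base_params"), inherits(tc, "train_consumption"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(dt) || dt <= 0 || dt > duration)
    stop("dt must be > 0 and <= duration")
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  atp <- relative_atp_ode(base, tc, times, rtol = rtol, atol = atol)
  structure(data.frame(time_s = times, atp_rel = atp),
            class = c("atp_trajectory", "data.frame"))
}

# Internal workhorse: solve the ODE at arbitrary ascending times (>= 0).
relative_atp_ode <- function(base, tc, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(all(is.finite(times)), all(times >= 0), !is.unsorted(times))
  grid <- if (times[1] > 0) c(0, times) else times
  deriv <- function(t, y, parms) {
    g <- consumption_rate_sigmoid(t, base$gamma_1, tc)
    list(base$gamma_b - (base$gamma_b + g) * y)
  }
  out <- deSolve::lsoda(y = c(atp = tc$atp0_rel), times = grid, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  atp <- out[, "atp"]
  if (any(!is.finite(atp))) {
    stop("ODE solver failed to produce finite relative-ATP values ",
         "(first bad index ", which(!is.finite(atp))[1], " of ",
         length(atp), ")")
  }
  if (times[1] > 0) atp <- atp[-1]
  unname(atp)
}

#' Hill-function transmission-failure rate from relative ATP
#'
#' Failure rate (%) = 100 / (1 + (\[ATP\] / K)^h). Equals exactly 50 when
#' the ATP level is at the half-failure level `K_rel`, and decreases
#' strictly with increasing ATP. `atp_rel` and `K_rel` need only share the
#' same units, so the result is invariant to rescaling both by a common
#' factor.
#'
#' @param atp_rel Relative ATP level(s), > 0. Vectorised.
#' @param K_rel Relative ATP level at 50% failure (same units as
#'   `atp_rel`), > 0.
#' @param h Hill coefficient, > 0.
#' @return Failure rate(s) in percent, in (0, 100).
#' @export
#' @examples
#' failure_rate_from_atp(0.046, K_rel = 0.046, h = 6) # exactly 50
failure_rate_from_atp <- function(atp_rel, K_rel, h) {
  if (any(!is.finite(atp_rel)) || any(atp_rel <= 0))
    stop("atp_rel must be finite and > 0 (failure model undefined otherwise)")
  if (!is.finite(K_rel) || K_rel <= 0) stop("K_rel must be > 0")
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  100 / (1 + (atp_rel / K_rel)^h)
}

#' Predicted failure-rate time course for one train
#'
#' Composition of [simulate_relative_atp()] and [failure_rate_from_atp()]:
#' integrates the ATP balance under the train's consumption profile and
#' maps the trajectory through the Hill failure link.
#'
#' @inheritParams simulate_relative_atp
#' @return A data frame (class `failure_curve`) with columns `time_s` and
#'   `failure_pct`.
#' @export
predict_failure_curve <- function(base, tc, duration, dt,
                                  rtol = 1e-9, atol = 1e-12) {
  traj <- simulate_relative_atp(base, tc, duration, dt,
                                rtol = rtol, atol = atol)
  structure(
    data.frame(time_s = traj$time_s,
               failure_pct = failure_rate_from_atp(traj$atp_rel,
                                                   base$K_rel, base$h)),
    class = c("failure_curve", "data.frame")
  )
}

# Predicted failure percentages at arbitrary times for a given train setup
# (used by the fitting routines; train 1 with constant rate uses the exact
# closed form, later trains the numeric ODE).
predict_failure_at <- function(base, tc, times) {
  atp <- if (tc$train_index == 1L && abs(tc$gamma_max - base$gamma_1) < 1e-15 &&
             tc$atp0_rel == 1) {
    relative_atp_closed_form(times, base$gamma_b, base$gamma_1)
  } else {
    relative_atp_ode(base, tc, times)
  }
  failure_rate_from_atp(atp, base$K_rel, base$h)
}

#' Reference parameter set for the mature calyx under OxPhos blockade
#'
#' Bioenergetic parameters characterising OxPhos-dependent transmission
#' failure during sustained 100 Hz stimulation at the mature calyx of
#' Held: basal consumption 0.0065 s^-1 rising to 0.11 s^-1 during
#' activity (a ~17-fold increase), Hill coefficient 6 and half-failure
#' ATP level at 4.6% of basal.
#'
#' @return A [base_params()] object.
#' @export
mature_oxphos_params <- function() {
  base_params(gamma_b = 0.0065, gamma_1 = 0.11, h = 6, K_rel = 0.046)
}

#' Solve for the sigmoid asymptote giving a target end-of-train rate
#'
#' Finds `gamma_max` such that the sigmoidal consumption rate reaches
#' `end_ratio * gamma_1` at `t = duration`.
#'
#' @param base A [base_params()] object.
#' @param end_ratio Desired end-of-train rate as a multiple of `gamma_1`
#'   (at least 1).
#' @param h_t,K_t Sigmoid shape parameters.
#' @param duration Train duration (s).
#' @return The `gamma_max` value (s^-1).
#' @export
gamma_max_for_end_ratio <- function(base, end_ratio, h_t, K_t, duration) {
  stopifnot(inherits(base, "base_params"), end_ratio >= 1)
  s <- duration^h_t / (K_t^h_t + duration^h_t)
  base$gamma_1 * (1 + (end_ratio - 1) / s)
}

#' Reference per-train consumption descriptors for the mature calyx
#'
#' Train 1 uses constant consumption at `gamma_1` from basal ATP. Trains 2
#' and 3 start from reduced ATP (10% and 4.7% of basal) with demand rising
#' sigmoidally so that the end-of-train rate exceeds the first-train rate
#' by 26% and 40% respectively. The sigmoid shape (`h_t = 4`, `K_t = 75` s
#' for a 150 s train) is a modelling choice; only the onset ATP and the
#' end-of-train rate are constrained by the estimates this preset encodes.
#'
#' @param train_index 1, 2 or 3.
#' @param base A [base_params()] object (default [mature_oxphos_params()]).
#' @param duration Train duration (s), default 150.
#' @return A [train_consumption()] object.
#' @export
mature_train_consumption <- function(train_index,
                                     base = mature_oxphos_params(),
                                     duration = 150) {
  stopifnot(train_index %in% 1:3)
  if (train_index == 1L) return(first_train_consumption(base))
  preset <- switch(as.character(train_index),
                   "2" = list(atp0 = 0.10, end_ratio = 1.26),
                   "3" = list(atp0 = 0.047, end_ratio = 1.40))
  h_t <- 4
  K_t <- duration / 2
  gmax <- gamma_max_for_end_ratio(base, preset$end_ratio, h_t, K_t, duration)
  train_consumption(as.integer(train_index), gamma_max = gmax, h_t = h_t,
                    K_t = K_t, atp0_rel = preset$atp0, base = base)
}
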
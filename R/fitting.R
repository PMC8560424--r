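#' Observed failure-rate series for one sustained train
#'
#' Container for a binned transmission-failure time course: the observed
#' failure percentage per bin of (by default) 25 consecutive stimuli,
#' timestamped at bin centres relative to train onset.
#'
#' @param train_index 1-based train number.
#' @param times Bin-centre times (s) from train onset, strictly ascending.
#' @param failure_pct Observed failure percentage per bin, in \[0, 100\].
#' @param n_per_bin Stimuli per bin (default 25).
#' @return An object of class `failure_series`.
#' @export
failure_series <- function(train_index, times, failure_pct, n_per_bin = 25) {
  stopifnot(length(train_index) == 1L, train_index >= 1)
  if (length(times) != length(failure_pct))
    stop("times and failure_pct must have equal length")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("times must be finite and strictly ascending")
  if (any(!is.finite(failure_pct)) || any(failure_pct < 0) ||
      any(failure_pct > 100))
    stop("failure_pct must lie in [0, 100]")
  structure(
    list(train_index = as.integer(train_index), times = as.numeric(times),
         failure_pct = as.numeric(failure_pct),
         n_per_bin = as.integer(n_per_bin)),
    class = "failure_series"
  )
}

#' OxPhos-dependent failure rate from paired condition success curves
#'
#' Isolates the component of transmission failure attributable to
#' oxidative phosphorylation by subtracting, bin by bin, the success rate
#' measured with OxPhos blocked from the success rate in control
#' (1 mM glucose). Negative differences (the blocked condition
#' occasionally outperforming control in a bin) carry no information about
#' OxPhos-dependent failure and are clamped to 0; the number of clamped
#' bins is recorded in attribute `n_clamped`.
#'
#' @param success_ctrl Control success percentages per bin, in \[0, 100\].
#' @param success_block Success percentages with OxPhos blocked, aligned
#'   on the same bins.
#' @param times Bin-centre times (s), strictly ascending.
#' @param train_index 1-based train number (default 1).
#' @param n_per_bin Stimuli per bin (default 25).
#' @return A [failure_series()].
#' @export
oxphos_dependent_failure <- function(success_ctrl, success_block, times,
                                     train_index = 1, n_per_bin = 25) {
  if (length(success_ctrl) != length(success_block) ||
      length(success_ctrl) != length(times))
    stop("success_ctrl, success_block and times must be aligned on ",
         "identical bins (lengths ", length(success_ctrl), ", ",
         length(success_block), ", ", length(times), ")")
  rng_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 100)
  if (!rng_ok(success_ctrl) || !rng_ok(success_block))
    stop("success percentages must lie in [0, 100]")
  diff <- success_ctrl - success_block
  n_clamped <- sum(diff < 0)
  fs <- failure_series(train_index, times, pmin(pmax(diff, 0), 100),
                       n_per_bin)
  attr(fs, "n_clamped") <- n_clamped
  fs
}

#' Configuration for the least-squares model fits
#'
#' Bounded nonlinear least squares with multi-start: `n_starts` starting
#' points are drawn by log-uniform perturbation of a central guess (seeded
#' for reproducibility) and the best converged solution is retained.
#'
#' @param n_starts Number of optimisation starts (>= 1), default 20.
#' @param seed RNG seed for start perturbation.
#' @param bounds Named list of `c(lower, upper)` bounds per parameter.
#'   Defaults are wide but physical.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol Solver convergence tolerances.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 17,
                       bounds = list(
                         gamma_b = c(1e-4, 1),
                         gamma_1 = c(1e-3, 10),
                         h = c(0.5, 20),
                         K_rel = c(1e-3, 0.5),
                         atp0_rel = c(1e-3, 1),
                         gamma_max = c(NA, 10),  # lower bound is gamma_1
                         K_t = c(1, 300),
                         h_t = c(0.5, 20)
                       ),
                       maxiter = 300, ftol = 1e-13, ptol = 1e-13) {
  stopifnot(n_starts >= 1)
  for (nm in setdiff(names(bounds), "gamma_max")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] >= b[2])
      stop("bounds for ", nm, " must be finite and ordered")
  }
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 bounds = bounds, maxiter = maxiter, ftol = ftol,
                 ptol = ptol),
            class = "fit_config")
}

# Run bounded Levenberg-Marquardt from multiple log-space starts and keep
# the best. `resid_fn` maps a natural-scale parameter vector to residuals.
multi_start_lm <- function(resid_fn, central, lower, upper, cfg) {
  lp_c <- log(central); lb <- log(lower); ub <- log(upper)
  k <- length(central)
  # Seed only the start perturbations, then restore the caller's RNG
  # stream so fitting never perturbs surrounding simulations.
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  starts <- matrix(NA_real_, nrow = cfg$n_starts, ncol = k)
  starts[1, ] <- pmin(pmax(lp_c, lb), ub)
  if (cfg$n_starts > 1) {
    for (j in 2:cfg$n_starts) {
      starts[j, ] <- pmin(pmax(lp_c + stats::runif(k, -1.5, 1.5), lb), ub)
    }
  }
  if (has_seed) {
    assign(".Random.seed", old_seed, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  }
  results <- vector("list", cfg$n_starts)
  for (j in seq_len(cfg$n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[j, ], lower = lb, upper = ub,
      fn = function(lp) resid_fn(exp(lp)),
      control = minpack.lm::nls.lm.control(maxiter = cfg$maxiter,
                                           ftol = cfg$ftol,
                                           ptol = cfg$ptol)
    ), silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$deviance)) {
      results[[j]] <- list(par = exp(fit$par), sse = fit$deviance,
                           info = fit$info)
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    stop("no optimisation start converged to a finite solution (",
         cfg$n_starts, " starts attempted)")
  }
  results <- results[ok]
  sses <- vapply(results, function(r) r$sse, numeric(1))
  best <- results[[which.min(sses)]]
  ests <- do.call(rbind, lapply(results, function(r) r$par))
  # Dispersion of log-estimates across starts that came close to the best
  # SSE: a large spread flags practical non-identifiability.
  near <- sses <= min(sses) * (1 + 1e-3) + 1e-10
  disp <- if (sum(near) > 1) {
    apply(log(ests[near, , drop = FALSE]), 2, stats::sd)
  } else {
    rep(0, ncol(ests))
  }
  list(par = best$par, sse = best$sse, info = best$info,
       start_estimates = ests, start_sses = sses, start_dispersion = disp,
       n_converged = length(results))
}

new_fit_result <- function(estimates, par_names, ms, fitted, observed) {
  res <- observed - fitted
  structure(
    list(estimates = estimates,
         par = stats::setNames(ms$par, par_names),
         sse = ms$sse,
         residuals = res,
         fitted = fitted,
         start_dispersion = stats::setNames(ms$start_dispersion, par_names),
         start_sses = ms$start_sses,
         n_converged = ms$n_converged,
         converged = ms$info %in% 1:3),
    class = "fit_result"
  )
}

#' Fit the shared model parameters to a first-train failure series
#'
#' Estimates (`gamma_b`, `gamma_1`, `h`, `K_rel`) by bounded multi-start
#' least squares, minimising the sum of squared differences between the
#' observed failure percentages and the model prediction obtained by
#' substituting the constant-rate closed-form ATP decay into the Hill
#' failure link. Optimisation is performed on log-parameters; the best of
#' `cfg$n_starts` starts is retained and the spread of estimates across
#' near-optimal starts is reported as an identifiability diagnostic.
#'
#' @param series A [failure_series()] with `train_index == 1` and at least
#'   8 bins.
#' @param cfg A [fit_config()].
#' @return A `fit_result` whose `estimates` element is a [base_params()].
#' @export
fit_first_train <- function(series, cfg = fit_config()) {
  stopifnot(inherits(series, "failure_series"))
  if (series$train_index != 1L)
    stop("fit_first_train requires a train-1 series")
  if (length(series$times) < 8)
    stop("need at least 8 bins to fit four parameters")
  if (all(series$failure_pct <= 0))
    stop("unidentifiable: failure series is identically zero, nothing ",
         "constrains h or K_rel")
  obs <- series$failure_pct
  tt <- series$times
  resid_fn <- function(p) {
    atp <- relative_atp_closed_form(tt, p[1], p[2])
    failure_rate_from_atp(atp, p[4], p[3]) - obs
  }
  b <- cfg$bounds
  ms <- multi_start_lm(
    resid_fn,
    central = c(0.01, 0.1, 4, 0.05),
    lower = c(b$gamma_b[1], b$gamma_1[1], b$h[1], b$K_rel[1]),
    upper = c(b$gamma_b[2], b$gamma_1[2], b$h[2], b$K_rel[2]),
    cfg = cfg
  )
  est <- base_params(ms$par[1], ms$par[2], ms$par[3], ms$par[4])
  fitted <- resid_fn(ms$par) + obs
  new_fit_result(est, c("gamma_b", "gamma_1", "h", "K_rel"), ms, fitted, obs)
}

#' Fit a later train's consumption dynamics with shared parameters fixed
#'
#' Estimates (`atp0_rel`, `gamma_max`, `h_t`, `K_t`) for the second or
#' third sustained train, holding (`gamma_b`, `gamma_1`, `h`, `K_rel`)
#' fixed at the first-train estimates, mirroring the sequential fitting
#' order. The prediction solves the ATP balance numerically with the
#' sigmoidally rising consumption rate and maps it through the Hill link.
#'
#' @param series A [failure_series()] with `train_index` 2 or 3.
#' @param base A [base_params()] fixed from the first-train fit.
#' @param cfg A [fit_config()].
#' @return A `fit_result` whose `estimates` element is a
#'   [train_consumption()].
#' @export
fit_subsequent_train <- function(series, base, cfg = fit_config()) {
  stopifnot(inherits(series, "failure_series"), inherits(base, "base_params"))
  if (!series$train_index %in% c(2L, 3L))
    stop("fit_subsequent_train requires a train-2 or train-3 series")
  if (length(series$times) < 8)
    stop("need at least 8 bins to fit four parameters")
  if (all(series$failure_pct <= 0))
    stop("unidentifiable: failure series is identically zero")
  obs <- series$failure_pct
  tt <- series$times
  idx <- series$train_index
  resid_fn <- function(p) {
    tc <- train_consumption(idx, gamma_max = p[2], h_t = p[3], K_t = p[4],
                            atp0_rel = min(p[1], 1))
    atp <- relative_atp_ode(base, tc, tt)
    failure_rate_from_atp(atp, base$K_rel, base$h) - obs
  }
  b <- cfg$bounds
  gmax_lo <- max(base$gamma_1, 1e-12)
  ms <- multi_start_lm(
    resid_fn,
    central = c(0.3, min(max(2 * base$gamma_1, gmax_lo * 1.01),
                         b$gamma_max[2]), 2, 50),
    lower = c(b$atp0_rel[1], gmax_lo, b$h_t[1], b$K_t[1]),
    upper = c(b$atp0_rel[2], b$gamma_max[2], b$h_t[2], b$K_t[2]),
    cfg = cfg
  )
  est <- train_consumption(idx, gamma_max = ms$par[2], h_t = ms$par[3],
                           K_t = ms$par[4], atp0_rel = min(ms$par[1], 1),
                           base = base)
  fitted <- resid_fn(ms$par) + obs
  new_fit_result(est, c("atp0_rel", "gamma_max", "h_t", "K_t"), ms, fitted,
                 obs)
}

#' Diagnostics for a fitted failure-rate model
#'
#' Recomputes the residual sum of squares of a fit against a (possibly
#' different) failure series, reports per-bin residuals and the
#' multi-start dispersion, and sweeps each parameter over a grid around
#' its estimate (others held fixed) to expose the local SSE profile.
#'
#' @param fit A `fit_result` from [fit_first_train()] or
#'   [fit_subsequent_train()].
#' @param series The [failure_series()] to evaluate against.
#' @param base For subsequent-train fits, the fixed [base_params()].
#' @param sweep Logical; compute the per-parameter SSE sweep (default
#'   TRUE).
#' @param n_grid Grid points per parameter sweep.
#' @param span Multiplicative half-range of each sweep (default 1.5, i.e.
#'   estimate/1.5 to estimate*1.5).
#' @return A list with elements `sse`, `residuals`, `start_dispersion`,
#'   `n_converged` and (if requested) `profiles` (one data frame of
#'   `value`, `sse` per parameter).
#' @export
fit_diagnostics <- function(fit, series, base = NULL, sweep = TRUE,
                            n_grid = 21, span = 1.5) {
  stopifnot(inherits(fit, "fit_result"), inherits(series, "failure_series"))
  if (!fit$converged) stop("fit did not converge; diagnostics unavailable")
  pred_fn <- function(par) {
    if (inherits(fit$estimates, "base_params")) {
      atp <- relative_atp_closed_form(series$times, par[["gamma_b"]],
                                      par[["gamma_1"]])
      failure_rate_from_atp(atp, par[["K_rel"]], par[["h"]])
    } else {
      stopifnot(inherits(base, "base_params"))
      tc <- train_consumption(series$train_index,
                              gamma_max = par[["gamma_max"]],
                              h_t = par[["h_t"]], K_t = par[["K_t"]],
                              atp0_rel = min(par[["atp0_rel"]], 1))
      atp <- relative_atp_ode(base, tc, series$times)
      failure_rate_from_atp(atp, base$K_rel, base$h)
    }
  }
  res <- series$failure_pct - pred_fn(fit$par)
  out <- list(sse = sum(res^2), residuals = res,
              start_dispersion = fit$start_dispersion,
              n_converged = fit$n_converged)
  if (sweep) {
    out$profiles <- lapply(stats::setNames(nm = names(fit$par)), function(nm) {
      grid <- exp(seq(log(fit$par[[nm]] / span), log(fit$par[[nm]] * span),
                      length.out = n_grid))
      sses <- vapply(grid, function(v) {
        p <- fit$par
        p[[nm]] <- v
        sum((series$failure_pct - pred_fn(p))^2)
      }, numeric(1))
      data.frame(value = grid, sse = sses)
    })
  }
  out
}

#' Noise-free model failure series on a stimulus-binned grid
#'
#' Evaluates the forward model at the bin-centre times that a
#' `n_per_bin`-stimulus binning of a train at `frequency` Hz would
#' produce, yielding the idealised failure series the fitting routines
#' would see for infinitely many cells.
#'
#' @param base A [base_params()].
#' @param tc A [train_consumption()].
#' @param duration Train duration (s).
#' @param frequency Stimulation frequency (Hz).
#' @param n_per_bin Stimuli per bin (default 25).
#' @return A [failure_series()].
#' @export
model_failure_series <- function(base, tc, duration = 150, frequency = 100,
                                 n_per_bin = 25) {
  n_stim <- round(frequency * duration)
  stim_t <- (seq_len(n_stim) - 1) / frequency
  nb <- floor(n_stim / n_per_bin)
  centre <- colMeans(matrix(stim_t[seq_len(nb * n_per_bin)],
                            nrow = n_per_bin))
  failure_series(tc$train_index, centre,
                 predict_failure_at(base, tc, centre), n_per_bin)
}
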
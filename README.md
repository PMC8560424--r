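# calyxatp

Presynaptic bioenergetics and transmission-failure analysis for
high-frequency synapses (calyx of Held style recordings).

During sustained high-frequency firing, a presynaptic terminal's ATP
supply can fall behind demand; when oxidative phosphorylation (OxPhos)
is blocked, transmission starts to fail tens of seconds into a
100 Hz train and failures accumulate across repeated trains. `calyxatp`
implements the kinetic model that links these failures to relative ATP
availability, the estimation machinery to fit it to per-train
failure-rate series, the standard electrophysiology train metrics used
around it, and a synthetic-data generator so the whole analysis can be
exercised end to end without recordings. It is written for
electrophysiologists and modellers analysing stimulus-aligned EPSC
amplitude series.

## The model

Relative ATP (basal level ≡ 1) during the *i*-th sustained train obeys

    d[ATP]/dt = γ_b − (γ_b + γ_i(t)) [ATP]

where γ_b is the basal consumption rate and γ_i(t) the
activity-dependent consumption. For the first train γ_1 is constant
and the solution is the closed-form exponential decay

    [ATP](t) = (1 + (γ_1/γ_b) e^{−(γ_1+γ_b)t}) / (1 + γ_1/γ_b),

approaching the steady state 1/(1 + γ_1/γ_b). For later trains the
demand rises sigmoidally, γ_i(t) = γ_1 + (γ_i^max − γ_1) t^{h_i} /
(K_i^{h_i} + t^{h_i}), and each train starts from a free onset level
[ATP]_i. The transmission-failure rate is a Hill function of ATP,

    Failure(%) = 100 / (1 + ([ATP]/K)^h),

equal to 50% when ATP falls to K. Parameters are estimated by bounded
multi-start least squares, sequentially: the first train fixes
(γ_b, γ_1, h, K), then each later train frees ([ATP]_i, γ_i^max, h_i, K_i).

## Worked example

Generate a noise-free first-train failure curve from the reference
parameter set for the mature calyx under OxPhos blockade and refit it
(this is what `analysis/04_reference_refit.R` runs):

```r
library(calyxatp)
cfg <- fit_config(seed = 17)
b   <- mature_oxphos_params()          # gamma_b 0.0065/s, gamma_1 0.11/s,
                                       # h 6, K at 4.6% of basal
s1   <- model_failure_series(b, first_train_consumption(b))
fit1 <- fit_first_train(s1, cfg)
bh   <- fit1$estimates
```

Printed output:

```
Train 1 refit: gamma_b 0.00650 /s, gamma_1 0.1100 /s (17-fold),
               h 6.00, K 4.6% of basal ATP (SSE 1.89e-25)
Train 2 refit: onset ATP 10.0%, end-of-train demand +26% over train 1 (SSE 6.25e-25)
Train 3 refit: onset ATP 4.7%, end-of-train demand +40% over train 1 (SSE 7.04e-24)
```

Reading: activity raises ATP consumption ~17-fold over basal; failures
require high cooperativity (h = 6), reaching 50% only when ATP falls to
4.6% of rest; the second train starts with only 10% of basal ATP and its
demand ends 26% above the first train's; the third starts at 4.7% (≈50%
initial failures) and ends 40% above.

The full stochastic pipeline — simulate 14-cell control and −OxPhos
cohorts under three 100 Hz × 150 s trains, classify successes (5% of
baseline threshold), bin per 25 stimuli, subtract conditions, and fit —
is one call:

```r
report <- run_reproduction(seed = 1, n_cells = 14, out_dir = "results")
```

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (`01` simulate, `02` train metrics, `03` subtract and
fit, `04` reference refit), writing tables under `results/`.

## Scope notes

Success/failure classification, rolling and binned success rates, time
to first failure (two consecutive misses), paired-pulse ratio,
single-exponential depression and recovery fits, steady-state
depression, RRP charge integrals with artifact blanking, and
spontaneous-event detection live in the train-analysis functions; see
`?fit_depression`, `?rrp_from_integral`, `?detect_spontaneous_events`.
The methods vignette (`vignettes/bioenergetics-failure-model.Rmd`)
documents model assumptions, fitting choices, the synthetic generator's
scope, and a parameter-identifiability analysis.
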
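# habgain

**Bayesian information-gain model of habituation to novelty, with a
synthetic surprise/ERP experiment and the matching P300 analysis chain.**

## The problem

Even a novel stimulus stops being surprising when it repeats. In
computational terms: an observer holds a Gaussian belief `N(η, s_pI)` about
a latent stimulus feature; each exposure delivers the same encoded datum (a
Gaussian likelihood with mean `x̄` and noise variance `s_l`), tempered by a
learning rate `α`. Surprise at the n-th exposure is the **information
gain** — the Kullback–Leibler divergence from the previous posterior to the
new one — and habituation is its decay:

```
G_n = ½ (A_n + B_n δ_I²)

A_n = g_{n−1}/g_n − ln(g_{n−1}/g_n) − 1
B_n = α² s_pI s_l / (g_{n−1} g_n²)
g_n = α n s_pI + s_l ,   δ_I = |η − x̄|
```

The three parameters — **initial uncertainty** `s_pI` (how unfamiliar the
stimulus class is), **initial prediction error** `δ_I` (how incongruent the
event is with expectation) and **external noise** `s_l` — interact: with no
prediction error, more uncertainty means more surprise; at high prediction
error the ordering of first-exposure surprise between two uncertainties
reverses exactly when `s_p1 · s_p2 > (s_l/α)²`; and more uncertainty always
means *faster* habituation.

The package is aimed at computational-cognitive-neuroscience use: it
provides the closed-form model (gains, integrated gain, asymptotic totals,
half-life, reversal threshold), parameter sweeps behind the standard decay
figures, a fully seeded generative emulation of a 2×2
familiarity-by-congruency surprise experiment (480 trials, Likert surprise
probes, synthetic 1000 Hz Pz epochs with a habituating P300-like
component), the standard ERP chain (0.1–20 Hz zero-phase band-pass,
baseline correction, ±80 µV artifact rejection, exposure-block averaging,
P300 peak measurement), and least-squares recovery of model parameters from
observed decay curves.

## Worked example

```r
library(habgain)

p <- habituation_params(initial_uncertainty = 1, initial_prediction_error = 10,
                        noise = 0.5, learning_rate = 0.1)
round(information_gain(p, 1:6), 4)
#> [1] 1.3967 0.8560 0.5623 0.3891 0.2805 0.2088
half_life(p)          # exposures until gain falls to half of G_1
#> [1] 3
round(total_gain_limit(p), 3)   # asymptotic total gain from exposure 1 on
#> [1] 3.958
```

The decay `1.3967, 0.8560, …` is the per-exposure surprise in nats; it
halves by the third exposure and sums to ≈ 3.96 over an indefinite run.
Sweeping the initial uncertainty at high prediction error shows the
interaction (first-exposure gain `g1` rises then falls across `s_pI`,
half-life shrinks, total gain falls):

```r
habituation_speed_table(run_sweep(figure_preset("fig3", n_max = 50)))
#>   swept_value    g1 half_life total_gain total_gain_sum
#> 1         0.5 0.829         4       4.42           4.86
#> 2         1.0 1.397         3       3.96           4.72
#> 3         2.0 2.066         2       3.25           4.45
#> 4         5.0 2.597         2       2.08           3.76
#> 5        10.0 2.438         2       1.31           3.03
```

End to end — simulate one synthetic subject and run the ERP pipeline:

```r
sub <- simulate_subject(seed = 1)
res <- analyze_experiment(sub$epochs)
res[res$block == 1, c("cell", "n_included", "p300_amplitude_uV", "p300_latency_ms")]
#>    cell n_included p300_amplitude_uV p300_latency_ms
#> 1    AX         37              2.57             434
#> 4    AY         38              4.94             391
#> 7    BX         40              2.25             376
#> 10   BY         38              3.72             399
```

Cells are familiar/unfamiliar instrument (A/B) × congruent/incongruent
sound (X/Y). In the incongruent condition the *familiar* cell (AY, 4.94 µV)
out-surprises the unfamiliar one (BY, 3.72 µV) at block 1 — the
uncertainty-ordering reversal at high prediction error. Fitting the model
back to a decay curve recovers the learning rate:

```r
truth <- habituation_params(0.5, 10, 0.5, 0.1)
obs <- decay_observation(1:120, 2 + 25 * information_gain(truth, 1:120))
fit_decay(obs, free = "learning_rate", fixed = truth)
#> <fit_result> free: learning_rate; loss = 1.24e-29; offset = 2, slope = 25
#> <habituation_params> s_pI = 0.5, delta_I = 10, s_l = 0.5, alpha = 0.1
```

A thin CLI over the same functions lives at `inst/cli/habgain`
(subcommands `gain`, `limit`, `sweep`, `simulate`, `analyze-erp`, `fit`).

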
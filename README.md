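# nanonmr

Simulation and classification toolkit for the binary measurement traces
produced by nitrogen-vacancy (NV) center magnetometers in nanoscale NMR
experiments. The package is for researchers studying how well competing
signal-processing methods can tell apart weak oscillating magnetic signals
read out one bit at a time by a single quantum probe, in regimes where
strong phase, amplitude and detection noise make the problem hard.

## The problem and the methods

One interrogation cycle prepares the probe, lets it precess for an
interval Δt under a signal `g·cos(ωt + φ)`, and measures it; the bright
outcome (bit 1) occurs with probability

    P(t) = sin²( (g/2ω)·[sin(ωt + φ) − sin(ω(t − Δt) + φ)] + π/4 ),

so an experiment yields a binary string x ∈ {0,1}^N with a fresh uniform
random phase per trace. Detection inefficiency maps P through
`Q = η_true·P + η_false·(1 − P)`. Two tasks are supported:

* **Frequency discrimination** — which of two known frequencies ω₁, ω₂
  generated a trace;
* **Frequency resolution** — whether a trace came from one central
  frequency or two frequencies δ_c ± Δ/2 whose quadrature amplitudes
  A_i(t), B_i(t) wander as Ornstein–Uhlenbeck processes.

Three classifiers are implemented, with balanced-error (Eq. chance level
0.5) and ROC/AUC scoring plus sweep harnesses over the separation:

* `classify_frequency_dataset()` — full-Bayesian likelihood-ratio test,
  maximizing the Bernoulli log-likelihood over the unknown phase
  (`L = Σ x_j log P_j + (1−x_j) log(1−P_j)` on a phase grid), or over a
  bank of sampled OU realizations for the resolution task;
* `classify_corr_dataset()` — nearest class template on the ±1
  autocorrelation vector `C_k = ⟨s_i s_{i+k}⟩`, L2 distance;
* `train_net()` / `predict()` — the reference feed-forward network
  (input = trace length, hidden layers of 20 and 35 ReLU units, one
  Sigmoid output, MSE loss, decision threshold 0.5), with optional
  unsupervised spectral initialization and streaming training for the
  long low-contrast traces (see the methods vignette for why those are
  needed there).

Everything is seeded and bit-reproducible; datasets read and write as
plain text (compact 0/1 strings or `trace_id,t,bit` CSV with a JSON
sidecar). A thin CLI (`inst/cli/nanonmr`) exposes `simulate`, `classify`
and the two `benchmark-*` commands.

## Worked example

Discriminate ω₁ = 10 rad/s from ω₂ = 10.0005 rad/s (g = 10 rad/s,
Δt = 0.5 s, 1000 bits, random phase per trace — a relative phase drift
of only 0.25 rad over the whole trace):

```r
library(nanonmr)
p1 <- signal_params(g = 10, omega = 10,      dt = 0.5, n_meas = 1000)
p2 <- signal_params(g = 10, omega = 10.0005, dt = 0.5, n_meas = 1000)
test <- simulate_discrimination_dataset(250, p1, p2, seed = 1)
res  <- classify_frequency_dataset(test, p1, p2, grid_size = 64)
error_probability(test$labels, res$pred)
#> <error_report> balanced error = 0.1520 (per class: 1: 0.1400, 2: 0.1640; n = 250/250)
roc_auc(res$score, test$labels, positive = 1)
#> <roc_result> AUC = 0.9208 (500 thresholds, positive = 1)
```

The balanced error is the mean of the two conditional misclassification
rates (0.5 = chance); the AUC uses the likelihood difference
`logL1 − logL2` as the ranking score. Doubling the separation to 0.001
rad/s drops the error to 0.036 (AUC 0.995); by 0.002 rad/s — a drift of
one radian — discrimination is essentially error-free. The same
experiment across separations and methods:

```r
run_discrimination_sweep("ideal", delta_omega = c(0.0005, 0.002),
                         methods = c("fb", "corr"), seeds = 1,
                         n_train_per_class = 200, n_test_per_class = 200)
```

returns one row per (separation, method) with `p_error` and `auc`, and
writes `sweep.csv` / ROC files when `out_dir` is given.

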
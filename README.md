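# ttdcast

Predicting time-to-death after terminal extubation in potential
donation-after-circulatory-death (DCD) donors, from irregularly sampled
pre-extubation clinical time series.

## The problem

When life support is withdrawn in the ICU, a potential DCD donor may reach
circulatory death within minutes or linger for hours; organs accrue warm
ischemic injury while teams wait. Procurement planning therefore hinges on
the time from terminal extubation to circulatory death (TTD). `ttdcast`
treats TTD as an ordinal outcome over four windows — 0–30, 30–60, 60–120
and > 120 minutes, matching standard/extended organ acceptance criteria —
and predicts the four probabilities per patient.

## The model

An **ODE-RNN**: between observations the hidden state evolves by a learned
ordinary differential equation,

    h(t_i^-) = ODESolve(dh/dt = f_ODE(h), h(t_{i-1}), [t_{i-1}, t_i]),

and at each observation a GRU cell folds in the new values, their
observation masks, and the elapsed gap:

    h(t_i) = f_GRU(h(t_i^-), [x_i; m_i; Δt_i]).

The final state is fused with the static profile into a *latent phenotype*
`z = f_fusion([f_static(s); f_longitudinal(h(t_n))])`, from which an MLP
classifier emits the four TTD probabilities (summing to 1 by construction).
Masks make the *pattern* of measurement — informative missingness — itself
a feature. The forward/backward pass is hand-written in RcppArmadillo
(exact gradients through the solver steps, verified against finite
differences in the tests); no deep-learning framework is required.

Alongside the main model the package ships, behind one fitting interface:
RNN/LSTM/GRU sequence baselines (identical input encoding, no ODE segment),
a gradient-boosted static baseline on last-observation features, a
clinical-criteria checklist score, the full metric suite (accuracy, grouped
binary tasks, ROC-AUC, PR-AUC, F1, PPV/NPV, expected calibration error with
reliability-curve data), permutation variable importance, and a phenoscape
analysis (2-D embedding of latent phenotypes, clustering, inter-cluster
t-tests). Because the real cohorts behind such analyses are
HIPAA-restricted, a synthetic DCD-cohort simulator with known ground truth
(`simulate_cohort()`) provides the study conditions; its accelerated
failure-time outcome model is calibrated so the default cohort reproduces
realistic class prevalences (two thirds of patients die within 30 minutes,
median TTD ≈ 7 min, heavily right-skewed).

## Worked example

```r
library(ttdcast)

sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 11))
summarize_cohort(sim$cohort)
#> Cohort summary (n = 2000 )
#>   TTD minutes: median 6.09, mean 151.80, sd 367.03
#>   History hours: median 3.75, mean 14.35, sd 26.13
#>   TTD categories (edges 30/60/120 min):
#>     0:  1351 (67.5%)
#>     1:   136 (6.8%)
#>     2:   131 (6.5%)
#>     3:   382 (19.1%)
#>   Sex: 1155 male / 845 female; median age 67; median BMI 28.30

sp    <- temporal_split(sim$cohort)          # train < 2021 <= test
stats <- normalization_stats(sp$train)       # training-split statistics only
train <- prepare_cohort(sp$train, stats)
test  <- prepare_cohort(sp$test, stats)

fit <- ttd_fit(train, "ode_rnn", ttd_config(epochs = 30), seed = 1)
evaluate_model(fit, test)
#> Evaluation of ode_rnn on 657 patients
#>   accuracy4          0.712 +/- 0.000
#>   accuracy_lt30      0.755 +/- 0.000
#>   accuracy_lt60      0.776 +/- 0.000
#>   accuracy_lt120     0.814 +/- 0.000
#>   roc_auc_lt30       0.798 +/- 0.000
#>   ...
#>   ece                0.048 +/- 0.000
```

Read: on 657 held-out later-era patients the model places 71.2% in the
right TTD window (marginal guessing: 68%), ranks sub-30-minute deaths with
AUC 0.80, and its sub-30 probabilities are well calibrated (ECE 0.048 —
they can be taken near face value). The static last-observation baseline
(`ttd_fit(train, "static")`) reaches 0.673 here: the trajectory shape and
the sampling pattern carry signal no single snapshot has.

Multi-seed uncertainty, importance and the phenoscape:

```r
ens  <- ttd_fit_ensemble(train, "ode_rnn", n_seeds = 5)  # metrics mean ± sd
imp  <- permutation_importance(fit, sp$test, task = 30)  # ΔAUC per variable
view <- phenoscape_view(fit, sp$test)                    # 2-D map + clusters
plot(view, color = "ttd_log")
```

Or everything at once, reproducibly, into a run directory:

```r
run_experiment(run_config(seed = 1), "runs/demo")
```

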
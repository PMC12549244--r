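# trustdyn

Estimating an operator's moment-to-moment **trust in an autonomous
teammate** from multimodal physiology and task behavior.

In supervisory human-autonomy teaming, trust is reported on a continuous
slider in [0, 1] at the end of every 45-s epoch. trustdyn models those
reports as an ordinary least squares regression

> y = b0 + b1 X1 + ... + bp Xp

whose predictors are drawn from ~1,800 candidates: per-epoch features from
six physiological streams (heart-rate variability from ECG, tonic/phasic
electrodermal activity, respiration, EEG band powers, fNIRS hemodynamics,
eye tracking), each expanded through eight baseline-normalization
"versions", plus 16 task-embedded behavioral measures and 25 operator
background variables. Predictors are chosen by **two-round relaxed-LASSO
stability selection** (10-fold CV, supports recorded at both the 1-SE and
minimum-MSE lambda, refit by OLS), constrained against overfitting
(predictor count <= n/5; |adjusted R-squared − leave-one-trial-out Q-squared| <= 0.2),
and validated externally with **leave-one-trial-out-per-session Monte-Carlo
cross-validation** (per split, one random trial per participant-session is
withheld; predictions are capped to [0, 1]; RMSE, median absolute error,
and test Q-squared are computed on the withheld trials).

Because the underlying human-subject data are not public, the package
ships a **synthetic study generator** that emulates the full protocol
(12 participants x 4 sessions x 6 trials x 8 epochs of 45 s, rest
baselines, reliability x explainability conditions) with
physiologically-shaped raw signals and a *planted* sparse linear trust
structure, so every stage — cleaning, event detection, feature extraction,
versioning, imputation, selection, validation — is testable against known
ground truth.

## Worked example

```r
library(trustdyn)

design <- study_design(n_participants = 2, n_sessions = 2,
                       n_trials = 3, n_epochs = 4)
study  <- generate_study(design, seed = 11)
study$index[1:3, c("participant", "session", "trial", "epoch", "y")]
#> # A tibble: 3 x 5
#>   participant session trial epoch     y
#>         <int>   <int> <int> <int> <dbl>
#> 1           1       1     1     1 0.501
#> 2           1       1     1     2 0.556
#> 3           1       1     1     3 0.587

feats <- extract_features(study)     # streams trials through the cleaners
fm    <- build_design_matrix(feats) |> impute_missing()
fm
#> <trust_matrix> 48 epochs x 1774 versioned predictors; 1448 missing cells (imputed)

cfg  <- selection_config(n_reps_round1 = 2, n_reps_round2 = 2,
                         nlambda = 30, seed = 3)
mccv <- run_mccv(feats, cfg, n_splits = 2, seed = 21,
                 max_p_fraction = 1, q2_tolerance = Inf)  # tiny-demo scale
tidy(mccv)
#> # A tibble: 2 x 8
#>   split adj_r2 model_q2 test_q2  rmse    mae predictors capped
#>   <int>  <dbl>    <dbl>   <dbl> <dbl>  <dbl>      <int>  <int>
#> 1     1  0.933    0.507   0.529 0.123 0.0992         19      0
#> 2     2  0.914    0.874   0.358 0.108 0.0795         12      0
```

Each row is one Monte-Carlo train/test split: `adj_r2` is the selected
model's fit on its training epochs, `model_q2` its leave-one-trial-out
cross-validation within the training partition, and `test_q2`/`rmse`/`mae`
its performance on the withheld trials (trust-scale units; `capped` counts
predictions clipped into [0, 1]). At this 48-epoch demo scale the
anti-overfitting constraints are lifted (`max_p_fraction`,
`q2_tolerance`); at realistic scales the defaults (n/5 and 0.2) apply.
`plot_trust_traces(mccv)` draws reported vs predicted trust per
participant across the withheld epochs, and
`fit_descriptive(feats, cfg)` fits the all-data model with per-category
predictor retention.

The methods vignette (`vignettes/trustdyn-methods.Rmd`) documents the
generator's physics, every cleaning step, the eight baseline versions,
the hierarchical imputation, the selection rules, and the problem sizes
used by the shipped checks.

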
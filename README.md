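# rootsplit

Exploratory discovery of heterogeneous treatment effects (HTE) in two-arm
randomised controlled trials with a binary outcome, for trial
statisticians and methods researchers who want to go beyond "is there an
interaction?" to "where is the clinically actionable boundary?".

A null average treatment effect can hide subgroups that benefit and
subgroups that are harmed. For a continuous effect modifier, classical
interaction tests — and even data-adaptive variable selection — can flag
the modifier but cannot say where to cut it. `rootsplit` implements three
escalating analyses and a procedure that turns the third into a threshold:

1. **Univariable screen** — per covariate `k`, the logistic interaction
   model `logit E[Y|W,X_k] = β0 + β1 W + β2 X_k + β3 W·X_k`, Wald
   inference on `β3`, Bonferroni correction `α/K`, volcano-plot export.
2. **Strong-hierarchy interaction lasso** — one penalised logistic model
   over all `W·X_k` interactions whose group penalty enforces
   `β3_k ≠ 0 ⇒ β2_k ≠ 0 and β1 ≠ 0` (an interaction can only enter with
   its main effects), with the penalty chosen by 5-fold cross-validation.
3. **Honest causal forest** — an ensemble of causal trees on residualised
   data estimating the conditional average treatment effect
   `τ(x) = E[Y(1) − Y(0) | X = x]` as the forest-weighted residual ratio

   ```
   τ̂(x) = Σ_i α_i(x) (W_i − p̂(X_i)) (Y_i − m̂(X_i)) / Σ_i α_i(x) (W_i − p̂(X_i))²
   ```

   with honesty (each tree's subsample is split: one half chooses splits,
   the other half estimates leaf effects), an omnibus calibration test for
   the presence of heterogeneity (differential forest prediction, DFP),
   and depth-weighted variable importance.
4. **Root-split subgroups** — the first split of each causal tree is the
   best single effect-separating cut on its subsample. Tallying root
   splits across the forest, taking the modal variable and averaging its
   thresholds yields a data-driven cut point; the population is
   partitioned there and each side's group average treatment effect
   (GATE) is estimated from doubly robust AIPW scores
   `Γ_i = τ̂_i + (W_i − p̂_i)/(p̂_i(1−p̂_i)) · (Y_i − m̂_i − (W_i − p̂_i) τ̂_i)`.

The package also ships the surrounding trial plumbing — missingness and
correlation filters, one-hot encoding and standardisation with threshold
back-transformation, four missing-data strategies (iterative
random-forest imputation, mean, complete-case, inverse-probability
weighting) — plus a calibrated synthetic trial generator and a simulation
harness that validates threshold recovery.

## Worked example

The generator is calibrated to a critical-care trial setting: control-arm
28-day survival 72.5%, an effect modifier distributed like maximum serum
potassium (mean 4.58, SD 0.937 mmol/L), and a true subgroup boundary at
4.68 mmol/L across which the treatment's risk difference flips from
+0.069 to −0.257.

```r
library(rootsplit)

cfg <- calibrate_dgp()          # solves the outcome model coefficients
cfg$n_participants <- 1000L
cfg$seed <- 7L
trial <- generate_trial(cfg)

fit <- causal_forest(trial, n_trees = 2000, seed = 7)
print(test_calibration(fit))
#>   omnibus calibration test: DFP = 0.908, one-sided p = 0.0003821

rs <- root_splits(fit)
print(rs)
#>   root splits: 2000 trees split at the root (0 stumps)
#>   modal root variable: X2, mean threshold 4.717 (SD 0.562)

partition_and_gate(fit, rs$modal_variable, rs$mean_threshold)
#> Data-driven subgroups on X2 at 4.717
#> GATE [X2 <= 4.717]: 0.0702 (95% CI -0.0122, 0.1525), n = 537
#> GATE [X2 > 4.717]: -0.1912 (95% CI -0.2868, -0.0957), n = 463
```

Reading the output: the DFP near 1 with a small one-sided p-value says
the forest's CATE heterogeneity is real and well calibrated; the modal
root split recovers the effect modifier `X2` and places the boundary at
4.717 mmol/L, close to the true 4.68; and the two GATEs reproduce the
planted pattern — little or no benefit below the threshold, clear harm
above it. The GATE intervals reuse the data that fit the forest and are
hypothesis-generating, not confirmatory; every printout carries that
caveat. The classical screen agrees that `X2` modifies the effect
(interaction OR 0.630, p = 0.0024 on this dataset) but, by itself, yields
no threshold.

For a full pipeline on messy data (missingness, mixed covariate types,
correlated columns) see `analyse_trial()`, which chains the filters,
imputation, all three analyses and the subgroup step, and
`generate_vanishlike()` for fixtures. `run_simulation()` repeats the
whole comparison over many synthetic trials and aggregates performance
metrics; the methods vignette (`vignettes/rootsplit-methods.Rmd`)
documents the models, defaults and design decisions.

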
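# deepgam

Interpretable neural additive models for binary clinical risk
classification, with embedded feature selection through straight-through
binary gates.

Clinical tabular data — biomarker panels, questionnaire scores,
demographics — often demands models whose per-feature effects can be
inspected and defended, not just a good AUC. `deepgam` fits a generalized
additive model whose shape functions are small neural networks:

    ỹ = β₀ + Σⱼ fⱼ(xⱼ · g(φⱼ)),     fⱼ(z) = tanh(θ⁽³⁾ relu(θ⁽²⁾ relu(θ⁽¹⁾ z)))

* Each feature gets its own bias-free three-layer network `fⱼ`, so
  `fⱼ(0) = 0` exactly and the tanh output bounds every contribution to
  (−1, 1) — no feature can silently dominate the sum.
* Each feature carries a gate logit `φⱼ`. The forward pass uses the hard
  binary gate `g(φ) = round(σ(φ))` (alive iff `φ ≥ 0`); the backward pass
  treats the gate as the smooth `σ(φ)` — a straight-through estimator —
  so feature selection is learned jointly with the model by plain SGD.
* Training minimizes `E[ L + λ₁R₁ + λ₂R₂ ]`, where `L` is mean squared
  error against ±1 labels, `R₁ = Σⱼ‖fⱼ(zⱼ)‖²` keeps per-feature effects
  small and honest, and `R₂ = Σⱼ g(φⱼ)` — the alive-feature count —
  prices every active feature and prunes the rest during training.

The package also provides the surrounding workflow: a synthetic cohort
generator with known additive ground truth (right-skewed features, class
imbalance), gradient-trained baselines (hinge-loss linear "SVM", logistic
regression, a 3-layer MLP), an L1 coordinate-descent feature-ranking
comparator, a class-rebalancing sampler, confusion/ROC/AUC metrics, a
leakage-free stratified cross-validation harness, shape-curve extraction
for model explanation, and an ablation grid over the R₁/tanh toggles.

## Worked example

Simulate a cohort shaped like a clinical biomarker panel (1000 subjects,
99 right-skewed features of which 5 carry signal, 22.6% positives), fit
DeepGAM at the reference hyperparameters, and inspect what it learned:

```r
library(deepgam)

sim <- make_classification(n = 1000, m_informative = 5, m_noise = 94,
                           positive_rate = 0.226, seed = 1)
sim$data
#> <deepgam_dataset> 1000 rows x 99 features (classification)
#>   positives: 232 (23.2%)

sp        <- split_dataset(sim$data, test_fraction = 0.3, seed = 2)
scaler    <- fit_standardizer(sp$train)
train_std <- apply_standardizer(sp$train, scaler)

cfg   <- training_config(seed = 1)   # lr 0.01, batch 16, 40 epochs, C 128,
                                     # lambda1 1, lambda2 0.005, phi-init 0.05
model <- init_model(M = 99, C = 128, seed = 1,
                    feature_names = train_std$feature_names)
fit   <- train(model, train_std, config = cfg)

model <- fit$model
model$scaler <- scaler
report <- evaluate_scores(predict_scores(model, sp$test$features)$scores,
                          sp$test$labels)
report
#> <eval n=300> AUC 0.860 | acc 0.587 | F1 0.508 | prec 0.352 | rec 0.914 | spec 0.487

head(rank_by_gate(model)[, c("rank", "feature_name", "score")], 5)
#>   rank feature_name      score
#> 1    1           x1 0.01959735
#> 2    2          x69 0.01904211
#> 3    3          x68 0.01720186
#> 4    4          x76 0.01708561
#> 5    5          x26 0.01701933

sim$ground_truth$informative_indices
#> [1]  1 34 39 68 87
```

Reading the output: the held-out AUC of 0.86 says the additive model
separates cases from controls well on this benchmark; the gate ranking
(by logit, descending) puts two truly informative features (`x1`, `x68`)
in its top five. `fit$history` tracks the objective components and the
alive-feature count per epoch; `shape_curve(model, 1, sim$data)` returns
the learned effect curve of a feature — the model's explanation — and
`export_explanation()` writes all curves, histograms and a summary to
CSV/JSON. `select_and_retrain()` retrains on the top-k features with the
gates frozen, `cross_validate()` wraps the whole protocol (standardizer
and selection refit inside each fold), and `ablation_suite()` reproduces
the R₁/tanh ablation signatures.

A thin command-line wrapper around the same functions lives at
`inst/cli/deepgam.R`:

```sh
Rscript inst/cli/deepgam.R simulate --n 1000 --informative 5 --noise 94 --seed 1 --out sim.csv
Rscript inst/cli/deepgam.R train    --data sim.csv --out-dir run/
Rscript inst/cli/deepgam.R select   --data sim.csv --method ste --k 5 --out-dir sel/
Rscript inst/cli/deepgam.R explain  --model run/model.json --data sim.csv --out-dir explain/
```

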
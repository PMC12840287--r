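# GTsurv

Restricted-mean-survival-time (RMST) prediction for arbitrarily censored
cohorts, combining a Turnbull nonparametric survival estimator, jackknife
pseudo-observations, and a hybrid graph-convolutional / soft-decision-tree
regressor.

## Who this is for

Biostatisticians and computational biologists who observe event times only
between irregular clinic visits — so every subject contributes an interval
`[L, R]` (left-, interval-, or right-censored, or an exact time) — and who
want per-subject predictions of expected survival within a clinical horizon
from high-dimensional baseline covariates such as gene expression.

## The method

For horizons `τ₁ < … < τ_K`, the target is the restricted mean survival
time

    μ(τ | X) = E[min(T, τ) | X] = ∫₀^τ S(t | X) dt.

The pipeline has three stages:

1. **Turnbull NPMLE** (`fitNPMLE`). Probability masses ρⱼ on the Turnbull
   intervals of the pooled endpoints maximise
   ∑ᵢ log ∑ⱼ αᵢⱼ ρⱼ, fitted by a hybrid EM–ICM scheme: a self-consistency
   sweep alternating with a projected-Newton step on the CDF under the
   monotonicity constraint (weighted pool-adjacent-violators projection,
   step-halving). The log-likelihood is monotone along iterations, and on
   fully exact data the estimator equals the empirical survival function.

2. **Jackknife pseudo-observations** (`pseudoRMST`). With μ̂(τ) the RMST of
   the fitted curve and μ̂⁽⁻ⁱ⁾ its leave-one-out version,

       ỹᵢ(τ_k) = n·μ̂(τ_k) − (n−1)·μ̂⁽⁻ⁱ⁾(τ_k)

   is a complete n×K regression response. For exact data,
   ỹᵢ(τ) = min(Tᵢ, τ) exactly.

3. **Hybrid predictor** (`patientGraph`, `gtTrain`, `predictRMST`). A KNN
   patient-similarity graph (union-symmetrised, uniformly weighted) gives
   the propagation matrix Â = D̃^(−1/2)(A+I)D̃^(−1/2); two GCN layers
   H⁽²⁾ = ReLU(Â ReLU(Â X W⁽⁰⁾) W⁽¹⁾) feed a soft binary decision tree:
   routing probability d_e = sigmoid(f_e) per internal node, leaf-reach
   probabilities p_l, and prediction g(Xᵢ, τ_k) = ∑_l λ_{lk} p_l(Xᵢ).
   Training is full-batch Adam on the masked loss
   (1/nK) ∑ᵢ∑ₖ (ỹᵢₖ − gᵢₖ)², with dropout, early stopping on a validation
   fold, and exact hand-derived backpropagation; the compact closed-form
   tree gradients (`treeGradients`) are kept as an independently tested
   oracle. Baselines `"gcn"` (no tree), `"dnn"` (no graph), `"ndf"`
   (tree, no graph) share the trainer.

A simulation engine (`simulateCohort`) reproduces the evaluation designs —
AR(1)-correlated Gaussian covariates, exponential hazards η(X) from three
designs, and a 10-visit censoring mechanism — and `runExperiment` is the
replicated end-to-end harness.

## Worked example

```r
library(GTsurv)

coh <- simulateCohort(n = 120, p = 20, experiment = 1, seed = 7)
coh
#> SimulatedCohort: experiment 1 with 120 subjects, 20 covariates
#>     left interval    right
#>       91       29        0

pv <- pseudoRMST(cohortData(coh), taus = c(1, 3))
pv
#> PseudoValues: 120 subjects x 2 horizons (tau = 1, 3 )
#>   population RMST: 0.4047, 0.5016

sp  <- makeSplit(120, seed = 7)
g   <- patientGraph(features(coh), k = 10)
fit <- gtTrain(features(coh), pv, g, method = "gt",
               trainIdx = sp$train, valIdx = sp$val,
               config = gtConfig(hidden = c(16, 8), depth = 2, seed = 7))
fit
#> GTModel [gt]: GCN + soft decision tree
#>   layers: 20 -> 16 -> 8 -> tree depth 2
#>   horizons: 1, 3
#>   best epoch: 83 of 133 (val MSE 0.1349 )

pred <- predictRMST(fit, features(coh), g)
round(head(pred, 3), 3)
#>       tau1  tau3
#> [1,] 0.409 0.500
#> [2,] 0.419 0.510
#> [3,] 0.362 0.451

rmstMetrics(pred[sp$test, ], trueRMST(coh, c(1, 3))[sp$test, ])
#>       mse       mae
#> 0.1619602 0.4547036
```

The cohort is dominated by left censoring because most simulated events in
design 1 occur before the first visit. The population RMST says the average
subject survives about 0.40 of the first year and 0.50 of the first three
years (event-free); per-subject predictions vary around those values, and
the test metrics are the sum-over-horizons squared and absolute errors
against the generative truth, averaged over held-out subjects.

A command-line front end for the whole pipeline
(simulate / pseudo / fit / predict / evaluate / experiment) is installed at
`inst/cli/gtsurv.R`:

    Rscript $(Rscript -e 'cat(system.file("cli/gtsurv.R", package="GTsurv"))') \
        simulate --out cohort_dir --n 200 --p 50 --experiment 1 --seed 1

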
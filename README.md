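# mfcpnet

Classification of subjects from resting-state fMRI ROI time series by
fusing **multiple functional connection patterns**: full correlation,
sparse (conditional) regression, and directed lagged influence, each fed
to its own graph convolutional branch, pooled, fused and classified — with
node-level Grad-CAM attribution of the prediction back to brain regions.
The package is aimed at researchers building connectome-based classifiers
(e.g. patient-vs-control studies) who want the whole pipeline — network
estimation, training protocol, ablations, sensitivity sweeps,
interpretation — as composable, seeded, testable R functions.

## The model

Each subject is a matrix $X \in \mathbb{R}^{t\times n}$ (time points ×
ROIs). Three estimators produce $n \times n$ adjacencies:

* **PC** — Pearson correlation of the mean-centred regional series,

$$w_{ij}=\frac{(x_i-\bar{x}_i)^\top (x_j-\bar{x}_j)}
  {\lVert x_i-\bar{x}_i\rVert\,\lVert x_j-\bar{x}_j\rVert};$$

* **SR** — per-region lasso
  $\min_w \lVert x_i-\sum_{j\neq i}w_j x_j\rVert^2+\lambda\sum_{j\neq i}\lvert w_j\rvert$
  solved by coordinate descent (default $\lambda = 1$), capturing
  conditional dependence;
* **GCM** — pairwise Granger causality
  $G_{x\to y}=\ln(\mathrm{RSS}_{restricted}/\mathrm{RSS}_{unrestricted})\ge 0$,
  symmetrised as $A_{ij}=\lvert G_{i\to j}+G_{j\to i}\rvert$.

Each matrix is canonicalized (symmetric, non-negative, zero diagonal,
rescaled to max 1, thresholded at 0.1/0.2/0.2 by default, weights kept)
and becomes a graph whose node features are the regions' connectivity
profiles. Each pattern's branch applies two first-order spectral graph
convolutions $H^{(l+1)}=\mathrm{ReLU}\big(\hat{D}^{-1/2}(A+I)\hat{D}^{-1/2}H^{(l)}W^{(l)}\big)$
(32 units each), a mean‖max readout to a 64-vector; branch readouts are
concatenated (192-dim for three patterns) and classified by fully
connected layers $[64\!\cdot\!B, 32, 16, 2]$ with dropout 0.5, trained
with Adam (lr 0.0025, weight decay 1e-5, 150 epochs, cross-entropy) and
validation-accuracy checkpointing. Grad-CAM scores each ROI by the
rectified, gradient-weighted sum of the final conv layer's features.

Because real clinical cohorts of this kind are access-restricted, the
package ships a seeded two-group VAR(1) cohort simulator whose groups
differ in directed lag coupling *and* contemporaneous covariance, so all
three patterns carry recoverable signal.

## Worked example

```r
library(mfcpnet)

cohort <- simulate_cohort(mfcp_demo_config(n_rois = 12, n_subjects_per_group = 15, seed = 1))
graphs <- build_cohort_graphs(cohort)             # PC + SR + GCM graphs per subject
fit    <- train_model(graphs, config = train_config(seed = 1))
fit
#> <mfcp_fit> patterns: PC+SR+GCM | best epoch 150 | test accuracy 1
glance(fit)
#> # A tibble: 1 × 11
#>   patterns  best_epoch accuracy precision recall    f1   auc    tp    tn    fp
#>   <chr>          <int>    <dbl>     <dbl>  <dbl> <dbl> <dbl> <int> <int> <int>
#> 1 PC+SR+GCM        150        1         1      1     1     1     3     3     0
```

The test-set metrics (accuracy, precision, recall, F1 from the confusion
counts; rank-based AUC) are computed on the held-out 20% of the stratified
70/10/20 split. On this strongly separable synthetic cohort the fused
model classifies the six held-out subjects perfectly. Region-level
attribution recovers the planted effect (the simulator's group difference
lives in ROIs 1–6):

```r
imp <- gradcam_cohort(fit, graphs, indices = fit$split$test)
top_k_rois(imp, k = 3)
#> # A tibble: 9 × 5
#>   pattern  rank   roi roi_label mean_score
#>   <chr>   <int> <int> <chr>          <dbl>
#> 1 GCM         1     5 ROI_5          0.5
#> 2 GCM         2     6 ROI_6          0.491
#> 3 GCM         3     3 ROI_3          0.222
#> 4 PC          1     2 ROI_2          0.495
#> 5 PC          2     1 ROI_1          0.491
#> 6 PC          3     4 ROI_4          0.489
#> 7 SR          1     2 ROI_2          0.490
#> 8 SR          2     4 ROI_4          0.485
#> 9 SR          3     3 ROI_3          0.464
```

Other entry points: `ablation_study()` (all seven pattern subsets under
identical splits), `cross_validate()` (stratified k-fold),
`repeated_runs()` (mean ± sd over seeds), `sweep_lambda()` /
`sweep_threshold()` (sensitivity tables), `export_embeddings()` (fused
vectors for external embedding tools), `run_pipeline()` (on-disk
end-to-end composition), and `autoplot()` on every result type. A thin
command-line wrapper lives at `inst/cli/mfcp.R`.

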
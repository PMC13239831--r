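---
title: "Multi-pattern functional connectivity classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pattern functional connectivity classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mfcpnet classifies subjects from resting-state ROI time series by fusing
three complementary views of functional connectivity — full correlation,
sparse (conditional) regression, and directed lagged influence — through a
multi-branch graph convolutional network, and explains the resulting
predictions at the level of individual brain regions. This vignette
describes the models, the numerical choices behind them, and what the
bundled synthetic cohort can and cannot tell you about real data.

## The three connection patterns

Each subject arrives as a matrix $X \in \mathbb{R}^{t \times n}$ of $t$
time points over $n$ ROIs (at full scale $232 \times 116$, matching a
standard whole-brain parcellation). Three estimators turn $X$ into an
$n \times n$ weighted adjacency:

**Pearson correlation (PC).** Edge $w_{ij}$ is the correlation of the two
regional time courses — the cosine of the mean-centred series. It captures
synchronous co-fluctuation, including indirect paths.

**Sparse representation (SR).** For each target region $i$ we solve

$$\min_{w} \; \lVert x_i - \textstyle\sum_{j \neq i} w_j x_j \rVert^2
  + \lambda \textstyle\sum_{j \neq i} \lvert w_j \rvert ,$$

an L1-penalised regression of each region on all others, by cyclic
coordinate descent with exact soft-threshold updates. Because every other
region competes as a regressor, surviving coefficients indicate
*conditional* dependence, in the spirit of partial correlation. The
penalty is read as an L1 norm: an unsigned linear penalty has no
minimiser, and the estimator is explicitly a lasso-type model. The default
$\lambda = 1$ is the value at which the SR-only classifier peaks in the
sensitivity sweep. Per-coordinate minimisation makes the objective
non-increasing at every step; the solver records per-sweep objective
traces and a convergence flag per row (non-convergence is a warning, not
an error). The solver is well-defined for $t < n$, so short recordings
over many ROIs still process.

**Granger causality mapping (GCM).** For each ordered pair
$(x \rightarrow y)$ we fit, by least squares over the common effective
sample, a restricted autoregression of $y$ on its own lags and an
unrestricted one that adds lags of $x$, and score

$$G_{x \rightarrow y} = \ln \frac{\mathrm{RSS}_{\text{restricted}}}
  {\mathrm{RSS}_{\text{unrestricted}}} \;\ge\; 0 .$$

The ratio is oriented so that stronger evidence of lagged influence gives
a larger non-negative strength, consistent with aggregating magnitudes in
the symmetrisation step $A_{ij} = \lvert G_{i \to j} + G_{j \to i}\rvert$.
The default lag order is 1 (configurable); rank-deficient designs are
ridge-stabilised with a $10^{-8}$ jitter, and a perfect unrestricted fit
is capped at $\ln 10^{12}$ with a warning.

## Canonicalization and thresholding

A raw estimate becomes a propagation-ready adjacency by: symmetrising
(averaging $W$ and $W^\top$ — the undirected analogue of the additive
aggregation used for GCM), taking absolute values (edge weights are
treated as non-negative connection strengths), zeroing the diagonal,
rescaling to maximum entry 1, and zeroing entries below a per-pattern
threshold while keeping surviving weights (the graphs stay weighted; the
convolution propagates weights, so binarising would discard information).
Defaults are 0.1 (PC) and 0.2 (SR, GCM), each pattern's accuracy peak in
the threshold sweep.

One subtlety is deliberate: with rescaling first, the maximum entry is
always 1 and no threshold below 1 can empty a graph. The alternative
reading — thresholding the raw magnitudes — can empty graphs whose weights
are uniformly small, which is exactly how sparse Granger log-ratio graphs
collapse at moderate absolute thresholds. `canonicalize()` defaults to the
rescaled convention and exposes `threshold_scale = "raw"` for the other;
the threshold sweep driver records an emptied pattern as a flagged
degenerate row rather than failing.

Node features are each region's connectivity profile — the rows of the
canonical adjacency. The network never sees raw time series; each branch
sees one pattern's graph with profile features, which keeps the feature
dimension equal to $n$ and is the standard convention for connectome
classifiers when no other node attributes exist.

## The classifier

Each pattern graph passes through its own branch of a first-order spectral
GCN. The propagation operator is the self-loop-augmented, symmetrically
normalised adjacency
$\hat{D}^{-1/2}(A + I)\hat{D}^{-1/2}$ with
$\hat{D}_{ii} = \sum_j (A + I)_{ij}$; its eigenvalues lie in $[-1, 1]$ and
self-loops guarantee positive degrees, so even an empty graph propagates
(as the identity). The normalised Laplacian is exposed as a derived
quantity for inspection; propagation itself always uses the renormalised
operator. A branch applies two propagate–linear–rectify rounds with
32-unit, bias-free weight matrices (the printed propagation rule carries
no bias; the fully connected head does, as is standard for MLP
classifiers), then a readout concatenating the columnwise mean and
maximum of the node embeddings into a 64-vector. Branch readouts are
concatenated in the fixed order PC, SR, GCM — so fused vectors are
comparable across runs — giving 64, 128 or 192 dimensions for one, two or
three branches, and pass through fully connected layers of widths
$[64\!\cdot\!B, 32, 16, 2]$ with rectifiers between layers and dropout
(rate 0.5) after the first two. Weights are Glorot-uniform from the run
seed.

Training minimises the softmax cross-entropy with Adam (learning rate
0.0025, weight decay $10^{-5}$) for 150 epochs, full batch — cohorts at
this scale are at most a few hundred subjects, and full-batch steps remove
an undocumented degree of freedom (mini-batching is available via
`batch_size`). After every epoch the model is scored on the validation
set; the checkpoint with the highest validation accuracy is kept, ties
resolved by lower validation loss and then by the earlier epoch. There is
no deep-learning framework dependency: the forward pass, the backward
pass (including the mean/max readout routing, where the max gradient flows
to the first-encountered argmax row) and Adam are implemented directly in
matrix algebra, and the analytic gradients are verified against central
finite differences in the test suite.

## Evaluation protocol

The single-split protocol is a stratified 70/10/20
train/validation/test partition (largest-remainder rounding keeps every
subset within one subject of exact stratification), repeated over
independent seeds that redraw both the split and the initialisation;
summaries report the mean and *sample* standard deviation ($n-1$) across
repetitions. Whether repeated runs should also resample the split is not
decidable from the protocol description alone; resampling both is the
stricter reading and is what `repeated_runs()` does. The k-fold driver
(default $k = 5$) stratifies folds and carves one eighth of each fold's
training portion out as the validation set used for checkpointing,
mirroring the 70/10 ratio; leave-one-out ($k = n$) is supported as a
special case. Metrics are accuracy, precision, recall and F1 from the
confusion counts (positive class = case throughout) and the rank-based
Mann–Whitney AUC with half-credit for ties; a single-class evaluation set
reports AUC as undefined rather than guessing.

The ablation driver trains the identical architecture on all seven
non-empty pattern subsets under identical splits and seeds, the head
width adapting to the branch count. Sensitivity drivers re-estimate only
the affected pattern per grid point ($\lambda$ for SR, threshold per
pattern) and retrain under fixed seeds.

## Grad-CAM attribution

For each branch, let $H \in \mathbb{R}^{n \times 32}$ be the final
convolution layer's node features, before readout. The gradient of the
target class's pre-softmax logit with respect to $H$ is obtained from the
same hand-derived backward pass used in training (dropout off). Channel
weights are the node-averaged gradients
$\alpha_k = \frac{1}{n}\sum_i \partial y_c / \partial H_{ik}$ — a global
weight per channel, implemented literally rather than substituting
per-node weights — and region $i$ scores
$S_i = \mathrm{ReLU}(\sum_k \alpha_k H_{ik})$. Scores are normalised
within each subject by dividing by the maximum, preserving zeros and
relative magnitudes; an all-zero vector (everything rectified away, or a
branch the head ignores) is returned unnormalised with a degenerate flag.
The attributed class defaults to the case class and is configurable, since
either class's logit is a legitimate target. Rankings average normalised
scores over subjects (and over models, when pooling repeated runs) per
pattern, with ties broken by ROI index; the report adds the pairwise
overlap of top-$k$ sets across patterns.

## The synthetic cohort

Real clinical resting-state cohorts of this kind are access-restricted,
so the package ships a generative stand-in rather than data. Each group
is a stationary VAR(1) process
$x_t = A_g x_{t-1} + \varepsilon_t$, $\varepsilon_t \sim N(0, \Sigma_g)$,
with a burn-in of 200 steps discarded and per-subject columns z-scored
(correlation-based estimators are scale-free, and no signal units are
assumed). The two levers are exactly the two kinds of structure the three
estimators see: the lag matrix $A_g$ carries directed influence
(recoverable by GCM) and the innovation covariance $\Sigma_g$ carries
contemporaneous coupling (recoverable by PC, and conditionally by SR) —
the premise being that the patterns are complementary, so each must carry
recoverable group signal. Configurations are validated up front: a lag
matrix with spectral radius $\ge 1$ or a non-positive-definite covariance
is rejected with a diagnostic. All randomness flows from one root seed
through deterministically derived per-subject seeds, so cohorts are
bitwise reproducible and individual subjects do not depend on how many
others were drawn.

The reference "strong-effect" study (`mfcp_demo_config()`) uses 20 ROIs,
30 subjects per group and 232 time points — a desk-scale stand-in chosen
so a full repeated-seed experiment runs in minutes on one CPU, with the
full 116-ROI scale supported through the same configuration object. Both
groups share an AR(1) self-dependence of 0.3; the case group additionally
has directed coupling 0.45 between consecutive pairs of the first six
ROIs and equicorrelated innovations ($\rho = 0.5$) among them. These
values were fixed once, before any classifier was run, as a plausible
"large, localised effect" regime: coupling strengths safely inside the
stationary region, an effect confined to 30% of regions, and noise at
unit scale. Which ROIs differ is purely a bookkeeping choice of the
simulator, not a claim about the biology of any disorder. At this effect
size the groups are strongly separable — single-pattern models often reach
perfect test accuracy at desk scale — so recovery experiments exercise
the machinery rather than discriminate between patterns;
`effect_scale` shrinks both levers for graded-difficulty experiments, and
the effect-monotonicity test works at reduced scales where the patterns
do differ.

What the simulator deliberately omits: hemodynamic response convolution,
scanner and physiological noise spectra, motion artefacts, multi-site
batch effects, and any realistic anatomical covariance structure. Passing
tests on this cohort therefore demonstrate that the estimators recover
the kinds of dependence they target and that the classifier and
attribution machinery behave correctly end to end — not that any
particular accuracy transfers to clinical recordings.

## Numerical choices and degenerate inputs

* Zero-variance (flat) regions: correlation weights are zeroed with a
  warning naming the region; Granger targets likewise. Cohorts with flat
  regressors process rather than fail.
* SR convergence: per-sweep maximum coefficient change below `tolerance`
  (default $10^{-8}$), capped at `max_iterations` sweeps with a warning
  flag.
* Readout max-gradient ties route to the first argmax row; argmax ties
  are measure-zero for generic inputs and the choice is deterministic.
* Prediction ties (equal logits) resolve to the control class.
* Dropout uses inverted scaling (masks scaled by $1/\mathrm{keep}$), so
  eval mode needs no rescaling and is exactly deterministic.
* All tabular outputs are tibbles; `tidy()`/`glance()` cover fitted
  models, repeated runs and cross-validations, and `autoplot()` covers
  histories, ablations, sweeps and importance reports.

## Known limitations

The pairwise Granger score uses bivariate conditioning only (each driver
tested against the target's own history), not the fully conditional
multivariate form; at lag 1 with modest $n$ this is the common choice for
connectome construction but can attribute shared-driver effects to
direct edges. The GCN is first-order spectral with two layers; deeper
stacks or polynomial filters are out of scope, as is attention-based
fusion — concatenation treats every pattern equally. Training is
single-threaded R matrix algebra: ample for desk-scale cohorts and the
116-ROI scale with hundreds of subjects, but not for thousands of
subjects or voxel-level graphs.
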
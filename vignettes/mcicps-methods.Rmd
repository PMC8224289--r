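---
title: "Subtype-based prediction of MCI-to-AD conversion: models and methods"
author: "mcicps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-based prediction of MCI-to-AD conversion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mild cognitive impairment (MCI) is the prodromal stage of Alzheimer's
disease (AD), but only a fraction of MCI patients progress to AD within a
clinically relevant horizon (here: three years; progressive MCI, P-MCI,
versus stable MCI, S-MCI).  Alzheimer's disease is heterogeneous: the
molecular processes that drive progression differ between patient
subgroups, so the features that predict conversion differ between
subgroups too.  `mcicps` implements a subtype-based prediction strategy on
three modalities per patient — SNP genotypes, peripheral-blood gene
expression and structural-MRI regional brain volumes (ROI volumes):

1. cluster the training patients into molecular subtypes from the
   genotype and expression layers (similarity network fusion + spectral
   clustering);
2. assign any new patient to a subtype by semi-supervised label
   propagation over a joint patient-similarity network;
3. within each subtype, select conversion-informative features per
   modality by repeated, class-balanced, undersampled Lasso with safe
   screening, and predict conversion with a variational-Bayes
   multiple-kernel multinomial-probit classifier on the selected
   features of all three modalities.

The "raw" baseline (`trainRawClassifier()`) is the identical pipeline
without the subtyping stage; the package's central testable property is
that, on cohorts whose conversion signal is genuinely subtype-specific,
the subtype-based model outperforms the raw baseline.

# Preprocessing

**Genotype QC** (`qcGenotypes()`): SNPs are excluded when the missing
rate exceeds 0.05, the minor allele frequency is below 0.05, or the
Hardy–Weinberg equilibrium p-value is below $10^{-3}$ (strict
inequalities, filters applied in that order, all statistics on
non-missing calls).  The HWE test is the 1-df chi-square of the genotype
counts against the expectation at the observed allele frequency, without
continuity correction.  PLINK's default is an exact test; at a $10^{-3}$
threshold the difference is immaterial and the chi-square is transparent
enough to verify by hand (counts (50, 0, 50) in 100 samples give
$\hat p = 0.5$, expectation (25, 50, 25) and $\chi^2 = 100$).
Genotype imputation against a reference panel is out of scope; missing
calls surviving QC are imputed at the per-SNP *training* mean, which after
z-scoring is exactly 0 (`applyStandardizer()`).

**ICV adjustment** (`fitIcvAdjuster()`/`applyIcvAdjuster()`): regional
volumes scale with head size, so each ROI volume is corrected by the
regression-slope method,
$$\mathrm{ROI}^{(i)}_{\mathrm{adj}} = \mathrm{ROI}^{(i)}_{\mathrm{raw}}
  - \theta_i\,(\mathrm{ICV} - \overline{\mathrm{ICV}}),$$
with $\theta_i$ the OLS slope of ROI $i$ on intracranial volume over the
training samples and $\overline{\mathrm{ICV}}$ the training mean.  Only
the slope component about the training mean is removed — the intercept is
retained, so volumes keep their physical scale, and on the training set
every adjusted ROI is exactly uncorrelated with ICV (OLS orthogonality,
a property the tests check to $10^{-10}$).

**Standardization**: all modalities are z-scored with training means and
SDs; test data always reuse the training parameters.  Adjustment precedes
z-scoring for ROI features: the order is not dictated by the protocol,
but a slope in mL per mL is only meaningful on raw volumes, so adjusting
z-scored volumes would be circular.  No statistic anywhere in the
pipeline is computed from test samples; the test suite checks this by
permuting test labels and hashing fitted parameters.

# Subtyping

**Affinity networks** (`buildAffinity()`): for each modality a scaled
exponential kernel
$W(i,j) = \exp\!\big(-d^2(i,j)/(\mu\,\varepsilon_{ij})\big)$ with local
scale $\varepsilon_{ij} = (\bar d_K(i) + \bar d_K(j) + d(i,j))/3$, where
$\bar d_K(i)$ is patient $i$'s mean distance to its $K$ nearest
neighbours.  Distances are Euclidean on standardized features; a
chi-squared distance on the 0/1/2 genotype counts is available by
configuration.

**SNF** (`snfFuse()`): the cross-diffusion update.  Each layer's full
kernel is normalized to a transition form $P_v$ (off-diagonal mass
halved, diagonal 1/2) and a sparse row-normalized K-nearest-neighbour
kernel $S_v$ is derived; for $T$ iterations,
$P_v \leftarrow S_v \left(\tfrac{1}{m-1}\sum_{u \neq v} P_u\right) S_v^\top,$
symmetrized and renormalized.  The fused network is the mean of the final
layers.  Similarity supported by several modalities is reinforced;
modality-specific noise decays.  Per-iteration Frobenius change norms are
kept as a convergence diagnostic.

**Spectral clustering** (`spectralCluster()`): the RatioCut relaxation —
eigenvectors of the $C$ smallest eigenvalues of the unnormalized
Laplacian $L = D - W$, then k-means on the embedded rows with a fixed
seed and multiple restarts.  $C = 2$ by default (two MCI subtypes); the
eigengap is reported as a diagnostic but never used to pick $C$.  If the
graph has more connected components than $C$ the components themselves
are returned with a warning.

**Label propagation** (`labelPropagate()`): a joint fused network is
built over training *and* new samples (genotype + expression layers),
row-normalized to a transition matrix $P$, and the clamped iteration
$F \leftarrow \alpha P F + (1-\alpha) Y$ is run with the training rows
reset to their one-hot labels after every step, until the largest row
change falls below `tol`.  Whether the original propagation operated on a
joint graph or projected new samples onto a fixed graph is not
recoverable from the protocol; the joint-graph clamped iteration is this
package's documented choice (it is the variant that makes the
"duplicate of a training sample inherits its subtype" property exact).
Defaults $\alpha = 0.99$, `tol` $= 10^{-6}$, 1000 iterations are the
standard settings for clamped propagation and are exposed in the
configuration.

SNF hyperparameters are not stated in the protocol; the defaults follow
the SNF reference's recommended ranges: $K = 20$ (capped at $N/3$),
$\mu = 0.5$, $T = 20$.  Subtyping deliberately uses only the genotype and
expression layers; the ROI layer enters the classifiers but not the
clustering.

# Feature selection

The selection score of a feature is the number of times the Lasso
$$\min_x \tfrac{1}{2}\lVert Ax - y\rVert_2^2 + \lambda \lVert x\rVert_1$$
picks it (nonzero coefficient — no post-hoc magnitude threshold) across
repeated class-balanced subproblems (`runStabilitySelection()`).  Each
inner run draws all minority-class samples plus an equal-size random
majority draw, centers the 0/1 response, draws one penalty fraction $f$
uniformly from a 10-point grid spanning 0.05–0.5 and solves at
$\lambda = f \cdot \lambda_{\max}$ of the subproblem
($\lambda_{\max} = \max_j |A_j^\top y|$, the smallest penalty with an
all-zero solution).  The printed range $0.05 < \lambda < 0.5$ is read as
*fractions of* $\lambda_{\max}$ — the convention of the screening toolbox
the protocol used; absolute penalties in (0.05, 0.5) would be
meaningless across subproblems of varying scale.  Counts accumulate over
all `outer` × `inner` runs (headline protocol 50 × 1000), with the outer
layer re-seeding the undersampler; whether the original drew one
$\lambda$ per run or swept the grid per run is unstated, and
one-draw-per-run is the documented choice here.  Ranking is by
descending count with ties broken by larger mean absolute coefficient,
then feature id — stable and deterministic.

The solver is exact cyclic coordinate descent with soft-thresholding on
the Gram form (compiled inner loop), certified by an independently
computed KKT residual.  **EDPP safe screening** (`edppScreen()`)
implements the enhanced dual polytope projection rule: from the exact
solution at $\lambda_0$ (possibly the zero solution at
$\lambda_{\max}$), features whose dual correlation bound
$|A_j^\top(\theta_0 + v_2^\perp/2)| < 1 - \tfrac{1}{2}\lVert v_2^\perp\rVert\,\lVert A_j\rVert$
holds are *provably* zero at $\lambda_1 < \lambda_0$ and are dropped
before solving.  The safety contract — a rejected feature is never active
in the unscreened solution, and screened and unscreened solutions agree
coefficientwise — is the module's central oracle test (100 random
instances, $10^{-8}$).

The per-modality feature count can be fixed (`n_features`, default 10) or
searched (`n_features = "auto"`): for $n = 1, \dots, 100$ the top-$n$
ranked features feed a single-modality VBpMKL classifier scored by mean
AUC over repeated stratified fivefold CV, with the ranking re-fit inside
each training fold; ties go to the smallest $n$.  Whether the original
search classifier saw one or all modalities is ambiguous;
single-modality is the tractable reading adopted here.  The search is
expensive and therefore opt-in.

# The classifier

`fitVbpmkl()` is a variational-Bayes multiple-kernel multinomial-probit
model.  Each modality contributes a base Gram matrix (Gaussian
$K(i,j) = \exp(-\lVert x_i - x_j\rVert^2 / 2\theta_m^2)$ by default,
$\theta_m$ set by the median pairwise-distance heuristic since no value
is stated); the composite kernel is the convex combination
$K_\beta = \sum_m \beta_m K_m$ with $M = 3$ modalities.  By default
$\beta = (1/M, \dots)$ — the *mean composite kernel*, which is what the
protocol's text describes.  An optional data-driven reweighting
(`beta_update = TRUE`) sets $\beta_m$ proportional to the normalized
centered alignment between $K_m$ and the class co-membership matrix; the
exact variational $\beta$ update of the original toolkit is not
recoverable from the text, so both modes are provided and the fixed mean
kernel stays the default.

Generatively, each sample has latent scores $y_n = W k_n + \epsilon$
with standard-normal noise and observed class
$t_n = \arg\max_c y_{nc}$; each class row of $W$ has an isotropic
Gaussian prior with precision $\phi$ (default 1).  The factorized
posterior $Q(W)\,Q(Y)$ is iterated: the $Q(W)$ update is the ridge-type
Gaussian update $V = (\phi I + K^\top K + \text{jitter})^{-1}$,
$M = V K^\top \mathbb E[Y]$ (covariance shared across classes); the
$\mathbb E[Y]$ update evaluates the truncated-Gaussian moments through a
one-dimensional integral over a standard-normal mixing variable,
computed by 64-node Gauss–Hermite quadrature.  Convergence is declared
when $\max |\Delta \mathbb E[Y]| < 10^{-5}$ (at most 200 iterations).  On
*separable* data the latent scores drift and the absolute criterion is
met only slowly; predictions stabilize long before, so hitting
`max_iter` raises a warning, not an error.

The predictive distribution is
$$P(t_n = i \mid W, k_n) = \mathbb E_{\mu \sim N(0,1)}\Big[\prod_{j \neq i}
  \Phi\big(\mu + (w_i - w_j)^\top k_n\big)\Big],$$
evaluated at the posterior-mean regressors by the same quadrature and
renormalized over classes; in the binary case this collapses to
$\Phi\big((w_1 - w_2)^\top k_n / \sqrt 2\big)$, which the tests verify
to $10^{-6}$, and the multiclass quadrature is checked against a
$10^6$-draw Monte-Carlo evaluation.  Binary decisions call P-MCI when its
posterior probability is at least $\tau$ (default 0.5, with the tie going
to P-MCI; the protocol states no threshold).

# Evaluation

`evaluateScores()` computes AUC by the rank (Mann–Whitney) formulation
with midrank tie correction — provably equal to the trapezoidal ROC
integral, which is recomputed as a cross-check — and accuracy,
sensitivity and specificity from the confusion matrix at $\tau$ with
P-MCI as the positive class.  `crossValidate()` runs repeated stratified
k-fold CV of the *entire* pipeline: subtyping, feature selection and
classifier are re-fit inside every training fold and test-fold patients
are subtyped by propagation, so no information crosses the fold
boundary.  Stratification is by conversion label (crossed with the true
subtype when one is recorded); the protocol does not state a
stratification scheme.  Subtype labels are arbitrary across folds; only
the pooled conversion scores are reported, so no cross-fold label
matching is needed.

`giniImportance()` interprets "mean decrease in Gini" with a bagged CART
ensemble (Gini split criterion, $\sqrt p$ features per node, bootstrap
resampling; defaults 500 trees × 10 repeats): the protocol never names
the model behind its importances, and no tree package is assumed at run
time, so a small in-package ensemble keeps the computation transparent.

# The synthetic cohort generator

`generateCohort()` states the world every downstream test measures
against: two latent subtypes drawn fairly, expressed **only** in the
genotype layer (allele-frequency shift ±0.15 at 30 of 100 SNPs) and the
expression layer (±1 SD at 30 of 100 genes) — matching the design in
which subtyping uses those two layers; conversion drawn per subtype at
rate 0.4 (three-year conversion frequencies in ADNI-like MCI cohorts run
around 35–40%); and conversion-informative features in *all three*
layers that are disjoint between subtypes and disjoint from the
subtype-informative sets, shifted by 1 SD in converters of that subtype
only (a volume *loss* for ROI features, matching atrophy).  Conversion
signal is injected as an additive shift after the label draw — not
through a logistic link — so per-feature effect sizes are exactly known
for recovery tests.  ROI volumes are
$\text{baseline}_j + \theta_j \cdot \text{ICV} + \text{shift} +
N(0, 0.5^2)$ mL with $\theta_j \sim U(0.002, 0.02)$ and
$\text{ICV} \sim N(1500, 150^2)$ mL, so the ICV confound and its known
slopes exercise the adjustment stage; 2% of genotype calls are masked
missing.  Cohort sizes default to 150 training + 100 test patients, the
order of the restricted clinical cohorts the method targets.  One global
seed drives per-stage substreams, and regeneration is bit-identical.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, probe-level microarray noise, correlated ROI atrophy patterns, or
covariate shift between cohorts.  A green recovery test therefore
establishes that the pipeline recovers planted structure of the stated
kind and magnitude — not that it attains any particular accuracy on
clinical data, which are access-restricted and outside what this package
can reproduce.

# Numerical choices

* Lasso: KKT tolerance $10^{-8}$ ($10^{-6}$ inside stability selection,
  where only the active set matters); the sweep tolerance is tightened
  until the independently recomputed KKT residual passes.
* Kernel systems carry a $10^{-8}$ jitter ridge.
* Gauss–Hermite nodes are computed by Golub–Welsch; 64 nodes keep the
  binary closed-form agreement below $10^{-6}$.
* k-means uses 25 restarts under a fixed seed; argmax ties resolve to
  the lower class index everywhere.
* Stratified splits use the largest-remainder rule, so an 80% split of
  125 samples is exactly 100/25 and five folds of 125 are exactly 25
  each.

# Limitations

The pipeline expects the three modalities used here and binary
conversion labels; survival-time modelling, probe-level normalization,
reference-panel genotype imputation, image segmentation and the
comparison baselines (logistic regression, SVM) are out of scope.
Subtype count is fixed by configuration rather than estimated.  Runtime
is dominated by the stability selection; the headline 1000 × 50
repetitions are practical but the package defaults in examples and tests
use reduced repetitions, stated where they occur.
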
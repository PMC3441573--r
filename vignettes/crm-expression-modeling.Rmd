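---
title: "Modeling gene expression from co-localized TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene expression from co-localized TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmx)
```

## The problem

Transcription factors (TFs) rarely act alone: ChIP-Seq experiments show
thousands of genomic regions where binding sites of several TFs co-localize.
When such a cluster sits in a gene's promoter it is a candidate
*cis-regulatory module* (CRM) — a region whose bound TFs may jointly control
the gene.  `crmx` asks a quantitative question about those modules: **how
well do the expression levels of the TFs bound in a gene's promoter CRM
predict the gene's own expression across cell types**, and how quickly does
that predictive power decay when the binding configuration differs between
cell types?

The package covers the full analysis path: CRM detection from per-TF peak
calls, promoter assignment, per-gene regression models, resampling-based
significance, cross-cell-line CRM comparison, and a synthetic-data generator
with known ground truth that makes every stage testable without any
external download.

## CRM detection

Each called peak is reduced to its center, `floor((start + end) / 2)`, in
0-based half-open (BED) coordinates.  Centers on one chromosome are sorted
and chained by single linkage: a gap of more than `max_gap` (default 500 bp,
a gap of exactly 500 bp still chains) starts a new group.  Groups containing
two or more *distinct* TFs become CRMs; repeated sites of one TF stay in the
site list but count once in the TF set.  The CRM's span is the min–max range
of its site positions and its center is the span midpoint — "center of a
CRM" has no canonical definition in the field, so the midpoint is our
choice, applied consistently everywhere.  A CRM is linked to a gene when its center lies
within `window` (default 1000 bp, inclusive) of the TSS; distances are
reported strand-oriented.

TF-combination enrichment uses a label-permutation null: the TF labels of
all CRM member sites are permuted genome-wide without replacement, which
preserves each CRM's site count and each TF's total site count.  Relabeled
groups that fall below two distinct TFs are dropped, mirroring the CRM
definition.  We chose the genome-wide scheme over independent per-CRM
resampling (available behind `per_crm = TRUE`) because it keeps the marginal
TF frequencies exactly fixed; p-values use the add-one estimator
`(1 + #{null >= obs}) / (1 + B)`, which cannot return 0.

## The expression model

For a gene $g$ with promoter CRM containing TFs $1..n$, the mean-centered
log expression $y_i$ in sample $i$ is modeled as

$$E(y_i) = \beta_0 + \sum_{j=1}^{n} s_j(x_{ij}) + \sum_{j<k} s_{jk}(x_{ij}, x_{ik})$$

where $x_{ij}$ is the mean-centered log expression of TF $j$ in sample $i$,
each $s_j$ is a penalized cubic regression spline, and the optional
$s_{jk}$ are bivariate tensor-product surfaces.  Because all profiles are
mean-centered and every smooth is centered over the training samples,
$\beta_0$ is 0 by construction.

Numerical choices:

* **Basis size.** `min(8, floor(n_samples / 3))` basis functions per
  univariate term; a 38-cell-type, 2-replicate panel therefore gets
  k = 8.  Below k = 3 the term degrades to a plain linear term.
  Interaction surfaces use a reduced 4×4 tensor basis.  These caps keep a
  model with up to four predictors identifiable on 38 cell types.
* **Smoothness selection.** Generalized cross-validation via
  `mgcv::magic()`, with `gamma = 1.4`.  Plain GCV is known to undersmooth
  at modest sample sizes (we observed ~8 effective degrees of freedom on
  purely linear truth); inflating the per-df cost by 1.4 is the standard
  mgcv remedy and restores near-linear fits on linear signal.  The fit is
  built on mgcv's constructor API (`smoothCon`/`magic`/`PredictMat`) and
  reproduces `gam(method = "GCV.Cp")` coefficients to numerical precision;
  the constructor route lets the null-model battery reuse per-TF bases
  across tens of thousands of refits.
* **Knots** are placed from the full panel's TF values.  Knot placement
  uses only predictor values — never the response — so sharing bases across
  CV folds and null replicates leaks no information about $y$.
* **Extrapolation.** Cubic regression splines extend linearly beyond the
  boundary knots; predictions outside the training range are flagged, and
  `clamp = TRUE` clamps predictors to the training range instead.
* **Degenerate inputs.** Constant predictors are dropped with a warning;
  fewer than 4 training samples is an error; if the penalized fit fails the
  model falls back to ordinary least squares on linear terms with a
  warning.

## Accuracy, cross-validation and replicates

Prediction accuracy is the squared Pearson correlation $R^2$ between
predicted and observed expression (not $1 - SS_{res}/SS_{tot}$; the two
differ when predictions are biased).  Five-fold cross-validation assigns
*cell types* — not samples — to folds, so biological replicates never
straddle the train/test boundary; leaking a replicate into training would
inflate $R^2$.  Fold $R^2$ values are averaged.  For the per-cell-type view,
every gene model is trained with one cell type held out; accuracy is then
the correlation *across genes* within the held-out cell type, computed per
replicate and averaged.

By default the smoothing parameters for a gene's model are selected once by
GCV on the full panel, and each CV fold refits only the coefficients at
those values (`sp_mode = "shared"`).  Hyperparameters are a property of the
predictor-response smoothness, not of a particular fold; reselecting them
per fold (`sp_mode = "per-fold"`) gives practically identical results at
five times the cost.  Because the observed model and all its null models
share identical folds and the identical protocol, paired comparisons are
unaffected by this choice.

## Null models and the bootstrap p-value

A high $R^2$ can reflect generic co-expression rather than the specific
CRM: many TFs correlate with many genes across a differentiation panel.
Each gene's observed accuracy is therefore compared against models with the
same *number* of predictors but resampled TF identities:

* **`pool14`** — predictors drawn uniformly without replacement from the
  assayed TF panel;
* **`motif41`** — predictors drawn from a wider candidate list, but a TF is
  eligible for a given gene only if it is expressed in the reference cell
  line *and* its binding motif is enriched near that gene's TSS (the motif
  table is an input; recomputing motif enrichment is out of scope).

With B replicates (default 1000; tests and the bundled studies use
100–200) the bootstrap p-value is the add-one tail fraction.  Null fits
reuse the observed model's fold assignment, removing fold-assignment
variance from the contrast, and repeated identical null TF sets within a
gene reuse the already-computed (deterministic) accuracy.  Draws may
coincide with the observed set — excluding them would bias p upward.

## Nonlinearity and interaction tests

Whether splines buy anything over straight lines is decided per gene by a
nested F-test; whether a TF pair interacts, by an F-test for an added
tensor-product block.  Three details matter for calibration:

* **Replicate averaging.**  Both tests run on cell-type mean expression.
  Replicates share their cell-type-level variation; treating them as
  independent observations overstated the residual degrees of freedom so
  badly that the nominal-0.01 test rejected 75% of purely linear genes.
* **Fixed-df alternatives.**  The tested spline terms are *unpenalized*:
  the nonlinearity test compares linear OLS against fixed-df regression
  splines (k = 5 per predictor, a classical exact F under the Gaussian
  null), and the interaction test adds an unpenalized $(k-1)^2 = 4$ df
  tensor block (k = 3 spans every bilinear surface, and leaves
  four-predictor CRMs testable on 38 cell types).  GCV-selected smooths
  adapt their effective degrees of freedom to the noise, and F-tests using
  those edf were measurably liberal — type-I 0.07–0.19 at nominal 0.01
  depending on the predictor count for nonlinearity, 0.06–0.07 for
  interactions (mgcv's term-wise test was equally liberal here).  With
  fixed-df alternatives the measured type-I error is ~0.01 and power
  remains high (1.0 against quadratic truth at low noise, ~0.9 against a
  planted multiplicative pair).
* **One pair at a time.**  Pairs are tested against the additive model
  individually, and the null-model battery then refits the model with the
  passing pairs as penalized tensor terms; jointly fitting all pairs of a
  4-TF CRM is not identifiable on 38 cell types.  Inside the battery the
  screen holds the main effects' smoothing at the full-panel values and
  works on replicate-averaged design rows, so one GCV selection per TF set
  serves both the screen and the cross-validated refits; the screen's
  calibration was verified separately (type-I 0.007).

## Comparing CRMs between cell lines

Two CRMs from different cell lines are *overlapping* when each span covers
strictly more than 50% of the other; a CRM overlapping several partners is
paired with the one of larger reciprocal overlap (ties to the smaller start
coordinate).  Binding dissimilarity is the Hamming distance (TFs in exactly
one of the two sets) and the Jaccard distance (Hamming over union size).
The permutation null for dissimilarity permutes labels genome-wide within
each cell line, exactly as in combination enrichment, and on enumerable
toys reproduces the hypergeometric law for the intersection size of random
subsets.

The dissimilarity-versus-transfer analysis trains, per overlapping pair,
one model on cell line A's TF set and one on cell line B's, predicts a
target cell type with both, and aggregates the MSPE ratio (B over A) in
Jaccard bins {0, (0, 0.3], (0.3, 0.5], (0.5, 0.8], (0.8, 1]} — bracketing
the 30/50/80% dissimilarity thresholds used in the source analyses.
DE-gene classification between two cell lines uses |mean log2 difference|
of replicate means ≥ 1 by default (the threshold is configurable; the
underlying studies do not state one).  TF co-occurrence clustering uses
1 − Jaccard similarity of each TF's CRM membership sets at DE-gene
promoters and average linkage (no linkage is stated upstream; average is
the usual choice for similarity-derived distances).

## The synthetic study

The generator emulates the statistical structure the analysis assumes, with
defaults mirroring the assayed design:

* 14 TFs, 38 cell types × 2 replicates (the hematopoietic panel shape);
* a 2 × 2 Mb genome with TSSs on a ≥5 kb grid; every gene's promoter
  receives a planted CRM of 2–4 distinct TFs (sites within 400 bp of an
  anchor inside ±600 bp of the TSS; peak widths even, 200–400 bp, so the
  peak center recovers the site exactly), plus background peaks at
  2×10⁻⁵ per bp per TF;
* TF expression standard normal per cell type, replicates adding N(0, 0.1)
  measurement noise (the replicate SD is deliberately not configurable, so
  the replicate-averaging code path is always exercised);
* half the genes are *regulated*: their expression is a sum of per-regulator
  response functions (linear, saturating `tanh`, sinusoidal, U-shaped)
  drawn per TF, 15% of multi-TF regulated genes adding a multiplicative
  pair on top of their main effects; the summed signal is standardized to
  unit variance before N(0, `noise_sigma` = 0.5) biological noise is added,
  so `noise_sigma` reads directly as inverse signal-to-noise.  The other
  half carry *non-functional binding*: a planted CRM but independent
  N(0, 1) expression — exactly the decoys the null battery must not flag;
* cell line B is derived from line A by adding/removing TFs per planted CRM
  to hit a target Jaccard distance (substitutions reuse vacated positions
  so spans stay aligned);
* the motif table marks every true (regulator, gene) pair as enriched plus
  random pairs at rate 0.3, and all panel TFs as expressed — consistent
  with, but noisier than, the ground truth, as a real motif scan would be.

What the generator does **not** emulate: correlated TF expression programs
(a correlation knob exists but calibration studies use the independent
setting), chromatin accessibility, distance-dependent regulatory strength
within the promoter window, distal enhancers, and measurement artifacts
such as probe saturation.  Passing the bundled studies therefore shows the
machinery is correct and calibrated under the stated generative model — not
that real regulatory networks satisfy that model.

## Problem sizes in the bundled studies

The validation studies shipped with the package use 200 genes per condition
(calibration, power, nonlinearity, interaction type-I), B = 200 null
replicates per gene at 38 cell types, ~50 genes per Jaccard level for the
transfer analysis, and B = 100–200 for permutation bands.  These sizes give
binomial standard errors of ~1.5 percentage points on the reported
fractions, which is tight enough to distinguish the calibrated from the
broken regimes we guard against.

## Known limitations

* The squared-correlation $R^2$ rewards any monotone association; a model
  can score well while being badly biased in level.  MSPE-based results are
  reported alongside for this reason.
* With ~7 cell types per held-out fold, the null expectation of a squared
  correlation is ~1/7, not 0 — per-gene accuracies must always be read
  against the null battery, never in absolute terms.
* Four-predictor CRMs with an interaction term sit at the identifiability
  edge on 38 cell types; such pairs are skipped (and logged) rather than
  fitted unstably.
* The permutation null for TF combinations conditions on the observed CRM
  site structure; it does not model peak-calling noise.
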
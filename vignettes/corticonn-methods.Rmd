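---
title: "Methods: cortico-subcortical connectivity analysis with multiple-kernel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortico-subcortical connectivity analysis with multiple-kernel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`corticonn` implements a complete resting-state fMRI analysis of
cortico-cerebellar and cortico-striatal functional circuits in multi-group
developmental cohorts (typically developing children, developmental
dyslexia, developmental coordination disorder, and their comorbid
combination — TYP, DD, DCD, COM).  The pipeline runs from motion quality
control through seed-to-voxel connectivity to two complementary group
analyses — a univariate voxelwise GLM and a multivariate sparse
multiple-kernel SVM — and a consensus map that intersects their evidence.

The unit of analysis is a per-subject, per-seed *Fisher-z map*: for each of
14 subcortical seeds (seven "cerebellar", seven "striatal", named after the
seven canonical large-scale networks: visual, somatomotor, dorsal
attention, ventral attention, limbic, frontoparietal, default-mode), the
Pearson correlation between the seed's mean denoised time course and every
gray-matter voxel, transformed by `z = atanh(r)`.

# Stages, parameters and defaults

## Motion QC and censoring

Framewise displacement (FD) is computed under three conventions:

* **Power**: sum of absolute backward differences of the six rigid-body
  parameters, rotations converted to mm on a 50 mm sphere.
* **Jenkinson**: `sqrt(R^2/5 * tr(A'A) + b'b)` with `[A|b]` the relative
  rigid transform between consecutive frames minus identity, `R` = 80 mm.
* **ART-style composite**: maximum Euclidean displacement over the eight
  corners of a head-sized bounding box (140 x 180 x 115 mm, configurable).
  The toolbox that popularised this composite does not publish a closed
  form; the max-corner-displacement definition preserves its
  single-number-vs-0.5 mm-threshold semantics and is documented here as
  this package's definition.

A frame is censored when FD exceeds **0.5 mm** (flagging variant: the
ART-style composite by default) or when the global mean intensity over the
brain mask deviates more than **3 SD** from the session mean.  `FD[1] = 0`
by convention (no predecessor), so the first frame is never FD-flagged.
Rotations in motion files are radians (SPM `rp_*.txt` convention); this
matters because every variant converts rotations to millimetres through a
radius.

## Denoising

Nuisance regression per voxel with: **5** principal components each from
the white-matter and CSF masks (aCompCor; the tissue masks are eroded by
one voxel as the partial-volume guard), the 6 motion parameters and their 6
backward-difference derivatives, one indicator column per censored frame,
an intercept and a linear drift.  Five components *per tissue* (10 total)
follows the common toolbox default; the count is configurable.  Linearly
dependent columns are dropped with a warning; a design in which every frame
is censored is an error.

Regression is followed by a **0.008–0.09 Hz** band-pass, implemented as a
discrete-Fourier mask over the *valid* frames only (treated as regularly
sampled at TR; the DC bin is removed).  Censored frames are excluded from
all later correlation sums rather than interpolated.  The two stages run
sequentially (regress, then filter) rather than simultaneously; for these
regressors the difference is second order.

Spatial smoothing uses a separable Gaussian with
`sigma = FWHM / (2 sqrt(2 log 2))` per axis (FWHM **8 mm** by default),
zero-padded at the grid boundary.  In the reference pipeline smoothing is
applied before denoising, mirroring the usual preprocessing order.

## Connectivity and GCOR

Correlations use valid frames only; `|r|` is clipped to `1 - 1e-7` before
`atanh` so self-seeded voxels stay finite (maximum z about 8.1).
Zero-variance voxels get `z = 0` and are logged.  GCOR — the average of all
pairwise voxel–voxel correlations including self-pairs — is computed in
closed form as the squared norm of the mean unit-norm voxel time series
(equivalent to the mean of the full correlation matrix, verified against it
in the tests) on denoised, band-passed gray-matter data, and is carried as
a *group-level* covariate rather than regressed from the time series.

## Group GLM

For each seed map, a voxelwise ANCOVA partial F tests the group factor
(reference level TYP; gender coded M = 1 — F-statistics are invariant to
both codings, fixed for reproducibility) given age, gender and GCOR.
Clusters form at voxelwise **p < 0.001** (18-connectivity; 6/26
configurable) and cluster extent is tested by **Freedman–Lane permutation**
of the covariate residuals: the null distribution of the maximum cluster
size gives `p_extent = (1 + #{perm max >= size})/(n_perm + 1)`.  The
original analysis used a parametric extent p from its toolbox, which is not
reproducible from published information; the permutation route is
assumption-free and testable, and the Benjamini–Hochberg step is applied to
cluster p-values exactly as in the reference procedure — within each map
(`p_fdr`), and pooling all clusters of the 14 seed maps into one family
(`p_fdr_adjusted`).  The pooling rule itself is not stated in the reference
analysis; pooling all cluster p-values was chosen as the most conservative
interpretable family, and both adjusted and unadjusted values are reported.
Designs admitting fewer distinct permutations than requested are enumerated
exhaustively.

Behavioural associations (M-ABC percentile; first principal component of
the four reading scores, sign-oriented so higher = better reading) are
tested by *bivariate* regression — no covariates — matching the stated
procedure.  Post hoc pairwise group contrasts are covariate-adjusted
t-tests reported as "later minus earlier" in TYP < DD < DCD < COM order,
so hyperconnectivity in DCD versus TYP appears as a positive t.

## Multiple-kernel SVM

One linear kernel per seed map (`K_m = X_m X_m'` over the gray mask).  Per
cross-validation fold, each kernel is mean-centred with training-set
statistics (applied consistently to held-out rows/columns) and scaled so
the training-block trace equals the training-set size; trace normalisation
was chosen over unit-diagonal normalisation as the more common default and
is configurable in principle through `center_normalize_kernel()`.

The MKL objective minimises the soft-margin SVM dual optimum over simplex
weights `d` (`d >= 0`, `sum d = 1`), whose gradient by Danskin's theorem is
`-S_m` with `S_m = 0.5 (a o y)' K_m (a o y)`.  Optimisation is reduced-
gradient descent with a backtracking line search that starts at the maximal
feasible step — accepting that step drives weights *exactly* to zero, which
is what makes the model sparse.  Convergence: relative simplex-optimality
gap `max_m S_m - d'S <= 1e-4 * d'S`, or weight update below `1e-5`.  The
inner problem for fixed `d` is a standard SVM dual solved by SMO
(maximal-violating-pair selection, KKT tolerance `1e-8`); `C = 1` by
default, the common toolbox default since no value is published.  The
implementation is compiled (Rcpp/Armadillo) because the permutation suites
run on the order of 1e5 fits; a single-kernel fit is verified against an
independent interior-point QP solver in the tests.

Class imbalance is handled by matched under-sampling: greedy nearest-age
pairing within MRI-center x gender strata, falling back to center-only and
then global strata for leftovers (with a warning), until the smaller class
is exhausted.  Ties break by roster order, so matching is deterministic.
Evaluation is leave-one-subject-per-class-out cross-validation; balanced
accuracy (mean of sensitivity and specificity, reported to 2 decimals) and
a rank-based AUC (midranks for ties) summarise the pooled held-out decision
values.  Significance uses **global label permutation**: "permutations of
the training labels" is ambiguous between per-fold and global relabelling;
the global scheme was adopted as the stricter null.  Folds are re-derived
from each permuted labelling by the same deterministic rule that yields
the observed folds (i-th positive subject with i-th negative subject in
roster order — which reproduces the matched pairs for the observed
labels), so observed and permuted labellings pass through an identical
labels-to-folds-to-CV procedure; keeping the folds fixed instead would let
permuted folds hold out same-class pairs, a structural asymmetry absent
from the observed labelling that biases the null downward.  The p-value
uses the add-one rule, so its lower bound is `1/(n_perm + 1)`.  Kernel contributions are across-fold
means of `100 d_m`; the expected ranking assigns, per fold, ascending ranks
1..14 (largest d = 14) with average ranks for ties and rank 0 pinned to
exactly-zero weights.

Mixture classes (e.g. DCD-COM) pool their labels *before* matching; the
mixture composition therefore follows from the matcher rather than being
imposed.

## Consensus

For an MKL model that performed above chance (`perm_p < 0.05`) and a seed
map whose GLM carries at least one FDR-significant cluster, the per-kernel
weight map is converted to z-scores (fold mean / fold SE, `SE` floored at
`1e-12`), both the z-map and the F-map are min-max rescaled to `[0, 1]`
over the analysis mask, thresholded at their own **95th percentile**
(linear-interpolation percentile), and intersected.  The z-map keeps its
*sign* before rescaling — that is the stated formula — so voxels pushing
the decision in the negative direction cannot survive a high percentile;
computing a separate consensus on `-z` would recover them, but the signed
convention is reproduced deliberately.  For this reason every binary model
is oriented with the *clinical* class as the positive class (+1): "true
positives" then reads as sensitivity to the disorder, and voxels whose
connectivity is elevated in the affected group carry positive weights —
the direction the signed consensus inspects.

# The synthetic cohort

No data accompany the reference analysis, so the package ships a generator
whose defaults define its study conditions: four groups, a desk-scale
3 mm grid (default 18 x 22 x 18 voxels) with block-shaped regions — 14
2x2x2 subcortical seed blocks, 14 3x3x3 cortical target blocks, 3-voxel
white-matter and CSF slabs — 150 volumes at TR 2.5 s, and 14 latent circuit
signals band-limited to 0.01–0.08 Hz so the 0.008–0.09 Hz analysis
band-pass preserves them.  Each circuit's latent signal is injected into
its seed and its cortical target with loading `coupling_base` (default
0.4), raised by `coupling_delta` (default +0.3) for DCD and COM subjects at
the two *affected* circuits: the somatomotor cortico-cerebellar circuit
(`cereb2`) and the frontoparietal cortico-striatal circuit (`stria6`) —
the hyperconnectivity pattern the analysis is meant to recover.  On top of
that: unit white noise, per-voxel linear drift, white-matter and CSF
confound signals leaking weakly (loadings 0.15 / 0.10) into gray matter, a
global component with per-subject amplitude (mean 0.3, SD
`global_signal_sd` = 0.1) to exercise the GCOR covariate, and motion traces
whose baseline Power FD stays below 0.2 mm with Poisson(`spike_rate` = 15)
step displacements that exceed 0.5 mm exactly at the planted frames.
The M-ABC percentile declines linearly in the mean affected-circuit loading
(about the 54th percentile at baseline loading, single digits for affected
children) with noise SD 8; the four reading scores share one latent ability
(pairwise r about 0.99, so PC1 explains about 99% of their variance),
lowered by 1.5 SD for DD and COM.

Determinism: each subject draws from an RNG stream derived from the master
seed, so cohorts regenerate bit-identically, with or without materialising
the runs in memory.

What the generator does **not** emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, scanner drift nonlinearity,
spatial autocorrelation beyond the block structure, motion-image coupling
(spikes live in the motion trace, not the images), and anatomical geometry.
Passing recovery tests therefore demonstrates that the *statistical
machinery* behaves as specified under its own assumptions — not that the
pipeline is robust to every artifact of real scanner data.

# Calibration and recovery suites: problem sizes

The package's calibration suites use reduced reference settings chosen
once: null cohorts of 4 x 15 subjects on a 15 x 18 x 12 grid with 80
volumes; 100 simulated null cohorts with 200 permutations for the
cluster-extent false-positive rate, processed with the reference 8 mm
smoothing — the max-cluster-size null needs the spatial correlation the
real analysis has, otherwise cluster sizes are tiny integers and the
permutation distribution is too discrete to reject at 5% at all; ANCOVA
p-value uniformity checked on unsmoothed cohorts (smoothing leaves the
marginal p distribution uniform but breaks the voxel independence a KS
test assumes); 200 resampled 12-vs-12 null classification problems (99
label permutations each) for the permutation test's rejection rate — 12
per class keeps the balanced-accuracy grid fine enough that ties at the
rejection threshold do not over-discretise the test; and 20
planted-effect cohorts of 4 x 20 subjects (coupling_delta 0.4, 100
volumes, 8 mm smoothing) for recovery.  The `scripts/acceptance.R` report
recomputes the same quantities at slightly smaller counts (30 null
cohorts, 100 null classification problems, 8 recovery cohorts).

Two behaviours of these suites are worth knowing.  First, leave-one-per-
class-out balanced accuracy is mildly pessimistic under the null (its mean
sits a few points below 50%) and over-dispersed relative to a binomial
count, because the folds share almost all their training subjects — both
well-known properties of leave-out estimators with balanced classes; the
permutation test is unaffected because observed and permuted labellings
share the full procedure.  Second, the within-map BH step over cluster
p-values makes the *map-level* false-positive rate conservative relative
to the nominal 5%: under the complete null BH controls (does not attain)
the error rate, and the permutation p-values are discrete, so the rate of
maps with any `p_fdr <= 0.05` sits below 5% by roughly the typical number
of clusters per map.

# Numerical choices and degenerate inputs

* Voxel flattening is column-major with x fastest everywhere; voxel
  indices are 1-based (R convention) throughout the package.
* `atanh` clipping at `|r| = 1 - 1e-7`; zero-variance voxels give z = 0.
* ANCOVA F is defined as 0 at voxels whose residual variance is
  numerically zero relative to their total variance.
* Kernels that are not PSD within round-off receive `1e-8` diagonal
  jitter with a warning; an all-zero kernel after centering is an error.
* The greedy matcher, rank ties, and cluster ordering all break ties by
  index order, keeping every stage deterministic for a fixed seed.
* A pipeline stage failure aborts the run with the stage name attached.

# Limitations

Desk-scale geometry cannot probe registration, atlas misalignment or
partial-volume effects at real anatomical boundaries; the permutation
cluster test assumes exchangeability of covariate residuals across
subjects (satisfied by construction in the generator); and the MKL
implementation covers linear kernels and one-vs-one binarisation only,
which is all the reference analysis requires.
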
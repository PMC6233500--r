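---
title: "Sparse-representation texture radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-representation texture radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtexture)
```

## The model

srtexture classifies square regions of interest (ROIs) from multi-modal
ultrasound images — grayscale B-mode plus pseudo-color stiffness/viscosity
maps — by how well class-specific texture dictionaries explain them. The
pipeline has four stages.

**1. Per-class dictionary learning.** ROIs are tiled into $p \times p$
patches (default $p = 8$), vectorized, and mean-removed; the per-patch mean
(brightness) is deliberately discarded because texture, not intensity, is the
discriminative signal. For each class $c$ and each coding channel, KSVD
learns an overcomplete dictionary $D_c \in \mathbb{R}^{p^2 \times K}$
(default $K = 256$, so each dictionary is $64 \times 256$) by alternating
two steps: (i) sparse-code all patches with orthogonal matching pursuit (OMP)
at a fixed sparsity $T$, and (ii) for each atom in turn, form the residual
matrix restricted to the patches using that atom, with the atom's own
contribution restored, and replace atom and coefficients by the leading
rank-1 SVD pair. The initial dictionary is the standard overcomplete 2-D DCT
(sampled cosines, non-DC atoms mean-removed, columns unit-normalized).

**2. Feature extraction against a FED.** The trained class dictionaries of a
channel are concatenated, class 0 block first, into a *feature extraction
dictionary* (FED) $F = [D_0\; D_1]$. Every ROI patch is OMP-coded against
$F$, and the per-case feature for atom $j$ is the mean absolute coefficient
over the ROI's patches. A patch drawn from class $c$ tends to load its
coefficient mass on the $D_c$ block, so the distribution of pooled
coefficients across the two blocks is the discriminative feature. Grayscale
modalities are coded directly; pseudo-color modalities are first converted
RGB → HSV and their hue and value channels coded separately (saturation is
discarded). With two classes and 256 atoms this yields $2 \times 256 = 512$
features for grayscale, $1024$ for one pseudo-color modality (two channels),
$1536$ for grayscale + one pseudo-color, and $2560$ for grayscale + two.

**3. Iterative sparse-representation feature selection.** The case labels
$y \in \{-1, +1\}^n$ are sparsely regressed on the column-standardized
feature matrix with OMP over feature columns; the absolute regression weight
is a feature's importance. To stabilize the importances at small $n$, the
regression is repeated on class-stratified subsamples (default: 50
iterations at fraction 0.8) and the absolute weights averaged. Features are
ranked by the averaged score (ties to the lower index) and the top
$k$ retained.

**4. Class-weighted SVM with leave-one-out evaluation.** A soft-margin SVM
on the selected, training-standardized features; with balanced weighting
each class's penalty is $C_c = C \cdot n / (2 n_c)$, which removes the bias
a skewed benign/malignant ratio induces on the margin. Performance is
estimated by leave-one-out cross-validation (LOOCV): accuracy, sensitivity
and specificity at decision threshold 0, AUC by the Mann–Whitney
pair-counting identity (tied scores count ½), a stratified case-resampling
bootstrap percentile interval for the AUC, and a Mann–Whitney U screen for
per-feature discriminative power (exact, tie-aware enumeration up to 12
observations, tie-corrected normal approximation beyond).

## Leakage control

`loocv_evaluate()` defaults to `refit_per_fold = TRUE`: dictionaries, FEDs,
feature pooling, feature selection, standardization and the SVM are all
refit on each fold's $n-1$ training cases, and the held-out case is coded
against the fold's own FEDs. This is the honest protocol — with
high-dimensional features and aggressive selection, selecting features on
all cases before LOOCV inflates the AUC substantially (the test suite
demonstrates the inflation on label-permuted data). The permissive variant
(`refit_per_fold = FALSE`: dictionaries, features and selection fit once on
all cases, SVM refit per fold) is retained for comparison and is recorded in
the report fingerprint so the two are never conflated. A consequence worth
stating: published results that did not refit inside folds are not
comparable to this package's defaults even on identical data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `patch_edge` | 8 px | patch edge; patches are 64-vectors |
| `n_atoms` | 256 | atoms per class dictionary (64 × 256 dictionaries) |
| `omp_sparsity` | 5 | OMP atoms per patch, shared by training and extraction |
| `ksvd_iters` | 30 | KSVD iterations (early stop at RMSE improvement < 1e-5) |
| `stride` | `patch_edge` | patch grid stride; non-overlapping by default |
| `pooling` | mean | mean or max of absolute coefficients over patches |
| `selection$n_iterations` | 50 | subsampled selection repetitions |
| `selection$subsample_fraction` | 0.8 | per-class fraction drawn per repetition |
| `selection$solver` | omp | `omp` (cardinality) or `lasso` (glmnet path point) |
| `selection$k_select` | auto | retained features; auto = min(n − 1, 30) |
| `svm$kernel`, `svm$C` | linear, 1 | RBF with median-heuristic bandwidth optional |
| `svm$weighting` | balanced | per-class penalty `C n / (2 n_c)` or none |
| `cv$refit_per_fold` | TRUE | leakage-safe LOOCV protocol |
| `cv$n_boot`, `cv$ci_level` | 2000, 0.95 | bootstrap AUC interval |

The OMP sparsity during training and extraction, the iteration count, the
subsample fraction and `k_select` are implementer defaults, not quantities
with a canonical value: they are exposed in `pipeline_config()` and recorded
in every report's configuration fingerprint. `k_select`'s automatic value
keeps the SVM well-posed at LOOCV sample sizes (tens of cases); the
selection solver's cardinality bound (`solver_sparsity`, default 10) is
additionally capped at $n-1$ so the regression never saturates.

## Numerical choices

* **OMP** selects the atom with maximal absolute correlation with the
  residual, refits all selected coefficients by SVD-based least squares on
  the original signal at every step (stable even when near-duplicate atoms
  enter the active set), and stops at the sparsity bound or at residual norm
  $< 10^{-10}$. Exact correlation ties resolve to the lowest atom index, so
  codes are platform-reproducible.
* **KSVD** is kept monotone by construction: after each atom sweep the
  patches are recoded, but a patch keeps its previous (still valid) code when
  that code has the smaller residual — greedy recoding alone does not
  guarantee improvement. Unused atoms, atoms active on fewer than `use_min`
  patches (default: a third of the expected usage $nT/K$), and near-duplicate
  atoms (coherence > 0.99) are replaced by the worst-represented patch;
  the cleanup is accepted only if it does not increase the training RMSE.
  Every updated atom's sign is normalized (first nonzero entry nonnegative),
  and dead-atom ties break at the lowest patch index, so training is fully
  deterministic — `seed` arguments exist for interface stability only.
* **Hue** is treated as a plain scalar channel in $[0,1]$ with the
  achromatic convention hue = 0; its circularity is ignored (a documented
  limitation — red hues near 0 and near 1 are treated as distant).
* **Decision threshold** for ACC/SENS/SPEC is a score of exactly 0, ties to
  class 0; ROC and AUC use the continuous scores. At LOOCV sample sizes a
  boundary case can land on the wrong side of 0 even when the score ranking
  is perfect, so accuracy can be slightly below an AUC of 1.
* **Standardization** always uses training-fold statistics; constant columns
  are set to exact zero rather than dividing by a vanishing scale.
* **Config fingerprints** are MD5 digests of the canonical JSON form of the
  configuration, stamped into reports so runs are auditable.

## The synthetic generator

No patient images are distributed with studies of this kind, so the package
ships a seeded generator that emulates exactly the structure the pipeline
assumes: each class has a bank of nonnegative, unit-norm smooth atoms
(Gaussian noise smoothed with a class-dependent oriented kernel — horizontal
streaks for class 0, vertical for class 1), and each ROI tile is a
`gen_sparsity`-sparse nonnegative combination of its class's atoms plus
Gaussian noise, clipped to $[0,1]$ and quantized to the 8-bit grid.
Pseudo-color modalities are rendered through a fixed blue-to-red colormap
($R = t$, $G = 0.15 + 0.35t$, $B = 0.3 + 0.2t$) whose HSV value channel is
strictly increasing in the underlying intensity, so value-channel coding
sees a monotone transform of the texture. Backgrounds are uniform noise
(the pipeline reads only ROIs), background and ROI-position draws are
label-independent (same seed ⇒ same background, different label ⇒ different
ROI texture), and per-case seeds derive from the master seed and case id by
a stable polynomial hash, so datasets reproduce byte for byte. ROI edge
defaults to 64 px — a choice, there being no canonical pixel size.

Two knobs matter for testing: `noise_sigma` (0 gives exactly sparse,
noise-free ROIs whose generating supports are retained in a debug attribute)
and `disjoint_support` (class atoms restricted to opposite patch halves,
making classes perfectly separable — LOOCV AUC 1.0 downstream).

What the generator does **not** emulate: acoustic speckle statistics,
shear-wave propagation physics, propagation-quality maps, anatomical
context, scanner or operator variability, or correlated pathology across
modalities (each modality's texture is drawn independently from the class
model). Passing tests therefore demonstrate that the pipeline's machinery —
dictionary learning, coding, pooling, selection, weighted classification,
honest cross-validation — behaves as specified on data satisfying its own
assumptions; they do not certify clinical performance on real ultrasound.

## Problem sizes

The test and acceptance runs use desk-scale instances chosen to exercise
every code path at full fidelity: 64-atom dictionaries on 32-px ROIs for the
end-to-end LOOCV properties (about 300 training patches per class per fold),
the full 64 × 256 dictionary geometry for the architectural worked examples
and the KSVD recovery study (2,560 exactly 3-sparse patches), 500
low-coherence instances for the OMP-vs-exhaustive-search equivalence, and a
200-feature, 60-case planted design for selection recovery. These sizes are
the package's own choices for routine verification; all of them scale up by
configuration only.

## Known limitations

* Two classes only; the FED layout and metrics assume a binary task.
* Hue circularity ignored (above).
* The exact Mann–Whitney branch enumerates label assignments and is capped
  at 12 observations; beyond that the tie-corrected normal approximation is
  used.
* KSVD trains each class independently; no discriminative or online
  dictionary-learning variants.
* The bootstrap interval is a percentile interval; no BCa correction.
* With fewer training patches than atoms the dictionary is underdetermined;
  the package warns and proceeds (the cleanup step keeps atoms tied to
  actual patches), but dictionaries trained this way inherit sampling noise.
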
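---
title: "Methods: synthetic cohorts, radiomics and chemometrics in fibroscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, radiomics and chemometrics in fibroscar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`fibroscar` implements a two-branch analysis of fibrotic cardiac tissue:

1. **MPM branch.** Two-channel multiphoton planes — second harmonic
   generation (SHG, dominated by fibrillar collagen) and two-photon excited
   fluorescence (TPEF, cardiomyocyte autofluorescence) — are preprocessed,
   masked, summarised by 152 IBSI-conform radiomic features per channel
   (304 per plane), and classified healthy versus pathologic by a
   heterogeneous committee trained over unique Monte-Carlo folds with mRMR
   feature ranking and SMOTE balancing.
2. **Raman branch.** Microspectra are despiked, baseline-corrected,
   smoothed and vector-normalized, then classified into muscle, necrotic,
   granulated and fibrotic tissue by PLS-DA (NIPALS PLS2 on mean-centered
   one-hot class indicators).

Because the underlying ovine tissue data are not deposited anywhere, the
package ships a seeded synthetic-data generator for both modalities. The
generator is first-class, tested code: its defaults *are* the study
conditions, and all pipeline-level performance claims in the test suite
refer to these synthetic cohorts, not to real tissue.

## The synthetic MPM generator

Each plane is rendered as a set of fibers: bounded random walks with unit
steps whose initial orientation is drawn from a von-Mises-like
concentrated distribution around a per-plane dominant tissue angle
(concentration parameter `orientation_concentration`) and whose per-step
turning angle is Gaussian with standard deviation `curliness`. Polylines
are splatted at one-pixel width and widened by a Gaussian blur of
`fiber_width_px / 2`, after which channel noise is added and a Gaussian
point-spread blur (`psf_sigma_px`) applied. The TPEF channel uses the
same mechanism with three-fold wider fibers (myocyte laminae) sharing
the plane's dominant orientation, plus a diffuse autofluorescence floor.

The per-class defaults (`default_fiber_params()`) encode infarct
maturation: SHG fiber counts 8 / 30 / 60 / 90 and SHG intensity scales
0.30 / 0.60 / 0.80 / 1.00 for healthy / necrotic / granulated / fibrotic
(sparse thin aligned fibers to a dense intertwined mesh), TPEF intensity
scales 1.00 / 0.70 / 0.45 / 0.25 (bright aligned laminae to dim sparse
remnants), orientation concentration 8 / 2 / 0.5 / 0.3 and curliness
0.05 / 0.25 / 0.35 / 0.40. Two orderings are enforced as invariants:
SHG fiber density healthy < necrotic < granulated <= fibrotic, and TPEF
intensity healthy > granulated > fibrotic.

The default cohorts reproduce the study design: 184 training/validation
planes (56 healthy + 128 pathologic, the latter split 43 / 43 / 42 across
necrotic / granulated / fibrotic — the pathologic split is not specified
by the design, so an even split is used) over 3 ROIs, and 378 test planes
(94 / 95 / 95 / 94) over 6 ROIs. Planes are assigned round-robin to ROIs
and uniformly in depth, as no per-ROI counts or depth spacing are part of
the design. The default image size is 256 x 256 pixels, a desk-scale
proxy for the microscope fields of view; physical pixel pitch is not
modeled.

What the generator does **not** emulate: optical physics (no coherent
SHG phase matching, no depth attenuation), vascular or histological
microanatomy, inter-sample biological variability beyond the per-plane
orientation and per-fiber intensity jitter, and imaging artifacts other
than additive Gaussian noise. Passing the pipeline tests on these
cohorts therefore demonstrates correctness and internal consistency of
the analysis machinery, not clinical performance on real tissue.

## Preprocessing and masking

Channels are mean-binned (`bin_factor`, default 1 at 256 x 256) and
normalized per plane (min-max to [0, 1] by default; the method is a
config choice, not a study constraint). Foreground masks are computed
per channel with Otsu's threshold, cleaned by a morphological opening of
radius 1 px (just enough to suppress single-pixel speckle), and combined
with a logical OR — collagen-only and myocyte-only regions both enter
feature extraction. A fixed-threshold path models manually thresholded
masks; a config switch (`use_mask`) selects per-channel masks to
reproduce the masking-comparison experiment.

## Radiomic features

The registry (`default_feature_registry()`) defines 152 features per
channel with IBSI definitions: local intensity (2), intensity statistics
(18), intensity histogram (23), GLCM (25), GLRLM (16), GLSZM (16),
GLDZM (16), NGTDM (5), NGLDM (17), and 2D mask morphology (14). The
published engine's exact roster is not enumerated anywhere, so this
composition is count-compatible by construction and versioned in the
registry.

Numerical choices:

* Discretization is fixed-bin-number with `N_g = 32` per channel within
  the mask (IBSI-recommended for arbitrary-unit intensities); a constant
  region maps to level 1.
* Texture matrices are computed per direction (0, 45, 90, 135 degrees)
  and merged by summation before feature computation; all neighborhood
  statistics respect the mask (out-of-mask pixels break runs and are
  excluded from neighborhoods).
* NGLDM uses dependence count `j = 1 +` similar neighbors, coarseness
  tolerance `alpha = 0`, Chebyshev radius 1.
* Zones (GLSZM/GLDZM) are 8-connected; GLDZM distances are city-block
  distances to the mask edge with border pixels at distance 1.
* The local intensity peak uses a 5 px disc radius (the radiology
  1 cm^3 convention has no microscopy analogue; the radius is
  configurable), with intensity ties broken at the smallest row-major
  index.
* NGTDM strength divides by `eps + sum(s_i)` with `eps = 1e-12`, so a
  single-level image scores 0.

Every texture feature is verified against independent brute-force
oracles (explicit per-pixel loops) on random fixtures up to 10 x 10 to
within 1e-10, and all direction-aggregated features are checked to be
invariant under 90-degree rotation.

## Classification of MPM planes

Per Monte-Carlo fold: mRMR ranks the 304 features on the fold's
*training rows only* (mutual information on 4-quantile discretized
features — deterministic and scale-free; ties broken by column order),
the top `d = 9` features are retained, SMOTE balances the training rows
(each synthetic sample interpolates a minority row toward one of its 5
nearest minority neighbors), and four classifier families are fitted on
standardized features: ridge-regularized logistic regression, a random
forest, k-nearest neighbors (k = 5) and an RBF-kernel SVM with
probability calibration. Feature selection and SMOTE never see
validation rows; a construction test corrupts all validation rows and
asserts the fitted ensemble is unchanged.

`d = 9` is retained as the design's own choice even though the
`d ~ sqrt(n)` guidance would suggest about 13 at n = 184; the guidance
is surfaced as a message, never enforced. Validation sets draw
`round(0.2 x minority size)` planes *per class* (11 + 11 at 56/128), so
validation is always balanced; fold validation sets are pairwise
distinct by construction. The number of folds (20), the classifier
identities and the SMOTE parameterization are not fixed by the study
description; the defaults here are the package's choices and are all
config surface.

At test time every classifier from every fold votes; the plane's class
is the majority vote and its score is the mean pathologic probability
over all classifiers (the per-plane mean rho). A tied vote resolves
pathologic iff rho >= 0.5.

## Raman preprocessing and PLS-DA

The spectral preprocessing chain (despike by median-filter residual
z-score > 8; asymmetric-least-squares baseline with lambda = 1e5,
p = 0.01; Savitzky-Golay smoothing, window 7, order 2; unit-norm
vector normalization) is unreported in the study description; this
order with conservative defaults is the standard chemometric choice and
every step is switchable. All filters operate per contiguous axis
segment, so nothing bleeds across the omitted silent region between the
fingerprint (600-1800 cm-1) and CH-stretch (2700-3100 cm-1) windows,
which are sampled at 2 cm-1.

The synthetic spectra are sums of Lorentzian bands at 728, 750, 869,
937, 1260, 1302, 1338, 1446, 1650, 2880 and 2920 cm-1 plus a 3rd-order
polynomial baseline with small random coefficients (an autofluorescence
stand-in), a 10% per-band multiplicative amplitude jitter emulating
tissue heterogeneity, and Gaussian noise. Collagen-associated band
amplitudes are non-decreasing along muscle, necrotic, granulated,
fibrotic; the CH-stretch bands decrease along that order; amide I
(1650 cm-1) has the largest inter-class range, reflecting its link to
collagen fiber packing. These orderings are enforced invariants of the
band model. Within those constraints the default table stages the bands
differently — amide III rises early in maturation, the backbone C-C
modes late, and the cytochrome band (tracking mitochondrial content,
not collagen) varies non-monotonically — so the four classes occupy a
genuinely multi-dimensional signature space. A band model in which
every band moves along a single common fibrosis axis makes the two
middle classes nearly indistinguishable to PLS-DA's
argmax-of-indicator-regression rule (the known middle-class squeeze for
ordinal classes), regardless of how far apart the class means are.

PLS-DA is fitted with NIPALS PLS2 (k = 4 latent variables by default,
one per class; LV1/LV2 are used for visualization). Each LV is
sign-normalized so the largest-magnitude element of its X-loading is
positive. The NIPALS convergence tolerance is 1e-24 on the squared
weight-vector change (capped at 1000 iterations), tight enough that
components agree with an eigendecomposition-based PLS oracle to 1e-8.
Prediction is the argmax of the indicator regression `(x - mean) B +
y_mean`, ties toward the first class in the canonical order muscle,
necrotic, granulated, fibrotic. The evaluation protocol for the
multiclass figures is not stated in the study description;
leave-one-out cross-validation is the default harness, and the overall
sensitivity/specificity are unweighted macro averages (the pooled
alternative is not used). The scrambled-label null check compares the
mean over several independent permutations to the chance level, because
a single permutation's leave-one-out sensitivity fluctuates widely and
sits slightly below chance (the well-known anti-learning bias of
leave-one-out under permuted labels).

## Pipeline, seeding and determinism

`run_pipeline()` drives both branches from a single validated YAML/list
config and one root seed, fanned out deterministically to stages and
items (a linear congruence kept inside the 32-bit integer range), so
identical config + seed reproduce identical metrics bit for bit. The
pipeline-determinism test runs a reduced cohort configuration:
determinism is a property of the seeding scheme, not of cohort size,
and the reduced run keeps the suite fast. Problem sizes used by the
test suite: the full default cohorts (184 + 378 planes at 256 x 256,
20 folds) for the parameter-recovery checks, 40 spectra per class for
the Raman checks, and 200 random fixtures up to 10 x 10 for the oracle
equivalence checks.

## Known limitations

* The 152-feature registry is count-compatible with, but not provably
  identical to, the unpublished roster of the original feature engine.
* The synthetic generator's class contrasts are deliberately strong;
  near-ceiling classification metrics on these cohorts are a
  recovery check, not an external validity claim.
* mRMR with an exact duplicate of the label is degenerate: every
  candidate's relevance equals its redundancy, all greedy scores tie at
  zero and the column-order tie-break decides (see the test suite).
* 3D/volumetric features, wavelet features, optical-physics simulation
  and cross-instrument harmonization are out of scope.
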
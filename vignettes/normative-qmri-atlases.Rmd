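---
title: "Normative quantitative-MRI atlases: models, choices and limits"
author: "qmriAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative quantitative-MRI atlases: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem the package addresses

Quantitative MRI maps physical tissue parameters — the relaxation rates R1
and R2 (1/s), the proton density PD (% of pure water) and, through a
multi-compartment model, the myelin volume fraction MVF (%) — instead of
arbitrary contrast. To decide whether a single patient's values are
abnormal, they must be compared against a normative reference: voxel-wise
mean and standard-deviation atlases built from a healthy cohort in a common
template space, plus per-region reference ranges. `qmriAtlas` implements
that workflow end to end and, because raw patient data of such studies are
not redistributable, ships a parcellated digital brain phantom so that every
step can be validated against known ground truth.

The pipeline has a fixed stage order, mirroring standard practice:
bias-field correction, co-registration, degree-4 B-spline reslicing to an
isotropic grid (1.5 mm by default), normalization to template space,
voxel-wise averaging into mean/SD atlases, region-of-interest (ROI)
reference ranges at mean ± 3 SD, and single-subject difference and z-score
maps. The orchestrator (`runPipeline()`) rejects any reordering.

## The digital phantom and what it emulates

`makeLabelPhantom()` builds a deterministic, brain-like labelled volume:
an ellipsoidal intracranial space with a subarachnoid CSF rim, a cortical
grey-matter ribbon split into four bilateral regions, ventricular CSF,
six deep grey nuclei (thalamus, putamen, pallidum; left/right) and a
white-matter interior parcellated into twelve named regions plus a
catch-all. Each named region carries a probabilistic map — its indicator
smoothed with a small Gaussian, emulating a probabilistic anatomical atlas —
capped at 0.5 outside the generating region so the strict 50 % threshold
can never include neighbouring tissue. The default grid is 48³ voxels at
3 mm: large enough to host all tissues with realistic proportions (healthy
brain parenchymal fraction ≈ 85 %), small enough that a 58-subject cohort
simulates in seconds.

Tissue ground truth (`defaultTissueTable()`) is constructed as fast-exchange
mixtures of the four compartment constants (myelin, cellular, free water,
excess parenchymal water), so the MVF solver is consistent with the phantom
by construction. Iron-rich deep grey nuclei add an R1/R2 offset emulating
paramagnetic shortening — deliberately off the compartment manifold, which
is why the solver flags them. The values land in physiological bands:
white-matter MVF 14.5–28.5 %, PD 66–77 %, R1 1.1–1.7 1/s, R2 10.8–13.5 1/s,
a pallidum with MVF > 15 %, R1 > 1.3 1/s, R2 > 14 1/s and PD < 74 %, and an
insular cortex with the lowest MVF/R1/R2 and highest PD.

Inter-subject variability is a per-tissue, per-parameter lognormal
multiplicative factor with unit mean. Its coefficients of variation are the
cohort-level CVs observed in such reference populations (white matter:
9.1 % MVF, 3.9 % PD, 6.6 % R1, 4.4 % R2; grey matter: 23.1 % MVF, 3.2 % PD,
7.2 % R1, 6.2 % R2). Additive Gaussian voxel noise (default ≈ 2 % of
typical white-matter values) is applied inside the intracranial space;
negative R1/R2 are clipped to a small floor and counted in a QC log. Ages
are sampled from the decade histogram 18/21/10/9 over 20–62 years, which
reproduces a 41/17-like split at the 40/41-year boundary in expectation.

Subjects are generated in template space; when a deformation amplitude is
configured, a smooth random displacement field plus a small random
translation is applied outward and recorded, so that registration can be
tested against the known inverse. MS-like subjects receive (i) diffuse
normal-appearing-white-matter multipliers (defaults MVF × 0.60, PD × 1.05,
R1 × 0.90, R2 × 0.93 — chosen so the white-matter MVF effect exceeds three
cohort SDs while PD/R1/R2 stay near their range edges), (ii) atrophy
modelled as white-matter loss nearest to CSF first (periventricular
dominant), which lowers the brain parenchymal fraction without touching
grey-matter ROI composition, and (iii) focal spherical lesions inside
white matter (MVF × 0.5, PD × 1.1, R1 × 0.8, R2 × 0.8 within each sphere).

What the generator does **not** emulate: cortical folding and real
neuroanatomy, scanner bias fields (the bias-correction stage is validated
against synthetic fields instead), spatially correlated noise, partial
volume at acquisition resolution, and multi-exponential relaxation. Passing
tests therefore demonstrate the correctness of the statistical machinery
and the spatial pipeline on known ground truth — not the fidelity of any
particular scanner or anatomy.

## The simplified MDME signal model

The multi-dynamic multi-echo acquisition is reduced to an exactly
invertible saturation-recovery spin-echo model,
`S(t, TE) = B1 · PD · (1 − exp(−R1 t)) · exp(−R2 TE)`, with the default
timing TR 6930 ms, TE 23/102 ms and a synthetic delay set
{200, 600, 2000, 6900} ms (the interleaved 2-D slice timing of the real
sequence is not exposed per voxel). R2 comes from the two echoes in closed
form; R1 and the amplitude from a profiled golden-section least-squares fit
over the delays; PD by undoing the TE1 decay and optionally anchoring a CSF
voxel at 100 % (the anchor choice is a design decision — which internal
water standard commercial packages use is not public). Monoexponential
decay is assumed throughout. B1 is a single multiplicative scale
(default 1).

The myelin solver is a fast-exchange linear-mixing surrogate for the
proprietary four-compartment model: observed (R1, R2, PD) are modelled as
fraction-weighted averages of fixed compartment constants, and the
non-negative, sum-to-one fractions minimising the scaled squared mismatch
are found exactly by enumerating all 15 active-support candidates of the
equality-constrained least-squares problem. Off-manifold voxels receive the
nearest feasible solution and are flagged. The default constants are
calibrated so white-matter mixtures span the physiological MVF band; they
are configurable because the true constants and exchange rates are not
published.

## Spatial pipeline choices

* **Reslicing** uses degree-4 B-spline interpolation with Unser's recursive
  prefilter and whole-sample mirror boundaries (degrees 0–5 available;
  0 for labels and masks). Polynomial reproduction in the interior is exact
  to well below 1e-6; the mirror transient decays like |z|^d with
  z ≈ −0.36, so "interior" in tests means at least ~15 voxels from a
  boundary for 1e-6 accuracy.
* **Bias correction** estimates a smooth multiplicative field by
  normalised-convolution Gaussian smoothing of the log intensities inside
  the brain mask (kernel FWHM = 1/3 of the brain extent by default) and
  preserves the in-mask mean. It corrects fields whose spatial scale is
  larger than the kernel; this stand-in is validated against synthetic
  fields.
* **Registration** has two modes. "known" replays the inverse of the
  recorded generator transform (displacement fields are inverted by
  fixed-point iteration); "affine-estimate" finds the integer translation
  by FFT cross-correlation and refines translation plus global scale by
  Nelder-Mead on the normalised cross-correlation. Full diffeomorphic
  registration is out of scope: registration quality is not this package's
  contribution, and correctness is tested via ground truth (noise-free
  round trips re-enter template space with <1 % of tissue contrast error
  away from boundaries — "away" meaning beyond the combined ±2.5-voxel
  support of the two interpolation passes — and label Dice > 0.95).
* **Normalization contract**: the transform is estimated from the
  T1-weighted contrast only and the identical transform object is applied
  to all four parameter maps (`applySubjectTransform()`).

## Atlas, reference ranges and deviation maps

Atlases store the voxel-wise mean and the **sample** SD (n − 1); the
printed per-subject summaries of reference cohorts round-trip only with the
n − 1 convention (e.g. an age SD of 7.4 for ages {28, 24, 34, 41}), which
settles the otherwise unstated choice. Zero-SD voxels are retained; z maps
divide by `max(SD, floor)` with the floor defaulting to the 1st percentile
of the in-mask SD, and floored voxels are counted.

ROI statistics are computed across per-subject ROI means (not pooled
voxels). The probability threshold is strict (> 0.5), boundary values
exactly on a ± 3 SD limit classify as "within" (closed interval), cortical
ROI pairs are averaged over both hemispheres, and white-matter tract ROIs
are kept per side. Difference maps use the atlas-minus-subject order, so
tissue loss is positive, and PD difference maps report absolute values;
z maps keep the same sign convention (a `flip` switch restores the common
subject-minus-mean convention). Global metrics normalise by intracranial
volume: BPF = 100 · parenchyma / ICV and the global myelin volume
100 · Σ(MVF/100 · voxel volume) / ICV.

Because the subject factors are lognormal, the ± 3 SD rule's exceedance
fraction on held-out healthy subjects sits slightly above the Gaussian
0.27 % (most visibly for grey-matter MVF, CV 23 %); the acceptance
experiment sizes (12 held-out subjects × 88 ROI-parameter combinations)
keep the binomial check meaningful without making this mild skew dominate.

## Validation statistics

Group comparisons use the two-sided Mann-Whitney U test at alpha = 0.01:
exact enumeration when min(n1, n2) ≤ 8 and the data are tie-free, the
tie-corrected normal approximation otherwise (the cutoff and tie handling
are design decisions; the exact branch is verified against exhaustive
permutation enumeration up to samples of 6 and 6). Age correlations are
Pearson, corrected per parameter family with Bonferroni by default
(Benjamini-Hochberg optional) — the correction method and family are design
decisions, configurable. Spatial agreement is quantified by the in-mask
Pearson cross-correlation of two images (`fslcc` semantics, not Lin's
concordance), banded as weak < 0.40 ≤ moderate < 0.70 ≤ strong. Template
tissue segmentation is intensity-only: k-means seeded at the 10th/50th/90th
percentiles, refined by a univariate Gaussian mixture (`mclust`), classes
labelled by ascending mean (CSF < GM < WM on T1w).

## Problem sizes and numerical choices

Tests and the acceptance script use the 48³ × 3 mm phantom, 58-subject
atlas cohorts, 12 held-out subjects, four-subject testing groups, 300-voxel
round-trip checks and 10⁴-voxel noise-bias checks; the replay-accuracy
check uses a 64³ grid so that homogeneous cores deeper than the combined
interpolation support exist. These are design choices balancing statistical
power against desk-scale runtimes. Randomness is funnelled through one root
seed with per-stage derived streams (FNV-hash based), so a fixed seed makes
cohorts bit-identical. Degenerate inputs are handled explicitly: empty
masks warn and record missing values, all-tied rank tests return p = 1 and
are flagged, zero-variance correlations are flagged, non-positive
amplitudes in the MDME fit are flagged, and grids smaller than 32³ are
rejected by the phantom.

## Known limitations

The compartment constants are surrogates, so absolute MVF values should be
read as model-consistent rather than scanner-comparable. The affine
registration estimator handles translation and global scale only. The
phantom's regular geometry makes ROI masks purer than real probabilistic
atlases, so real-data misclassification effects are under-represented.
Results at other field strengths, in elderly populations, or under
multi-exponential relaxation are outside the validated envelope.
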
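---
title: "Segmented-UTE attenuation correction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented-UTE attenuation correction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(suteac)
```

## The problem

PET quantification requires correcting each line of response for the
absorption of 511 keV annihilation photons, encoded as a map of linear
attenuation coefficients mu (cm^-1). On hybrid PET/MR scanners no
transmission or CT scan is available, and cortical bone — the strongest
absorber in the head — is nearly invisible on conventional MR sequences.
Ultrashort-echo-time (UTE) acquisitions capture bone signal at TE of about
0.07 ms before T2\* decay extinguishes it; by the second echo (2.46 ms)
bone has lost most of its signal while soft tissue has barely changed.
This package implements a segmentation-based attenuation-correction
workflow that exploits exactly that contrast, together with everything
needed to exercise it end-to-end on synthetic data: a dual-echo UTE head
phantom generator with ground truth, a template/tissue-probability-map
(TPM) builder, a prior-guided Gaussian-mixture segmenter, R2\* mapping,
attenuation-map assembly, a desk-scale attenuated OSEM emission simulator,
and the full evaluation suite (Dice/FP/FN, difference maps, relative-error
analysis, SVD representative histograms, Mann-Whitney tests).

## The method

1. **Template and TPMs.** First-echo UTE images of a cohort are averaged
   (after alignment) into a UTE template. Expert air/soft/bone masks are
   averaged per class into probability maps. Because the air and bone maps
   come from trusted expert segmentations, they are *protected*: wherever
   the six per-voxel class probabilities do not sum to 1, only the
   non-protected classes (soft, GM, WM, CSF) are rescaled by
   `(1 - sum(protected)) / (sum(non-protected))`, so the unit-sum
   constraint holds while air and bone stay untouched. Voxels with no
   class mass at all default to air (outside-head background is air).
2. **Segmentation.** The subject's first-echo image alone (the second
   echo is used only for R2\*) is segmented by an EM-fitted Gaussian
   mixture in which each tissue class carries the voxel-wise TPM prior:
   posterior_k(x) proportional to prior_k(x) w_kj N(I(x); mu_kj,
   sigma^2_kj). Hard labels follow two threshold rules: air posterior
   above 0.1 is air, then bone posterior above 0.2 is bone. The two rules
   can both fire at a voxel; bone wins, because a hole in the skull is the
   costlier PET error (this precedence is configurable).
3. **R2\* mapping.** R2\*(x) = (ln I1 - ln I2) / (TE2 - TE1), natural
   logarithm, 1/ms for TEs in ms. Intensities are floored before the log;
   negative estimates (noise can push I2 above I1) clamp to 0.
4. **Attenuation assignment.** Air 0, soft tissue 0.100 cm^-1, and bone
   either the fixed 0.151 cm^-1 ("fix" mode) or a clamped third-order
   polynomial of the voxel R2\* ("cont" mode). The assembled map is
   smoothed with a 2-mm FWHM Gaussian. A six-class variant (mcAC) assigns
   GM 0.099, WM 0.099 and CSF 0.096 cm^-1 to probe the effect of
   multi-compartment brain coefficients. The reference map assigns the
   three fixed coefficients to ground-truth labels without smoothing.
   Evaluation-side converters cover CT (bilinear HU conversion anchored at
   air and water; classification at -500/300 HU) and vendor UTE maps
   (voxels exactly at 0.151 are bone, exactly 0 air).
5. **Emission simulation and reconstruction.** A 2-D slice-wise
   parallel-beam model: Poisson counts with mean ACF(mu_true) x
   P(activity), reconstructed by OSEM with the attenuated system matrix
   (3 iterations, 21 requested subsets, 5-mm FWHM in-plane post-filter).
   Candidate attenuation maps enter only through their attenuation
   factors, so reconstruction differences isolate AC-induced bias.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| TE1, TE2 | 0.07, 2.46 | ms | dual-echo UTE brain protocol |
| air / bone posterior thresholds | 0.1 / 0.2 | — | hard-label rules |
| mu air/soft/bone | 0 / 0.100 / 0.151 | cm^-1 | fixed-coefficient assignment |
| mu GM/WM/CSF | 0.099 / 0.099 / 0.096 | cm^-1 | multi-compartment variant |
| AC smoothing | 2 | mm FWHM | matches the map-assembly smoothing |
| PET post-filter | 5 | mm FWHM | reconstruction post-filtering |
| OSEM | 3 it, 21 subsets | — | subsets reduced to the largest divisor of the angle count (20 for 180 angles), with a warning |
| CT thresholds | -500 / 300 | HU | air / bone classification |
| EM convergence | 1e-6 rel., 100 it | — | log-likelihood stopping rule |
| variance floor | 1e-4 x global var | — | prevents component collapse |

All smoothing kernels are specified as FWHM, the neuroimaging convention
(sigma = FWHM / (2 sqrt(2 ln 2))); the interpretation matters because the
sources of such parameters rarely say which is meant. Boundary handling is
constant-zero padding: the physical background of an attenuation map is
air.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a nested head: scalp soft tissue, a closed
ellipsoidal skull shell (6 mm), a subarachnoid CSF rim, a GM rind over a
WM core, two ventricles, and air cavities in the facial soft tissue. Per
class it assigns proton density, R2\* (bone 2.0 /ms; soft 0.02; GM/WM
0.025; CSF 0.005 — chosen once so the 0.07/2.46 ms echo pair suppresses
bone in echo 2, the contrast the method relies on), true mu, and FDG-like
activity with a GM:WM:CSF ratio of 4:1:0.1 (a typical grey-white FDG
contrast; the coefficients themselves are configurable). Echoes follow
I = PD exp(-TE R2\*), degraded by an optional polynomial bias field and
Rician noise at 3% of the mean soft-tissue echo-1 intensity (the
magnitude-MR noise model). The default grid is 96^3 at 2 mm; the template
cohort applies seeded geometry jitter (about 3% semi-axis scale, 2 mm
shifts) to emulate residual inter-subject variability after alignment.

What it deliberately does not model: k-space/radial UTE acquisition,
partial-volume mixing at tissue borders (labels are crisp), motion,
susceptibility effects, scatter/randoms and PSF in PET, and deformable
registration (the cohort is generated pre-aligned; the template builder
accepts affine transforms from upstream). Consequently a passing test
shows the *algorithmic chain* is correct under its stated model — crisp
boundaries and large class contrast make phantom Dice scores higher than
any human dataset would give, so they bound the implementation, not
clinical performance.

## Numerical and design choices

- **Dice denominator.** The standard form 2|A∩B| / (|A|+|B|) is the
  default; a literal "union-denominator" variant (which scores 2 for
  identical masks) is exposed as `dice(..., variant = "union")` for
  audit. Empty-vs-empty Dice is 1; empty-vs-nonempty is 0.
- **FP/FN denominators.** fp_rate = |pred \\ ref| / |pred| and fn_rate =
  |ref \\ pred| / |ref|; consistent with reading bone over-segmentation as
  a false-positive rate.
- **Relative-error signs.** The voxel-wise map is
  R = 100 (ref - test)/ref, so a test image *hotter* than the reference is
  negative. Summary tables are additionally reported in the opposite,
  test-minus-reference orientation (`full_brain_bias`), in which an
  under-corrected reconstruction reads negative; both are exact
  negations of each other.
- **R2\*-to-mu calibration.** The exact cubic used by scanner vendors is
  site-specific; the package ships a fitter (least squares, degree 3,
  monotonicity enforced on a dense grid) plus a documented default through
  the anchors (0 /ms, 0.100 cm^-1) and (2.0 /ms, 0.151 cm^-1).
  Continuous-mode results are therefore calibration-dependent; mu is
  clamped to [0.100, 0.20] cm^-1 so bone never falls below soft tissue.
- **HU conversion.** Bilinear with anchors at air (-1000 HU, 0) and water
  (0 HU, 0.096 cm^-1) and a configurable high-side slope of 6.4e-5 cm^-1
  per HU — a standard published family of curves rather than one specific
  scanner's.
- **EM initialization.** Class means start at prior-weighted intensity
  means; when several classes carry uninformative (tied) priors the tied
  means are spread over intensity quantiles so EM can break the symmetry.
  Log-space likelihood evaluation prevents underflow at extreme
  intensities.
- **mcAC inputs.** In the pipeline the six-class map is built from
  ground-truth labels rather than GMM posteriors: the mcAC arm measures
  the effect of coefficient *assignment*, and using truth keeps
  segmentation error out of that measurement.
- **Protected renormalization below unit sum.** The protected rule is
  stated for voxel sums above 1; for sums below 1 the same multiplicative
  fill of non-protected classes restores the unit-sum constraint. Where
  no non-protected mass exists at all, the residual deficit goes to soft
  tissue.
- **Fallback pasting.** Outside template coverage, values from a fallback
  map (e.g. a vendor map) are pasted after smoothing, unsmoothed across
  the seam — no blending is attempted.

## Problem sizes

The default ("fast") pipeline profile generates a 5-subject jittered
cohort and one test subject at 96^3 x 2 mm, segments the full volume, and
reconstructs 3 brain slices per attenuation map with 180 angles x 128 bins
x 2 mm and 5e6 expected counts — enough to resolve the 1–5% regional
biases the attenuation arms produce while keeping a complete run around
half a minute on one core. The "full" profile reconstructs 9 slices.
Reported regional tables cover the atlas regions intersecting the
reconstructed slices.

## Known limitations

- The projector is 2-D parallel-beam without PSF, scatter, randoms or
  TOF; absolute reconstructed values are in arbitrary activity units and
  only *relative* comparisons between attenuation arms are meaningful.
- Deformable registration is out of scope; transforms are inputs.
- The GMM has no Markov-random-field spatial regularization or cleanup;
  priors carry all the spatial information.
- Bias-field correction is a low-order polynomial gain, not a full
  DCT-basis model; it is off by default and intended for the phantom's
  polynomial bias fields.
- The vendor-map and CT classification rules are evaluation-side
  converters; no pseudo-CT synthesis from an MR-CT database is
  implemented.
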
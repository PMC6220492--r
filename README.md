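# suteac

MR-based attenuation correction for brain PET/MR using dual-echo
ultrashort-echo-time (UTE) imaging — implemented end-to-end with a
synthetic head phantom so every stage is testable without scanner data.

## The problem

Quantitative PET needs a map of 511 keV linear attenuation coefficients
μ (cm⁻¹) to correct every line of response for photon absorption. On
PET/MR scanners there is no CT, and cortical bone — the dominant absorber
in the head — gives almost no signal on conventional MR. UTE sequences
acquire a first echo at TE₁ ≈ 0.07 ms, early enough to catch bone signal,
and a second at TE₂ ≈ 2.46 ms by which bone has decayed. The package
implements a segmented-UTE (sUTE) workflow on top of that contrast:

1. a **UTE template** and six-class **tissue probability maps** (TPMs)
   built from cohort images and expert masks, with air/bone maps protected
   during per-voxel renormalization;
2. **Gaussian-mixture segmentation** of the first-echo image with the TPMs
   as voxel-wise priors, hard-labelled at air posterior > 0.1 and bone
   posterior > 0.2;
3. the **R2\*** map, R2\* = (ln I₁ − ln I₂)/(TE₂ − TE₁) (1/ms);
4. **attenuation maps**: air 0, soft 0.100 cm⁻¹, bone either fixed
   0.151 cm⁻¹ (sUTE-fix) or a monotone cubic of R2\* (sUTE-cont), smoothed
   with a 2-mm FWHM Gaussian; plus a six-class variant
   (GM/WM/CSF = 0.099/0.099/0.096 cm⁻¹), a ground-truth reference map, and
   CT/vendor-map converters for comparison;
5. a **desk-scale PET simulator**: parallel-beam projector/backprojector
   (exact adjoint pair), Poisson emission with true-μ attenuation factors,
   OSEM reconstruction (3 iterations, 21 requested subsets, 5-mm
   post-filter);
6. an **evaluation suite**: Dice / false-positive / false-negative rates,
   Diff/AbsDiff statistics, voxel-wise and regional relative error
   RE% = 100·(PET_ref − PET_X)/PET_ref, 150-bin SVD representative
   histograms, and Mann-Whitney U tests.

A seeded phantom generator supplies dual-echo volumes with ground-truth
labels, true μ, an FDG-like activity map and a brain region atlas, so the
whole chain runs and is verified on synthetic data.

## Worked example

```r
library(suteac)

# noiseless phantom: R2* mapping inverts the echo simulation
ph  <- generate_phantom(phantom_spec(noise_sigma = 0))
r2s <- compute_r2star(echo_pair(ph$echo1, ph$echo2))
print(r2s)
#> suteac_volume: 96x96x96, spacing 2x2x2 mm, units 'r2star_per_ms'
#>   range [0, 2]

# full workflow: cohort TPMs -> segmentation -> AC maps -> OSEM -> report
rep <- run_pipeline(run_config())
print(rep)
#> suteac pipeline report
#>   segmentation accuracy (head region):
#>  class dice fp_rate fn_rate
#>    air    1       0       0
#>   soft    1       0       0
#>   bone    1       0       0
#>   full-brain RE% vs reference reconstruction:
#>     sute_fix    +0.01%
#>     sute_cont   +2.10%
#>     mcac        +1.78%
#>     no_bone     +4.93%
```

The R2\* range ends at 2.0 /ms — the phantom's cortical-bone relaxation
rate — confirming the dual-echo inversion. In the report, Dice of 1.0
reflects the phantom's crisp boundaries and large class contrast (an upper
bound for the implementation, not a clinical claim). The RE% lines compare
each reconstruction against the reference-map reconstruction in the
RE% = 100·(ref − X)/ref orientation: ignoring bone entirely (`no_bone`)
costs about 5% of brain signal, the fixed-bone sUTE map is essentially
unbiased, and the six-class map (`mcac`) shifts the brain by ~2% because
its GM/WM/CSF coefficients sit slightly below the single soft-tissue
value. `rep$full_brain_bias` holds the same numbers in the
test-minus-reference orientation (underestimation negative), and
`rep$regional_re` the per-region tables.

A thin command-line wrapper with subcommands (`phantom`, `r2star`,
`segment`, `make-acmap`, `simulate-pet`, `evaluate`, `run-all`) is
installed at `inst/cli/sute-ac`.

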
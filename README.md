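# notchseg

Automatic measurement of the femoral intercondylar notch (fossa) volume
from axial knee MRI: a residual U-Net segments the notch slice by slice,
pixel-counting volumetry turns the binary masks into physical volumes, and
a statistics module provides the agreement and group-comparison analyses
used to validate automatic against manual measurement.

**Who it is for.** Researchers studying the link between notch geometry
and anterior cruciate ligament (ACL) injury, and anyone who needs a
self-contained, fully testable slice-wise segmentation + volumetry
pipeline in R. Because clinical MRI cohorts are rarely shareable, the
package ships a synthetic phantom generator with *analytically known*
notch volumes, so every stage — segmentation, volumetry, statistics — can
be validated end-to-end without patient data.

## The model in brief

- **Volumetry.** With per-slice ROI areas `s_z` (foreground pixels ×
  pixel area) and slice pitch `d` = thickness + gap (4.0 + 0.4 = 4.4 mm
  by default), the notch volume is `V = Σ_z s_z · d`, in cm³
  (`notch_volume()`).
- **Segmentation.** A residual U-Net (`build_network()`): five encoder
  levels of residual blocks (conv3×3–BN–ReLU ×2 + identity skip) with
  max-pool downsampling, pyramid pooling at the bottleneck and before the
  head, five upsampling + combine-block decoder stages, a per-pixel 1×1
  convolution head and sigmoid — 10 convolution layers, 11 residual
  blocks, 2 pyramid-pooling modules, 5 upsampling layers, 6 combine
  blocks. Trained with SGD + momentum (lr 1e-4) on the soft dice loss
  `1 − (2Σpt + ε)/(Σp + Σt + ε)`; forward and backward passes are
  implemented in the package (C++ kernels via Rcpp), no external deep
  learning framework.
- **Validation statistics.** Dice similarity `DSC = 2|X∩Y|/(|X|+|Y|)`
  (`dsc()`), two-way random-effects absolute-agreement ICC with F-based
  CIs (`icc_absolute_agreement()`), Pearson r/R² (`pearson()`),
  Bland–Altman limits of agreement (`bland_altman()`), unpaired two-tailed
  t-tests from raw values or from printed summary statistics
  (`ttest_unpaired()`, `ttest_from_summary()`), relative error
  `E = (R − P)/R` (`relative_error()`), and subject-level five-fold
  cross-validation (`crossvalidate()`).
- **Phantoms.** `generate_phantom()` renders axial stacks with a
  parabolic-segment notch carved between two bright condyle lobes; the
  true volume `Σ_z (2/3)·w(z)·h(z)·d` is exact. `generate_cohort()`
  simulates per-subject volume tables with configurable group/sex strata.

## Worked example

```r
library(notchseg)

# a noiseless phantom whose true notch volume is known in closed form
spec <- phantom_spec(size = 256, noise_sd = 0, bias_amplitude = 0)
spec$analytic_volume_cm3
#> [1] 6.576107

ph <- generate_phantom(spec, subject_id = "demo")
notch_volume(ph$mask)
#> <volume_measurement> subject demo: 6.576 cm^3 over 8 ROI slices
```

Pixel counting over the 8 ROI slices recovers the analytic 6.576 cm³ —
at 256×256 the voxelisation error is below 0.01%.

```r
# group comparison directly from printed summary statistics
ttest_from_summary(group_summary(363, 6.12, 1.34, "ACL injured"),
                   group_summary(232, 6.95, 1.75, "ACL intact"))
#> Unpaired two-tailed t-test (pooled): ACL injured vs ACL intact
#>   t = -6.527, df = 593, p = 1.45e-10, mean difference = -0.83
```

The injured group's mean notch volume is 0.83 cm³ smaller; with these
group sizes the difference is overwhelming (p ≈ 1e-10, far below the
printed `< 0.001` bound).

```r
# a simulated case-control cohort and its full comparison table
cohort <- generate_cohort(cohort_spec(seed = 1))
cmp <- cohort_comparison(cohort)
cmp$stratified[, c("contrast", "n_a", "n_b", "t", "p")]
#> # A tibble: 4 × 5
#>   contrast                     n_a   n_b     t        p
#>   <chr>                      <int> <int> <dbl>    <dbl>
#> 1 injured: male vs female      311    52  8.36 1.40e-15
#> 2 intact: male vs female       147    85  8.99 9.29e-17
#> 3 males: injured vs intact     311   147 -8.68 7.18e-17
#> 4 females: injured vs intact    52    85 -3.71 3.04e- 4
```

All four stratified contrasts are significant, the weakest being the
smallest stratum pair (52 vs 85 females). Agreement between two
measurement methods is summarised the same way the field reports it:

```r
set.seed(1)
manual <- rnorm(60, 6.8, 1.5)
auto   <- manual - 0.05 + rnorm(60, 0, 0.25)
glance(agreement_report(manual, auto))
#> # A tibble: 1 × 8
#>     icc icc_low icc_high     r r_squared mean_difference loa_low loa_high
#>   <dbl>   <dbl>    <dbl> <dbl>     <dbl>           <dbl>   <dbl>    <dbl>
#> 1 0.984   0.974    0.991 0.984     0.969          0.0220  -0.426    0.470
```

ICC 0.984 ("good", > 0.75), R² 0.97, and Bland–Altman limits of
agreement of −0.43 to +0.47 cm³ around a +0.02 cm³ mean difference.
`autoplot(bland_altman(manual, auto))` draws the corresponding plot.

Training end to end on phantoms (about five minutes on one core):

```r
bench <- benchmark_heldout_dsc(seed = 1)   # 40 phantoms, 30 train / 10 test
bench$mean_dsc
#> [1] 0.9751723
```

A thin command-line wrapper over the same functions lives at
`inst/cli/notchseg.R` (`simulate`, `volume`, `evaluate`, `stats`, `ttest`,
`run` subcommands).

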
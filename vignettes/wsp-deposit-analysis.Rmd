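---
title: "Methods: spray deposit analysis from water-sensitive paper"
author: "wspdeposit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spray deposit analysis from water-sensitive paper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wspdeposit)
```

## The measurement problem

Water-sensitive paper (WSP) cards are yellow cards coated with
bromophenol blue that stain blue wherever an aqueous droplet lands. Set
out in a crop during a pesticide application and scanned afterwards,
they are the standard low-cost collector for characterising spray
deposition — for spray-quality audits, drift assessment, and estimating
the exposure of non-target organisms that live on the foliage.

Getting from a scanned card to a deposition estimate involves a chain of
conversions, each with its own assumptions:

1. **Segmentation.** The grayscale scan is thresholded and connected
   components of dark pixels become stains. Pixel counts become areas
   through the scan resolution: the pixel pitch is $25400/\mathrm{dpi}$
   µm (42.33 µm at the 600 dpi typical of flatbed scans).
2. **Spread factor.** A stain is larger than the droplet that made it,
   because the liquid spreads and the paper absorbs. A *spread factor*
   inverts that inflation.
3. **Volume and deposition.** Droplet diameters $d$ (µm) become
   spherical volumes $V = \frac{\pi}{6} d^3 \times 10^{-9}$ µL, and the
   card's *deposition* is the summed volume per unit card area
   (µL cm⁻²), alongside *coverage* (% of the card surface stained) and
   *droplet density* (stains cm⁻²).
4. **Residue.** If the tank-mix concentration of active ingredient $C$
   (µg µL⁻¹) is known, deposition converts to an areal residue
   $R = C \times D$ (µg cm⁻²).
5. **Calibration.** WSP-derived residues systematically overestimate
   what chemical analysis finds on leaves; an empirical correction
   factor aligns the two.

The package implements this chain, plus the synthetic-stain experiments
that probe where it goes wrong.

## The two spread-factor models

The **constant power-law** model applies a single factor to the stain
area $A$ (µm²):

$$d = SF \cdot A^{0.455}, \qquad SF = 1.06,$$

the default built into widely used deposit-scanning software. The
**diameter-binned** model first computes the equivalent-circle stain
diameter $d_s = 2\sqrt{A/\pi}$ and divides by a factor that grows with
stain size, from the manufacturer-derived table for water:

| stain diameter (µm) | spread factor |
|---|---|
| (0, 100]   | 1.7 |
| (100, 200] | 1.8 |
| (200, 300] | 1.9 |
| (300, 400] | 2.0 |
| (400, 500] | 2.1 |
| (500, 600] | 2.1 |

Bins are half-open on the upper bound (a 100 µm stain uses 1.7, a
100.01 µm stain uses 1.8); stains beyond 600 µm clamp to 2.1, because
the table plateaus there and no extrapolation rule is published.
Across the tabulated 100–600 µm range the constant model always returns
the larger droplet:

```{r}
rep <- runSpreadFactorComparison(c(100, 200, 300, 400, 500, 600))
rep$table[, c("stain_diameter_um", "d_constant_um", "d_binned_um",
              "pct_difference")]
```

The percent difference column is computed relative to the
constant-model diameter, $100\,(d_{const} - d_{binned})/d_{const}$ —
the convention under which all six tabulated reference values
recompute exactly.

Because volumes scale as $d^3$, these 6–12% diameter gaps become
~20–40% volume gaps, which is why the choice of spread factor is the
dominant modelling decision in card-based deposition estimates.

### The touching-droplet artefact

Segmentation cannot separate stains that touch: two tangent stains
become one component with twice the area. Under the constant power law
the merged deposit's volume exceeds the separated pair's by exactly

$$\frac{(2A)^{3 \times 0.455}}{2\,A^{3 \times 0.455}} - 1 =
  2^{0.365} - 1 = 28.79\%$$

independent of droplet size — a closed form the rasterized experiments
reproduce to within pixelation error:

```{r}
rt <- runTouchingTest(c(300, 800), mode = "analytic")
rt$table$overestimation_pct
```

This is a structural bias: any card with touching stains overestimates
deposition, and the denser the spray the more stains touch. That is the
rationale for the high-coverage exclusion below.

## Residue estimation and the correction factor

Leaf residues measured chemically are expressed per unit upper leaf
surface, $R_{area} = R_{leaf}/A_{leaf}$ (µg cm⁻²), under the assumption
that spray residue sits on the upper surface. WSP residues come from
$R = C \times D$. The correction factor is the **ratio of arm means**:

$$CF = \bar{R}_{leaf} / \bar{R}_{WSP},$$

fitted after excluding WSP cards whose coverage exceeds 30%. A ratio of
means — not a mean of per-pair ratios, nor a regression slope — because
the two arms are unpaired samples of different sizes from different
substrates, and this is the unique factor for which the corrected WSP
mean equals the leaf mean identically. With the motivating study's
printed arm means:

```{r}
m <- fitCorrectionFactor(0.039, 0.24)
correctionFactor(m)
applyCorrection(0.24, m)
```

CF is reported to 4 decimal places; correction is applied per data
point, so distributional summaries of the corrected arm remain
meaningful.

### The paired-residue generator

`simulatePairedResidues()` provides the synthetic calibration data used
to validate recovery of a known factor $\gamma$. Both arms observe the
same latent spray-deposit field: deposits vary across sampling
locations as a shared lognormal spatial component, and each arm adds
its own multiplicative lognormal measurement noise. The shared
component's CV is the smaller of the two target arm CVs (default WSP
44%); the leaf arm's residual noise tops its marginal CV up to 50%.
Defaults are the calibration arm sizes of the motivating field study,
$n = 90$ leaves and $61$ cards.

This construction was a genuine design choice. Fully independent arms
would make the ratio-of-means estimator's sampling error at these
sample sizes about 7.7% (so a ~5% median relative error), which would
say nothing about the estimator and everything about the design; fully
paired arms are impossible with unequal $n$. A shared field is also the
physically sensible model — leaves and cards hanging in the same
canopy zone sample the same spray gradient, which is what makes an
empirical calibration between the two meaningful at all. Under it,
recovery at the default conditions has median relative error well
under 5%:

```{r}
errs <- vapply(1:25, function(i) {
  s <- simulatePairedResidues(0.1625, seed = i)
  abs(correctionFactor(fitCorrectionFactor(s$leaf, s$wsp)) - 0.1625) /
    0.1625
}, 0)
median(errs)
```

What the generator does **not** emulate: spatial autocorrelation beyond
a common location effect, residue decay between application and
sampling, translocation of active ingredient into the leaf, or the
wetting-agent chemistry that makes pesticide mixtures spread
differently from the water used to derive the spread factors. Passing
recovery tests therefore demonstrates estimator correctness under the
stated noise model, not field validity of a particular CF value.

## Synthetic cards and segmentation

### Rasterization

`rasterizeCircle()` uses deterministic centre-inclusion rasterization:
pixel $(x, y)$ (0-based, centred at integer coordinates) is stained
when its centre lies within the circle, boundary inclusive with a
$10^{-12}$ relative tolerance on the squared radius. The tolerance
exists so that exactly tangent circle pairs — whose tangency point
`generateTouchingPair()` snaps to a pixel centre — rasterize
symmetrically instead of depending on the rounding direction of the
last floating-point bit; it is far below one part in $10^9$ of a pixel,
so it never changes counts for generic geometry. The rule is simple
enough to check by brute force, which the test suite does
pixel-by-pixel.

Consequences worth knowing:

- a circle one pixel-pitch wide marks exactly one pixel;
- measured equivalent-circle diameters converge to truth as dpi grows
  (relative error under 1% at 2400 dpi for stains ≥ 200 µm) but a
  ~200 µm stain at 600 dpi is only ~4.7 px across and its pixelated
  area can sit several percent from $\pi r^2$;
- stains below about one pixel (95.5 µm at 600 dpi is 2.3 px) survive
  rasterization but their measured sizes are dominated by the grid.

### Segmentation

`binarize()` thresholds globally. Automatic mode maximises
between-class variance on the 256-level histogram (Otsu's method) —
parameter-free and appropriate for the bimodal histograms of WSP scans;
a uniform image falls back to the fixed threshold with a warning.
`extractStains()` labels connected components under 8-connectivity by
default (4 available), drops components below `minPixels = 1`, and
converts counts to areas via the pitch squared. One pixel is the honest
detection floor: claims of ~17 µm minimum detectable droplets are
sub-pixel at 600 dpi and cannot be honoured by any pixel-counting
method. No sub-pixel or partial-intensity area refinement is attempted.

On noiseless synthetic cards segmentation is exact — component counts
and pixel counts equal the rasterizer's ground truth, a conservation
property the tests assert card by card.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `dpi` | 600 | dots inch⁻¹ | typical flatbed scan resolution for WSP |
| `sf`, `exponent` | 1.06, 0.455 | — | deposit-scanning software default power law |
| bin table | see above | µm → factor | manufacturer values for water |
| `connectivity` | 8 | — | tangent stains merge, matching scanner-software behaviour |
| `minPixels` | 1 | px | one pixel is the resolution-limited floor |
| `coverage_threshold` | 30 | % | above this stains merge extensively and volumes are unreliable |
| `tank_concentration` | 0.18 | µg µL⁻¹ | example study's tank mix |

## Experiment drivers and problem sizes

`runSpreadFactorComparison()` and `runTouchingTest()` accept any
diameter set; the original artificial-stain set is unpublished, so the
package substitutes a seeded log-uniform sample of 33 diameters over
the printed 95.5–1438 µm range (right-skewed, like field droplet
spectra) plus the exact 100–600 µm grid as a fixed fixture. Analytic
mode uses exact circle areas; rasterized mode draws, segments and
measures each stain, so the two modes bracket what pixelation
contributes. Effect sizes are reported with seeded bootstrap CIs rather
than rank tests: the effect, not the p-value, is the reproducible
content.

The test suite runs its validations at deliberately modest sizes —
50 seeded cards of 2–5 stains for the segmentation-oracle equivalence,
100 replicates per factor for correction-factor recovery, 215 small
cards for the batch pipeline — chosen so the full suite completes in
seconds while still exercising every claimed property at the study's
sample-size scale where that scale matters (n = 90/61, n = 215,
zone n = 106/109).

## Known limitations

- Real WSP scans have texture, vignetting and colour bleed that the
  noiseless synthetic cards do not; the Gaussian-noise robustness test
  (σ = 10 intensity levels, < 1% pixel disagreement) is a lower bound
  on messiness, not a scanner model.
- The global threshold assumes a bimodal histogram; heavily saturated
  cards (coverage far above 30%) violate it, which is one more reason
  for the exclusion rule.
- BMP and GIF scans are not read directly (no reader in the supported
  stack); convert to PNG or TIFF first.
- The correction factor is an empirical ratio tied to the crop,
  product, and spray conditions it was fitted under; applying a fitted
  `CorrectionModel` elsewhere is an extrapolation the package cannot
  police.
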
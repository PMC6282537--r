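# wspdeposit

Quantifying pesticide spray deposition — and the exposure of whatever
lives on the sprayed foliage — from scanned water-sensitive paper (WSP)
cards.

WSP cards stain blue where aqueous spray droplets land. `wspdeposit`
turns a grayscale card scan into per-card spray metrics and residue
estimates:

1. **Segmentation** — global thresholding (Otsu) and connected-component
   labelling turn the scan into stains; pixel counts become areas through
   the pixel pitch 25400/dpi µm.
2. **Spread factor** — stains are larger than the droplets that made
   them. Two inversion models are provided: the constant power law
   *d = SF·A^0.455* (SF = 1.06, *A* the stain area in µm²) used by
   deposit-scanning software, and a diameter-binned table for water that
   divides the equivalent-circle stain diameter *dₛ = 2√(A/π)* by a
   factor rising from 1.7 (≤ 100 µm) to 2.1 (> 400 µm).
3. **Card metrics** — coverage (%), droplet density (cm⁻²) and liquid
   deposition (µL cm⁻², summed spherical volumes *V = (π/6)d³·10⁻⁹*).
4. **Residue** — with the tank-mix concentration *C* (µg µL⁻¹), residue
   is *R = C·D* (µg cm⁻²), and an empirical correction factor
   *CF = mean(leaf residues)/mean(WSP residues)* calibrates WSP
   estimates against chemically measured leaf residues
   (*R_corrected = R·CF*), after excluding cards with > 30% coverage.

A synthetic-card generator (deterministic centre-inclusion
rasterization with exact ground truth) supports the validation
experiments: spread-factor model comparison and the touching-droplet
artefact, where two tangent stains segment as one deposit and inflate
its volume by exactly 2^0.365 − 1 = 28.79% under the constant model.

## Worked example

```r
library(wspdeposit)

# a synthetic 900x700 px card at 600 dpi with 33 log-uniform stains
gen <- generateCard(sampleStainDiameters(33, seed = 42),
                    900, 700, dpi = 600, seed = 42)
res <- analyzeCards(gen$card)
res$cards
#>   card_id coverage_pct density_per_cm2 deposition_uL_per_cm2 n_stains
#> 1 card001     1.368095        2.922863             0.1253291       33
#>   high_coverage_flag residue_ug_per_cm2
#> 1              FALSE         0.02255923
```

1.37% of the card is stained; 33 stains at 2.9 cm⁻² deposited
0.125 µL cm⁻² of liquid, which at the default tank mix
(0.18 µg µL⁻¹) is an estimated 0.023 µg cm⁻² of active ingredient.
The per-stain table carries the full conversion chain:

```r
head(res$stains[, -1], 3)
#>   stain_id pixel_count  area_um2 stain_diameter_um droplet_diameter_um
#> 1        1         135 241935.00          555.0146            298.4618
#> 2        2          83 148745.22          435.1877            239.2035
#> 3        3          52  93189.78          344.4603            193.3608
#>     volume_uL
#> 1 0.013920824
#> 2 0.007166398
#> 3 0.003785331
```

Calibrating WSP residues against leaf measurements:

```r
m <- fitCorrectionFactor(0.039, 0.24)   # arm means in ug cm-2
m
#> CorrectionModel
#>   CF = 0.1625 (leaf mean 0.039 / WSP mean 0.24 ug cm-2)
#>   n = 1 leaf, 1 WSP (0 WSP excluded)
applyCorrection(0.24, m)
#> [1] 0.039
```

The experiment drivers — `runSpreadFactorComparison()`,
`runTouchingTest()`, `compareMethods()` — produce the reference tables
and calibration reports; `inst/cli/wspdeposit.R` exposes them as shell
subcommands (`analyze-cards`, `spreadfactor-compare`, `touching-test`,
`compare-methods`, `generate-fixtures`).

See the methods vignette (`vignettes/wsp-deposit-analysis.Rmd`) for the
models, their assumptions, and the numerical choices.

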
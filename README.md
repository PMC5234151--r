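# nirfat

Monte Carlo simulation of near-infrared (NIR) diffuse reflectance over layered
skin, for quantifying how well an angled fibre-optic probe can sense
subcutaneous fat thickness in neonates — and how badly tissue hydration and
skin colour (epidermal melanin) confound it.

## What it computes

Each tissue layer gets composition-derived optical properties:

- absorption from chromophore volume fractions,
  `μa(λ) = V_fat μa_fat + V_water μa_water + V_blood μa_blood +
  V_melanin μa_melanin + (1 − ΣV) · 7.84e7 λ^−3.255`, with blood mixing
  deoxy-/oxy-hemoglobin by saturation
  (`μa_blood = (1−V_oxy) V_hb μa_Hb + V_oxy V_hb μa_HbO2`);
- reduced scattering `μs'(λ) = a (λ/500 nm)^−b` per layer
  ((a, b) = (45.3, 1.29) epidermis–dermis, (15.4, 0.68) subcutaneous fat,
  (9.8, 2.82) muscle), isotropic scattering (g = 0);
- refractive indices 1.4 / 1.44 / 1.37; dehydration lowers the water
  fractions and raises n and μs' of the skin layers by 5% (1.4 → 1.47,
  1.44 → 1.512).

Six built-in models cross these: two air-bounded single-fat slabs and four
three-layer skin models (Caucasian/African × normal/dehydrated). A weighted
Monte Carlo kernel (continuous Beer–Lambert attenuation along exponential
scattering steps, unpolarized Fresnel boundaries with Snell refraction,
Russian roulette, per-photon RNG substreams for bit-reproducibility) traces
packets from a +45°-tilted 0.4 mm NA 0.39 fibre to a −45° cosine-corrector
detector (4 mm, NA 1.0) 10 mm away. Experiment drivers sweep fat thickness
(1–15 mm), fit the logarithmic response `R = A ln t + B`, compute the per-mm
sensitivity `(R_15 − R_1)/14`, sweep wavelength (800–1100 nm), and locate
hydration-robust wavelength windows.

Chromophore spectra come from user-supplied two-column tables
(`read_spectrum()`) or from built-in synthetic emulations of the literature
band shapes (`synth_chromophore()`); the synthetic set reproduces orderings
and contrasts, not absolute published magnitudes.

## Worked example

```r
library(nirfat)

# reflection vs fat thickness for the bare fat slab at 930 nm
curve <- thickness_sweep("single_fat_1", lam = 930, n_photons = 2e5, seed = 11)
sensitivity(curve)
#> [1] 0.01018104
glance(fit_logarithmic(curve))
#> # A tibble: 1 × 4
#>        A      B r_squared     n
#>    <dbl>  <dbl>     <dbl> <int>
#> 1 0.0575 0.0282     0.927    15
autoplot(curve)

# skin colour: African epidermis absorbs more, so everything shrinks
c_afr <- thickness_sweep("skin_3", lam = 930, n_photons = 2e5, seed = 11)
sensitivity(c_afr)
#> [1] 0.0001062625

# hydration contrast: 930 nm sits in a hydration-robust window, 970 nm on
# the water band
hw <- hydration_window("single_fat_1", "single_fat_2", lam_grid = c(930, 970),
                       n_photons = 1e6, seed = 5)
hw$table
#> # A tibble: 2 × 5
#>     lam r_normal r_dehydrated flagged rel_diff
#>   <dbl>    <dbl>        <dbl> <lgl>      <dbl>
#> 1   930    0.134        0.137 FALSE     0.0164
#> 2   970    0.161        0.194 FALSE     0.206
```

The sensitivity is the mean reflection change per mm of added fat, in
percentage points of detected reflection per mm: the bare fat slab responds
roughly two orders of magnitude more strongly than African skin, which is
the melanin penalty the probe design must correct for. The `rel_diff`
column shows the hydration effect is ~12× smaller at 930 nm than at 970 nm.

A thin CLI over the same functions lives at `inst/cli/nirfat.R`
(`Rscript inst/cli/nirfat.R sweep-thickness --model skin_1 --lambda 930 ...`).

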
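# capquant

Quantitative analytics for chemically modified mRNA cap analogs.

Synthetic trinucleotide cap analogs — 7-methylguanosine linked to the first
two transcribed nucleotides through a modified oligophosphate bridge — are
characterized by a standard battery of assays: fluorescence quenching
titrations against the cap-binding translation initiation factor eIF4E,
optical-density quantitation of synthesis yields, gel densitometry of in
vitro transcription and decapping reactions, reporter-luciferase expression
time courses in cell lines, and TMT-multiplexed pull-down proteomics.
`capquant` implements the quantitative analysis behind each assay for
researchers who run (or simulate) these experiments and want a tested,
scriptable pipeline instead of spreadsheet arithmetic and desktop tools.

## The models at the core

**Binding.** Titrations run under ligand depletion (protein ~ K_D), so the
complex concentration comes from the exact single-site equilibrium

    [cx] = (L + P)/2 + (1 - sqrt((K_as (L - P) + 1)^2 + 4 K_as P)) / (2 K_as)

and the fluorescence model

    F = F(0) - [cx] (dPhi + Phi_free) + L Phi_free

is fitted by bounded multi-start Levenberg–Marquardt after dilution and
inner-filter corrections (`F_obs x (V_i/V_0) x 10^((A_ex + A_em)/2)`).
Replicate association constants are pooled by inverse-variance weighting
and reported as K_D in nM.

**Densitometry.** Lanes are 1-D traces; bands are detected above an
asymmetric-least-squares baseline and integrated valley-to-valley after a
second-pass baseline refit. Capping efficiency is
`A_capped / (A_capped + A_uncapped)`; decapping susceptibility is
`1 - cf(30 min)/cf(0)`.

**Expression.** Cumulative luminescence over the 16/40/64/88 h schedule,
normalized to the mean of the reference cap within each cell line.

**Proteomics.** The fixed cascade clean → log2 + median-center →
completeness filter (≥ 2 razor peptides, complete 9 channels) → two-sided
moderated test `d = (mean_A - mean_B)/(s + s0)` with `s0 = 1` and a
permutation-based FDR threshold (balanced 3-vs-3 relabelings) at 0.02,
followed by preferential-binder classification, fold-change–fold-change
comparison and an iBAQ top-quartile abundance screen.

Seeded generators (`sim_titration()`, `sim_lane_profile()`,
`sim_decapping_series()`, `sim_expression_plate()`,
`sim_protein_groups()`) simulate each assay's raw data with ground truth
attached, so the whole pipeline is testable end to end with no external
data.

## Worked example

Recover the dissociation constant of the reference cap-1 trinucleotide
(ground truth 42.1 nM) from three simulated titrations at the standard
protocol — 1 ul aliquots into 1.4 ml of 0.1 uM eIF4E, 2% fluorescence
noise — then pool:

```r
library(capquant)

protocol <- design_titration_protocol(kd_nM = 42.1)
truth    <- sim_binding_params(42.1)

fits <- lapply(1:3, function(i) {
  raw   <- sim_titration(truth, protocol, sim_config(seed = i, noise_scale = 0.02))
  curve <- build_titration_curve(raw, protocol)
  fit_titration(curve, fix = list(P_act = 0.1, phi_lig_free = 25))
})
glance(fits[[1]])
#> # A tibble: 1 × 8
#>   kas_per_uM kas_se kd_nM kd_se_nM   ssr sigma n_points converged
#>        <dbl>  <dbl> <dbl>    <dbl> <dbl> <dbl>    <int> <lgl>
#> 1       23.7   1.14  42.1     2.03 5747.  12.5       40 TRUE

pool_binding_fits(fits)
#> # A tibble: 1 × 6
#>   kas_per_uM kas_se kd_nM kd_se_nM n_replicates method
#>        <dbl>  <dbl> <dbl>    <dbl>        <int> <chr>
#> 1       23.7  0.660  42.2     1.17            3 inverse_variance
```

The pooled K_D of 42.2 ± 1.2 nM recovers the generating 42.1 nM; each
per-replicate fit carries its curvature-based standard error, and pooling
is inverse-variance weighted. `autoplot(fits[[1]])` overlays the fitted
binding curve on the corrected titration points.

Densitometry on a synthetic lane with a 9:1 capped:uncapped band ratio on a
drifting baseline:

```r
lane  <- sim_lane_profile(
  data.frame(position = c(40, 60), area = c(1, 9), width = 2),
  baseline = c(0.01, 0.0009),
  sim = sim_config(seed = 7, noise_scale = 0.01))
bands <- assign_cap_bands(integrate_bands(lane))
bands
#> # A tibble: 2 × 5
#>   band_id  position  area height saturated
#>   <chr>       <dbl> <dbl>  <dbl> <lgl>
#> 1 capped       60.0 8.98   1.74  FALSE
#> 2 uncapped     40.0 0.999  0.203 FALSE

capping_efficiency(bands[bands$band_id == "capped", ],
                   bands[bands$band_id == "uncapped", ])
#> [1] 0.9000754
```

The integrated areas (8.98 and 0.999) recover the generated 9 and 1, giving
90% capping efficiency.

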
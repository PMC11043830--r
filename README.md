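# mossdiv

Multi-scale diversity analysis of moss communities in paired
herbivore-exclosure experiments.

## What it is for

Arctic geese disturb the moss carpet when they grub for graminoid
rhizomes. Long-term exclosure experiments quantify the consequences by
counting moss shoots of every species in a nested design — 2 × 2 cm
cells (4 cm²) within 10 × 10 cm quadrats within paired
exclosure/control plots. `mossdiv` is for ecologists analysing such
hierarchical abundance data. It provides, at any of the three scales:

- **Alpha diversity**: richness *S*; the log-variance evenness
  *E* = 1 − (2/π)·arctan(*V*), with *V* the population variance of
  ln *x* over the species present; and the bias-corrected inverse
  Simpson index 1/λ, λ = Σ nᵢ(nᵢ−1)/(T(T−1)).
- **Beta diversity**: Bray–Curtis dissimilarity
  β_BC = (B+C)/(2A+B+C) partitioned into balanced variation (turnover)
  β_bal = min(B,C)/(A+min(B,C)) and abundance gradient (nestedness)
  β_gra = β_BC − β_bal, summarised per sampling unit; and SCBD, each
  species' share of the total among-unit sum of squares.
- **Interspecific association**: the variance-ratio test
  VR = S_T²/δ_T² with W = VR·N against chi-square bounds, and pairwise
  Spearman screening with multiplicity control.
- **Inference**: PERMANOVA on Bray–Curtis distances and a paired
  permutation contrast that respects the exclosure/control pairing.
- **Synthetic data**: a deterministic hierarchical generator (lognormal
  species-abundance distribution, plot/quadrat patchiness, occupancy
  thinning, Poisson counts) with tunable treatment effects, emulating a
  10-pair, 2500-cell, 52-species design at 9.0 shoots cm⁻² baseline
  density and a 1.7× grazing multiplier.

## Worked example

```r
library(mossdiv)
ds <- simulate_dataset(synthetic_config(seed = 1))

shoot_density(ds, "absence")    # 9.04 shoots / cm^2
shoot_density(ds, "presence")   # 15.26 shoots / cm^2  (~1.7x)

alpha_by_scale(ds, "quadrat")$summary
#   treatment   scale   statistic   mean     se  n
#     absence quadrat    richness 11.500 0.3847 50
#     absence quadrat    evenness  0.268 0.0128 50
#     absence quadrat inv_simpson  3.401 0.2507 50
#    presence quadrat    richness 16.040 0.4571 50
#    presence quadrat    evenness  0.359 0.0130 50
#    presence quadrat inv_simpson  6.592 0.2856 50

per_unit_beta(aggregate_counts(ds, "quadrat"))$summary
#   treatment   scale statistic    mean       se  n
#     absence quadrat   beta_bc 0.45013 0.018234 50
#     absence quadrat  beta_bal 0.43964 0.018486 50
#     absence quadrat  beta_gra 0.01049 0.000635 50
#    presence quadrat   beta_bc 0.39528 0.010548 50
#    presence quadrat  beta_bal 0.38624 0.010813 50
#    presence quadrat  beta_gra 0.00904 0.000591 50

variance_ratio_test(aggregate_counts(ds, "quadrat"), "presence")
# variance ratio VR = 1.194, W = 59.71, N = 50, S = 52
# chi-square bounds (df = N): [34.76, 67.50]; verdict: independent
```

Read as an experiment: grazing raised quadrat richness (11.5 → 16.0),
evenness and inverse Simpson, lowered community dissimilarity
(β_BC 0.450 → 0.395) mostly through reduced turnover (β_bal), and kept
the 1.7× shoot-density contrast — the qualitative pattern the generator
is built to emulate. Turnover dominates nestedness by two orders of
magnitude at this scale.

The whole chain, ending in seven CSV tables and a JSON manifest, runs
with:

```r
run_pipeline(pipeline_config(seed = 1, output_dir = "mossdiv_out"))
```

or from a shell via the thin wrapper
`inst/scripts/mossdiv-pipeline.R` (`simulate` and `analyze`
subcommands).

See `vignettes/multiscale-moss-diversity.Rmd` for the model details,
generator assumptions and numerical choices.

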
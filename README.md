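# hescale

Cross-study standardization of microsatellite expected heterozygosity.

## The problem

Expected heterozygosity (He = 1 − Σp², with p the allele frequencies of a
locus) is the workhorse diversity statistic of population genetics, but it is
not comparable across studies that genotyped different microsatellite panels:
the same population typed with highly polymorphic loci shows a higher He than
when typed with less polymorphic ones. Meta-analyses that pool He across
publications therefore confound demographic signal (population size, glacial
refugia, post-glacial expansion routes) with marker choice, and panels
developed in one part of a species range are often more polymorphic there
(ascertainment or "discovery" bias), which can invert apparent geographic
gradients.

`hescale` standardizes He so that multi-study meta-datasets can be analyzed
together. For a locus with at most K alleles whose most frequent allele has
frequency M, homozygosity H = Σp² is constrained to a theoretical interval

    (KM² − 2M + 1)/(K − 1)  ≤  H  ≤  1 − M(⌈M⁻¹⌉ − 1)(2 − ⌈M⁻¹⌉M)

Min–max scaling places each observed H inside its interval,

    H_scaled = (H − h_min) / (h_max − h_min),      scaled He = 1 − H_scaled,

and scaled He is averaged over loci per population. Because the interval
captures exactly the part of He's range that is fixed by panel polymorphism
(K, M), the scaled statistic is comparable across panels.

The package is aimed at population geneticists compiling multi-study
microsatellite datasets (the motivating application is the European beech
*Fagus sylvatica* literature) and provides the full downstream analysis:

- GENEPOP / long-format genotype readers, allele frequencies, per-cell
  K, M, H, He summaries, multi-study merging with locus aliasing, and
  panel-similarity clustering of studies (`read_genepop()`,
  `allele_frequencies()`, `locus_population_summary()`, `merge_studies()`,
  `cluster_studies_by_loci()`);
- theorem-based bounds and scaling (`theoretical_h_bounds()`,
  `scale_cell()`, `scaled_he()`), with an exhaustive enumeration oracle
  (`enumerate_h_given_m()`);
- geographic gradient analysis — Spearman correlations of a per-population
  metric against latitude, longitude, and great-circle distance from a
  hypothesized expansion origin (`gradient_analysis()`), plus
  Kruskal–Wallis and Dunn–Bonferroni panel-effect tests;
- resampling bias-validation scenarios that split populations
  geographically or randomly and loci by polymorphism or randomly, then
  compare raw vs scaled gradients (`run_bias_scenarios()`);
- inverse-distance-weighted interpolation (power 5, 2 × 2 block averaging)
  with polygon masking, leave-one-out cross-validation and jackknife
  confidence intervals (`interpolate_surface()`, `loo_cross_validate()`,
  `jackknife_intervals()`);
- a synthetic range-expansion generator with planted diversity gradients
  and polymorphism "kits" for bias injection (`simulate_meta()`), and an
  end-to-end pipeline (`run_pipeline()`).

## Worked example

```r
library(hescale)

# a synthetic meta-dataset: 85 populations, 20 loci, with the
# high-polymorphism kit assigned to populations far from the origin
sim <- simulate_meta(synthetic_config(seed = 1, kit_assignment = "by_distance"))
sc  <- scaled_he(sim$meta)
pops <- sim$meta$populations
idx  <- match(pops$population_id, sc$populations$population_id)

gradient_analysis(pops, sc$populations$mean_raw_he[idx],    metric_name = "raw")
gradient_analysis(pops, sc$populations$mean_scaled_he[idx], metric_name = "scaled")
```

```
# A tibble: 3 × 6
  metric correlate               r_s       p     n method
1 raw    latitude              0.189 0.0826     85 t-approximation
2 raw    longitude            -0.243 0.0250     85 t-approximation
3 raw    distance_from_origin  0.338 0.00158    85 t-approximation
# A tibble: 3 × 6
  metric correlate                r_s        p     n method
1 scaled latitude              0.0140 8.99e- 1    85 t-approximation
2 scaled longitude             0.292  6.78e- 3    85 t-approximation
3 scaled distance_from_origin -0.657  8.51e-12    85 t-approximation
```

The planted truth is a *negative* He–distance gradient, but the distal
populations were typed with the more polymorphic kit, so raw mean He
*increases* with distance (r_s = 0.34, a spurious ascertainment artifact).
After scaling, the true decline reappears (r_s = −0.66, p ≈ 9e−12). A single
worked cell: with K = 3 alleles and M = 0.4 the bounds are
[0.34, 0.36]; an observed H = 0.345 scales to H_scaled = 0.25, scaled
He = 0.75.

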
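---
title: "Standardizing expected heterozygosity across microsatellite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing expected heterozygosity across microsatellite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hescale)
```

## The model

Expected heterozygosity at a locus, $He = 1 - \sum_a p_a^2$, depends on two
very different things: the demographic history of the population (what a
meta-analysis wants to measure) and the polymorphism of the marker itself
(what it wants to ignore). `hescale` separates the two with a theorem about
the homozygosity $H = \sum_a p_a^2$: if a locus carries at most $K$ alleles
and its most frequent allele has frequency $M$, then

$$\frac{KM^2 - 2M + 1}{K - 1} \;\le\; H \;\le\;
  1 - M\left(\lceil M^{-1}\rceil - 1\right)\left(2 - \lceil M^{-1}\rceil M\right).$$

The lower bound is attained when the remaining mass $1 - M$ is spread evenly
over the other $K - 1$ alleles; the upper bound when as many alleles as
possible sit at frequency $M$ with one remainder allele. Both bounds are
functions of the panel-determined quantities $(K, M)$ only. Min–max scaling

$$H_{scaled} = \frac{H - h_{min}}{h_{max} - h_{min}}, \qquad
  \text{scaled } He = 1 - H_{scaled}$$

therefore expresses each cell's homozygosity as a position inside the range
that its own marker permits, and the per-population mean of scaled He is
comparable across panels of different polymorphism. The theorem's premise is
Hardy–Weinberg proportions; strong departures (null alleles, inbreeding,
genotyping artifacts) are outside the model.

`theoretical_h_bounds()` implements the closed forms and
`enumerate_h_given_m()` verifies them independently: it enumerates every
frequency vector on a 0.01-step simplex grid of length $K$ with maximum
entry $M$ (about 2.4 million vectors for $K \le 8$) and confirms that all
enumerated $H$ lie inside the interval and that both endpoints are
approached. The enumeration is written in C++ because it is a literal
brute force, not a formula.

### Degenerate cells

The interval collapses ($h_{max} = h_{min}$, detected at $\varepsilon =
10^{-12}$) exactly when $K \le 2$, $M = 1$, or $M = 1/K$: a biallelic or
monomorphic cell's $H$ is fully determined by $M$, so it carries no
information about where the population sits inside its marker's range.
By default such cells are excluded from the per-population average
(`degenerate_policy = "exclude"`): any imputed constant would re-introduce a
signal proportional to panel composition, which is precisely the artifact
being removed. `degenerate_policy = "midpoint"` (0.5 per degenerate cell) is
available for sensitivity analysis.

### Which K enters the bounds

The theorem speaks of "at most $K$ alleles", and two readings are
defensible: the allele count observed in the cell itself, or the allele
count of the locus in the study. The package defaults to the study-wide
count (`k_mode = "study"`; the number of distinct alleles observed for the
locus across all the study's populations, falling back to the maximum
per-cell count when raw frequencies are unavailable). The reason is
empirical and reproducible with the package's own generator: at realistic
sample sizes (10–20 diploid individuals, i.e. 20–40 gene copies) the
per-cell observed count is a strongly downward-biased, sample-size-dependent
estimate of the locus's allele count. Conditioning the bounds on it couples
the interval to sampling noise and flattens the scaled statistic's response
to true diversity to near zero — mean scaled He moves only about 0.05 across
a 0.25-unit range of target He, versus about 0.25 with the study-wide count.
With per-cell K, the bias-reversal validation below fails outright; with
study-wide K it is decisive. `k_mode = "cell"` remains available for
comparison.

Observed $H$ values that fall outside the bounds by more than $10^{-9}$
indicate internally inconsistent inputs and raise an error; smaller
excursions (rounding of published frequencies) are clipped to the interval.
$He$ is the plain Gini–Simpson complement $1 - \sum p^2$ without a
small-sample correction, because the bounds constrain exactly $\sum p^2$;
gene-copy counts are carried through so a corrected variant can be layered
on later.

## Data model and merging

Genotypes enter via GENEPOP or a long-format table (one row per individual
× locus). A genotype with either allele missing is treated as fully
missing: a half-call cannot enter allele counts without biasing $M$.
Per-cell summaries are computed from observed frequencies with missing
calls excluded from the denominator, and cells with no observations are
absent rather than zero-filled. Merging applies a user-supplied locus alias
table (the same marker often appears under variant names across
publications); identity is deliberately a curation input, not an inference.
Loci with unusually low polymorphism are retained — cell-level degeneracy
handling replaces locus-level filtering. Studies can be clustered by
locus-panel Jaccard similarity (average linkage, cut 0.5) to define the
panel groups used in panel-effect tests.

## Gradient analysis and test primitives

Under a post-glacial expansion from a refugial origin, diversity is
expected to decay with distance from the origin; `gradient_analysis()`
correlates a per-population metric with latitude, longitude and
great-circle distance from a configurable origin. The default origin
(46.05° N, 14.5° E, the Slovenian eastern Alps) follows the
palaeoecological hypothesis for European beech; no exact canonical
coordinates exist, so distance-based results should be read at
sign/trend level.

Distances use the haversine formula on a sphere of radius 6371.0088 km
(IUGG mean, via `geosphere`); ellipsoidal refinements are irrelevant at the
method's resolution. Spearman's $r_s$ is the Pearson correlation of average
ranks; its two-sided p-value uses the $t$ approximation ($df = n-2$) for
$n \ge 10$, exact enumeration of all $n!$ permutations for $n \le 8$, and a
seeded $10^5$-draw Monte-Carlo permutation at $n = 9$. Kruskal–Wallis tests
delegate to `stats::kruskal.test` (with the all-equal edge case defined as
$H = 0$); Dunn's post-hoc z-tests with tie correction and Bonferroni
adjustment are provided for pairwise panel comparisons.

## Bias-validation scenarios

`run_bias_scenarios()` reproduces the resampling design used to probe
ascertainment bias: populations are split into two groups (median split on
latitude or longitude with ties going south/west, or a seeded random
balanced split), loci are partitioned into low/high polymorphism halves
(ranked by global mean He — the quantity whose bias is under study — with
allele-count then name as tie-breaks, the middle locus of an odd panel
going to "low") or into random halves, and each population group is
restricted to one locus group before raw and scaled mean He and their
gradients are recomputed. Seven scenarios are tabulated (complete dataset
plus the 3 × 2 split grid, 3 correlates × 2 metrics each). In the
polymorphism scenarios the more polymorphic half goes to the southern,
eastern, or arbitrary-B group. All seeds are explicit inputs recorded in
the report, and scenario execution is a pure function of (data, seed).

## Spatial interpolation

The interpolated surface is block-averaged inverse-distance weighting:
each 0.5° cell (configurable) averages predictions at 2 × 2 regularly
spaced sub-points, with weights $d^{-5}$ in kilometres. Weighting in
ground distance rather than degrees keeps weights isotropic at high
latitude; the power default of 5 gives strongly local surfaces. Queries
within $10^{-9}$ km of a data point return that point's value (ties: their
mean), so the interpolator is exact at data sites, and all predictions are
convex combinations of observations. Leave-one-out cross-validation
reports residuals and RMSE, with co-located points excluded from each
other's donor sets to prevent self-prediction leakage. Jackknife
confidence intervals compute, per grid cell, pseudo-values
$\theta_i = n\,s_{full} - (n-1)\,s_{-i}$ over the $n$ delete-one surfaces
and report $t_{0.975,\,n-1}\,sd(\theta)/\sqrt{n}$ half-widths. Masks are
closed GeoJSON rings combined under the even–odd rule with boundary points
counted inside. Variogram-based kriging is deliberately out of scope: the
procedure implemented is distance weighting with a block average, and it
is documented as such.

## The synthetic generator

`simulate_meta()` builds meta-datasets with the statistical structure the
analysis assumes, so every stage is testable without external data:

- 85 populations of 10–20 diploid individuals at 20 loci (defaults),
  placed uniformly over a European window (lon −5…25, lat 40…55);
- a planted linear He decay of 0.08 per 1000 km from the origin, starting
  at 0.70, with population-level Gaussian jitter (sd 0.02);
- locus kits of differing polymorphism: by default a low kit ($K = 4$,
  target-He offset −0.05) and a high kit ($K = 12$, +0.05) covering half
  the panel each — a separation large enough to drive a raw-He bias while
  staying inside a realistic He band;
- allele frequencies drawn from a symmetric Dirichlet whose concentration
  is calibrated in closed form, $\alpha = He/(K(1-He)-1)$, so that the
  *expected* He of a draw equals the target (verified by Monte Carlo);
  targets are clipped to $(0.01,\, 1 - 1/K - 0.01)$ with clipping logged;
- genotypes as two independent draws per individual (Hardy–Weinberg),
  allele index $k$ mapped to fragment length $100 + 2k$.

`kit_assignment` controls bias injection: `"all"` types every population
with every locus, `"random"` gives each population one kit at random (an
unbiased control), and `"by_distance"` gives populations beyond the median
distance the high-polymorphism kit — the discovery-effect construction.
Everything is deterministic given the mandatory seed.

A symmetric Dirichlet was chosen over coalescent simulation because the
claims under test concern He summaries, not genealogies, and the closed
form provides an exact expectation to test against. What the generator does
*not* emulate: skewed real microsatellite allele-frequency spectra,
mutation models, linkage, migration, null alleles and genotyping error, and
spatial clustering of sampling effort. Passing tests therefore demonstrate
that the pipeline removes the polymorphism artifact it models, not that
every real-data artifact is removable.

Two quantitative notes on the generator at its default settings, measured
with the package's own oracles: the truth model itself (slope 0.08/1000 km
against jitter sd 0.02 over the default window) has a Spearman
He–distance correlation of about −0.82, not arbitrarily close to −1; and
genotype sampling at 10–20 individuals attenuates the recovered
per-population gradient (raw mean He $r_s \approx -0.5$, scaled
$\approx -0.35$ with a single shared kit). The test suite asserts these
oracle-derived magnitudes rather than nominal ones.

## Validation signatures

Three end-to-end signatures, each evaluated over 20 seeds at the default
conditions, define success for the method:

1. **Bias reversal.** With the high-polymorphism kit assigned distally and
   a planted negative gradient, raw mean He correlates *positively* with
   distance while scaled mean He correlates *negatively* with $p < 0.01$.
2. **Unbiased control.** With random kit assignment, raw and scaled
   distance correlations agree in sign.
3. **Variance reduction.** With identical populations typed by both kits,
   the Kruskal–Wallis statistic between kit groups is strictly smaller on
   scaled than raw values.

`scripts/acceptance.R` recomputes all three rates, plus the
bounds-enumeration check and the interpolation and calibration contracts,
from scratch under a caller-supplied seed.

## Numerical choices and limitations

- $\varepsilon = 10^{-12}$ for degeneracy, $10^{-9}$ for bound violations;
  both configurable. $\lceil M^{-1}\rceil$ uses a $10^{-9}$ fuzz so exact
  grid reciprocals do not tip to the next integer.
- Frequency-table cells must sum to 1 within $10^{-6}$ (renormalized), a
  tolerance for publication rounding.
- Problem sizes in tests and the acceptance script: 20 seeds per
  simulation signature at the full default scale (85 × 20), smaller
  (16 × 6, 2° cells) for pipeline determinism and interpolation checks —
  sizes at which every property is already stable.
- Scaling removes the component of He differences attributable to $(K, M)$;
  real target-He differences between kits (the generator's offsets) are
  partially retained by design — scaled values still measure diversity.
- Distance-from-origin analyses depend on an origin that is a modelling
  choice; only signs and trends are interpretable.
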
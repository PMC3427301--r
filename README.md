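# fragsar

Landscape-scale species–area relationships under late-stage habitat
fragmentation.

## The problem

In the late stage of habitat fragmentation, total habitat area and the
number of habitat patches decline *together* as whole patches are
eliminated. The classic species–area relationship (SAR), fitted patch
by patch, cannot separate the effect of losing area from the effect of
*fragmentation per se* — the changing spatial configuration (patch
number, patch size variability, shape complexity, isolation) of the
habitat that remains.

`fragsar` implements a landscape-scale analysis of this problem for
island systems (one row of attributes plus a species presence/absence
list per island):

1. **Stratified landscape resampling.** Random subsets of islands are
   drawn without replacement for every patch number `PN = 2 … 50`, with
   subset total areas stratified over five equal-width sections of a
   common admissible range, 200 replicates per cell — an ensemble of
   49,000 simulated fragmented landscapes whose area distributions
   overlap across patch numbers.
2. **Landscape-scale SAR (LSAR).** For each landscape, species lists of
   member islands are pooled; for each patch number, ordinary least
   squares of `log10(S)` on `log10(A)` across its 1,000 landscapes
   estimates the power law `S = c·A^z`. The resulting z-versus-PN
   series measures how sensitive landscape richness is to total
   habitat amount at each fragmentation level.
3. **Null incidence models.** RDM redraws each island's species
   identities uniformly from the pool while preserving the island's
   observed richness; OWRDM weights the draws by observed species
   occupancy. Comparing observed, RDM and OWRDM z-series isolates the
   contribution of inter-specific differences.
4. **Threshold detection.** A two-segment continuous piecewise
   regression of z on PN locates the breakpoint ψ separating the
   *stable* phase (many patches, z low and flat) from the *responsive*
   phase (few patches, z rising steeply as patches are lost).
5. **Attribution.** Spearman and partial Spearman rank correlations
   (Bonferroni-corrected) relate landscape attributes — total Area,
   PN, patch size variability (PSV), landscape shape index
   (LSI = E/minE), mean distance to mainland (MDM) — to richness and
   z; two-set variation partitioning on adjusted R² splits the
   variation in z between Area and the fragmentation-per-se set
   {PN, PSV, LSI, MDM} within each phase.

A synthetic archipelago generator emulating a subtropical land-bridge
island system (152 islands with a bottom-heavy size spectrum,
383 species, roughly two thirds of them "rare" at the ≤10%-occupancy
cutoff, patch-scale SAR slope near z = 0.16) makes the entire pipeline
reproducible and testable without any field data.

## Worked example

```r
library(fragsar)
set.seed(42)
arch <- generate_archipelago(synth_config())
arch
#> Archipelago: 152 islands, 383 species, 6017 occurrences
#>   area 0.203-86.679 ha, total 567.037 ha

table(classify_species(arch)$class)
#>   rare common
#>    252    131

set.seed(43)
ens <- build_ensemble(arch, sampler_config(n_reps = 50))
ens
#> Landscape ensemble: 12250 landscapes, pn 2-50, 5 area sections over
#> [15.99, 148.71] ha

zs <- z_series(ens, list(observed = arch))
head(zs[, c("pn_level", "z", "mean_richness")], 3)
#>   pn_level          z mean_richness
#> 1        2 0.12648208        99.012
#> 2        3 0.11017692       119.936
#> 3        4 0.08367241       136.068

fit <- fit_piecewise(zs$pn_level, zs$z)
fit
#> Piecewise fit: psi = 10.46, slopes -0.00938 | 0.0001021, R2 = 0.879,
#> p = 1.24e-20

phase_varpart(ens, zs, fit)
#>        phase   frac_a    frac_b frac_c frac_d     n
#> 1 responsive 0.000275 -0.000136  0.838  0.162  2250
#> 2     stable 0.005286 -0.005208  0.112  0.888 10000
```

Reading the output: with 252 of 383 species rare, landscape z falls
from 0.126 at two patches toward near zero as patch number grows; the
breakpoint near PN ≈ 10 splits the series into a responsive phase —
where fragmentation per se (`frac_c`, here 84%) rather than area
(`frac_a`, ≈0%) explains the variation in z — and a stable phase where
little variation remains to explain (`frac_d`, 89% unexplained).

`run_fragmentation_analysis(run_config(...), outdir)` chains every
stage (generation or CSV input, classification, resampling, null
models, z-series, breakpoints, correlation tables, variation
partitioning) and writes all result tables plus a reproducibility
manifest. A thin command-line front end with the same stages as
subcommands lives in `inst/cli/fragsar.R`.

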
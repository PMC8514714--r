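# ylineage

Diachronic Y-chromosome STR analysis: forensic diversity indexes,
Bayesian pairwise TMRCA estimation, and paternal-line continuity testing
between ancient and modern males of the same community.

## What it is for

When ancient male remains (e.g. crypt burials dated to a 300–500 year
window) and present-day men from the same village are typed on a Y-STR
panel, their haplotypes — transmitted father to son, altered only by
mutation — can answer two questions:

* **How discriminating is the panel in this community?** Per-locus gene
  diversity `GD = n(1 − Σxᵢ²)/(n−1)`, haplotype diversity
  `HD = n(1 − HMP)/(n−1)` with haplotype match probability
  `HMP = Σpᵢ²`, and discrimination capacity `DC = #distinct/n`,
  computed on the 27-series Yfiler Plus panel and on its 17-series
  Yfiler projection, with compatibility clustering of partial
  (degraded-DNA) profiles.
* **Which ancient men have modern paternal relatives?** For each
  ancient–modern pair, a Bayesian posterior over the time `t`
  (generations) to their most recent common paternal ancestor:
  `posterior(t) ∝ prior(t) · L(t)`, with per-locus IAM likelihood
  `(1−μᵢ)^{2t}` for matches and `1−(1−μᵢ)^{2t}` for mismatches (a
  stepwise alternative is included), a geometric prior with mean λ, and
  — because the pair is non-contemporary — the separation `2t`
  generations, converted to years at 33 years/generation. A pair shows
  *continuity* when its 50% credible interval overlaps the chronological
  window; an ancient individual is continuous when any modern partner
  qualifies.

Two-population structure (AMOVA FST on lineage labels, RST on squared
repeat distances, permutation p-values), panel/locus conventions
(DYS389b, multi-copy splitting, duplication handling), qPCR degradation
indexes, a seeded forward genealogy simulator, and a one-call pipeline
(`run_all()`) complete the toolkit.

## Worked example

```r
library(ylineage)

village <- simulate_village(simulation_config(seed = 42))
haps    <- filter_by_missing(village$haplotypes, 3)

haplotype_diversity(cluster_haplotypes(haps))
#> HD  = 0.9316
#> HMP = 0.1150
#> DC  = 0.5500
#> (n = 20, 11 distinct haplotypes)
```

Twenty individuals survive the three-missing-loci filter; they carry 11
distinct haplotypes, and two random individuals share one with
probability 0.115. A same-lineage ancient–modern pair, 16 true
generations apart:

```r
d <- difference_vector(haps, "L3G03I3", "L3G15I4")
d
#> L3G03I3 vs L3G15I4: 24 series compared, 2 mismatch(es)
#>    DYS437 (-1), DYS438 (-1)

yrs <- to_years(generations_separating(
  tmrca_walsh(d, default_mutation_rates())))
yrs
#> TMRCA posterior (IAM, years) for L3G03I3 vs L3G15I4
#>   mean 804.7, median 726, mode 528
#>   50% CI: [462, 1056]
#>   95% CI: [198, 1914]

assess_pair(yrs)$verdict   # 50% CI [462, 1056] overlaps [300, 500]
#> [1] TRUE
```

Two mismatches over 24 shared series place the common ancestor a few
hundred years back; the 50% interval reaches the 300–500-year window, so
the pair is flagged. Summarised over all pairs:

```r
tm <- tmrca_pairs(haps, default_mutation_rates(),
                  from_pop = "RP_A", to_pop = "RP_M")
continuity_matrix(tm)
#> Continuity vs window [300, 500] years (decisive CI 50%):
#>   6 of 6 ancient individuals show continuity
```

Cross-lineage pairs (11+ mismatches in this village) land thousands of
years back and are never flagged — the discrimination the estimator is
built for.

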
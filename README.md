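# gsikit

Genetic stock identification (GSI) with GT-seq microhaplotype panels.

Mobile marine fishes such as Pacific cod mix across management boundaries
outside the spawning season. To ask *which spawning stock is present
where*, practitioners genotype a few hundred amplicon loci
(genotyping-in-thousands, GT-seq) on mixture samples of unknown origin and
assign them against a baseline of spawning-site reference collections.
`gsikit` implements that analysis chain end to end, with synthetic-data
generators so every stage is testable without access to restricted data:

* **Panel design** — a four-step, FST-ranked downsampler over a per-locus
  pairwise-FST landscape: top-10 loci per chromosome per pairwise
  comparison, deduplication, an FST ≥ 0.2 floor, then 6 equal windows × 2
  loci per chromosome with at most one locus per comparison per
  chromosome (276 candidates on a saturated 23-chromosome genome, plus
  supplemental loci).
* **Microhaplotype calling** — per-cell depth (≥ 20 reads) and depth-ratio
  (≥ 0.2) rules, strict two-pass 75%/75% missingness filtering and a
  collection-majority Hardy–Weinberg locus filter.
* **Population genetics** — Weir–Cockerham θ (multi-allelic, per-locus and
  genome-wide), exact/Monte-Carlo HWE tests, a permutation linkage screen.
* **Mixture inference** — the conditional Pella–Masuda mixture model via a
  seeded Gibbs sampler: for mixture individual *i* with genotype *G_i*,

      z_i | π  ~  Categorical(π_c · P(G_i | c)),
      π | z    ~  Dirichlet(1/C + counts(z)),

  with P(G|c) a Hardy–Weinberg product over loci under the collection's
  Dirichlet-posterior-mean allele frequencies. Outputs are mixing
  proportions, per-individual reporting-unit posteriors, z-score
  diagnostics, a > 0.9-confidence / |z| < 5 filter, and leave-one-out
  simulated-mixture accuracy assessment.
* **Movement tests** — Pearson chi-square on season × (local/non-local)
  assignment tables with 5000-replicate Monte-Carlo p-values.

## Worked example

```r
library(gsikit)

model    <- random_population_model(n_loci = 120, n_pops = 4, fst = 0.05, seed = 1)
freqs    <- draw_population_freqs(model, seed = 2)
baseline <- gsi_baseline(simulate_baseline(freqs, n_per_pop = 40, seed = 3))
mix      <- simulate_mixture(freqs,
                             c(pop01 = 0.5, pop02 = 0.3, pop03 = 0.2, pop04 = 0),
                             n_individuals = 200, seed = 4)
fit <- infer_mixture(baseline, mix$genotypes, mcmc_config(seed = 5))
fit
#> gsi_mixture_result: 200 individuals, 4 collections, 120 loci
#> # A tibble: 4 × 2
#>   repunit      pi
#>   <chr>     <dbl>
#> 1 pop01   0.495
#> 2 pop02   0.269
#> 3 pop03   0.235
#> 4 pop04   0.00124
```

The posterior mixing proportions track the *realized* composition of the
200 sampled individuals (here slightly off the nominal 0.5/0.3/0.2/0
because of sampling), and `pop04` — absent from the mixture — is correctly
driven to ~0. Every individual is assigned to its true unit:

```r
flt <- confidence_filter(fit)              # > 0.9 posterior, z in (-5, 5)
nrow(flt$retained)                         #> 200 (none excluded)
mean(fit$indiv$map_repunit ==
       mix$truth$true_repunit[match(fit$indiv$indiv, mix$truth$indiv)])
#> 1
```

A seasonal movement test compares the mixture's local-assignment counts
against a winter reference:

```r
winter <- tibble::tibble(map_repunit = rep(c("pop01", "pop02", "pop03", "pop04"),
                                           each = 40))
ct <- build_contingency(flt$retained, winter, region = "pop01", site = "demo")
movement_tests(list(ct), seed = 6)
#> # A tibble: 1 × 6
#>   site  region statistic    p_value method     signif_code
#> 1 demo  pop01       22.5 0.00000209 asymptotic ***
```

Half of the summer sample assigns locally versus a quarter of the winter
reference, so the shift in composition is highly significant.

`run_pipeline()` chains the full simulate → FST → select-panel →
call-haplotypes → infer → movement-test sequence and writes CSV artifacts
plus a seed/hash manifest.

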
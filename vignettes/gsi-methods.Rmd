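---
title: "Methods: panel design, microhaplotype calling and mixed-stock inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, microhaplotype calling and mixed-stock inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsikit)
```

`gsikit` implements the analysis chain behind amplicon-panel (GT-seq)
genetic stock identification of marine fishes: ranking candidate loci from
a pairwise-FST landscape, calling multi-allelic microhaplotype genotypes
from read counts, assigning mixture individuals to reporting units with a
Bayesian mixture model, and testing seasonal shifts in stock composition.
This vignette documents the models, the parameters that matter, and the
design decisions taken where the methodology leaves choices open.

## Synthetic data model

All pipeline stages are exercised against simulated data with known ground
truth, so the generators are first-class, tested code.

**Population divergence.** Populations diverge from a shared ancestral
allele-frequency vector $\mathbf{p}$ under the Balding–Nichols model: each
population's frequency vector is drawn from
$\mathrm{Dirichlet}\!\big(\mathbf{p} \cdot (1-F)/F\big)$, so that a
biallelic frequency has mean $p$ and variance $p(1-p)F$. This is the
standard simulation model for GSI benchmarking because its analytic
moments give independent oracles for the FST estimator and for the
generators themselves. The degenerate ends are handled explicitly: $F = 0$
returns the ancestral vector verbatim, and at $F \to 1$ (where gamma draws
underflow) the limiting categorical-over-corners distribution is
substituted. $F = 1$ itself is rejected.

**Marker model.** The default marker set emulates a microhaplotype panel:
178 loci spread over 23 chromosomes, 2–8 alleles per locus with
geometrically decaying weights (mean ≈ 3.5 alleles per locus, matching the
multi-allelism reported for amplicon microhaplotype panels), and skewed
ancestral frequencies (one or two common haplotypes plus rare ones). The
default baseline holds 4 reporting units at between-unit $F_{ST} = 0.05$
with 50 diploids per collection — the information content the package's
accuracy benchmarks are anchored to.

**Read counts.** Per individual and locus, total depth is negative
binomial (default mean 100, dispersion 5; `Inf` selects Poisson) because
empirical amplicon depth is overdispersed. Reads split 50/50 between the
two true haplotypes; with probability `error_rate` (default 0.005) a read
is reported as a uniformly chosen other haplotype at the locus. Allocation
is a single multinomial draw, so haplotype counts always sum to the drawn
total. What this generator does *not* emulate: index hopping, allele-
specific amplification bias, paralogous co-amplification and alignment
artefacts. Tests passing on simulated reads therefore validate the
filtering logic, not robustness to those real-data failure modes.

**FST landscapes.** Panel selection consumes a per-locus, per-pair FST
table directly, so users can substitute tables computed upstream from real
data (e.g. from genotype likelihoods). The simulated landscape offers a
`"saturated"` configuration (every selection window contains at least two
eligible loci with distinct maximising pairs — selection returns its
ceiling), an `"all_below_0.2"` starvation configuration, and a random
background.

## Weir–Cockerham FST and the other core statistics

Per-locus pairwise differentiation is the Weir & Cockerham (1984) $\theta$
from called genotypes, extended to multi-allelic loci by summing the
$a$, $b$, $c$ variance components over alleles before the ratio
$\theta = \sum_a a / \sum_a (a+b+c)$. Multi-locus values
(`genomewide_fst()`) are ratios of summed components, never averages of
ratios. Negative per-locus estimates are retained for ranking. Upstream
analyses of low-coverage data often use SFS-based estimators from genotype
likelihoods instead; since this package works from called genotypes,
$\theta$ is the deliberate genotype-based analogue, and only
rank-consistency (not numerical equivalence) with SFS estimators is
relied on by the selection stage.

Hardy–Weinberg testing uses the exact conditional test for biallelic loci
(two-sided by probability ordering) and a Monte-Carlo exact test for
multi-allelic loci: the pooled $2n$ alleles are re-paired at random
(default 10,000 permutations) and compared on the conditional probability
of the genotype configuration, with the add-one rule $p = (1+b)/(B+1)$.
Like all exact conditional tests, the biallelic test is discrete and
conservative — its p-values are *sub*-uniform under the null, and the
package's calibration tests assert uniformity on the multi-allelic
Monte-Carlo path (the one the default microhaplotype markers actually
take) and validity, not uniformity, on the biallelic path.

The linkage screen reduces each locus to the dosage of its most frequent
allele and flags same-chromosome pairs by squared dosage correlation with
a permutation p-value (default 999 shuffles, add-one rule). This is a
simpler decision rule than multilocus association indices, chosen because
it has the same decision function (flag linked pairs at a chosen level),
an obvious null, and an exactly testable type-I rate.

## Panel selection

The four-step downsampler converts an FST landscape into a candidate
panel:

1. per chromosome and pairwise comparison, keep the `top_n` (default 10)
   loci by that comparison's FST;
2. deduplicate;
3. drop loci whose **maximum** FST across comparisons is below the floor
   (default 0.2);
4. split each chromosome into `windows_per_chrom` (default 6) equal
   *physical* windows and keep up to `loci_per_window` (default 2) loci
   per window, at most one locus per attributed comparison per
   chromosome.

Open choices resolved here: the floor is interpreted against the locus's
maximum pairwise FST, because the stated rationale for the filter is that
comparisons with very low overall differentiation should not eject loci
that are informative elsewhere; windows are equal physical intervals
$[iL/W, (i+1)L/W)$ (the last closed at $L$) with lengths supplied per
chromosome; a locus's *attributed pair* is its argmax-FST comparison (ties
to the lexicographically first pair id); and the one-pair-per-chromosome
constraint is resolved greedily in descending score order across the whole
chromosome, ties broken by lower position then locus id. The greedy order
makes the procedure deterministic; it is score-maximal on instances like
the documented same-pair window case but is not guaranteed to maximise
total score in general, which is acceptable because the goal is a
deterministic, explainable spread of informative loci, not an optimum.
With defaults on a saturated 23-chromosome landscape the output is exactly
$6 \times 2 \times 23 = 276$ candidates; supplemental loci (e.g. markers
tagging known inversion-like regions of concentrated differentiation) are
then unioned in, with duplicates rejected loudly.

## Microhaplotype genotype calling

Per individual-locus cell, with defaults: a cell with fewer than 20 total
reads is missing; haplotypes below 0.2 of the top haplotype's depth are
dropped; two or more survivors call a heterozygote for the two
deepest (second-place ties broken lexicographically and flagged), a single
survivor calls a homozygote. The 20-read minimum is interpreted as *total
cell depth* (the microhaplot convention): a per-haplotype floor of 20
would make the 0.2 ratio rule nearly vacuous at typical depths. More than
two survivors is flagged (`extra_haplotypes`) as possible contamination or
paralogy but still calls the top two.

Missingness filtering is two-pass and strictly ordered: individuals at
call rate $> 0.75$ are kept first, then loci at $> 0.75$ of the
*remaining* individuals — both inequalities strict, so exactly 75% fails.
The filter is idempotent. The HWE filter then removes a locus if it is out
of equilibrium ($p <$ 0.05) in at least `floor(n_collections/2) + 1`
collections (8 when there are 15, reproducing the published rule);
collections with fewer than 5 called individuals at the locus are excluded
from the count rather than counted as conforming, since they carry no
power either way.

## The mixture model

Assignment uses the conditional (Pella–Masuda) mixture model. Baseline
allele frequencies per collection are fixed at their Dirichlet-posterior
means with prior $1/A_\ell$ per allele at a locus with $A_\ell$ alleles:
$\hat f = (\mathrm{count} + 1/A_\ell)/(2n + 1)$. Genotype likelihoods are
Hardy–Weinberg products across loci ($p^2$, $2pq$), missing loci
contributing factor 1. The Gibbs sampler alternates
$z_i \mid \pi \sim \mathrm{Cat}(\pi_c \, P(G_i \mid c))$ and
$\pi \mid z \sim \mathrm{Dirichlet}(1/C + \mathrm{counts})$, default 2000
sweeps with 100 discarded; reported mixing proportions are post-burn-in
means and per-individual posteriors are Rao-Blackwellised sweep averages.
Reporting-unit quantities are sums over member collections. The fully
Bayesian variant that resamples baseline frequencies is out of scope. All
chains are seeded and bit-reproducible. A practical note on the degenerate
regime: with uninformative data the chain's marginal for $\pi$ is its
prior, which at parameter $1/C$ is heavy-tailed and slow-mixing, so tests
of that limit average long chains.

The z-score diagnostic standardises each individual's observed
log-likelihood under its MAP collection against the analytic mean and
variance of the genotype log-probability under Hardy–Weinberg draws from
that collection's posterior-mean frequencies (all $A(A+1)/2$ genotypes
enumerated per locus, loci independent, restricted to the individual's
called loci). Frequencies here include the individual — the z-score is a
diagnostic for "not from any baseline population", not an assignment
quantity. $\sigma = 0$ (all called loci monomorphic) yields an undefined,
flagged z. Assignment filtering keeps individuals with maximum unit
posterior strictly above 0.9 and z strictly inside $(-5, 5)$.

Leave-one-out assessment simulates mixtures by resampling baseline
individuals: unit proportions from $\mathrm{Dirichlet}(1.5)$ (the
conventional weakly-informative choice for simulated mixing proportions,
configurable), collections within units likewise, individuals with
replacement. When a resampled individual is scored against its own source
collection, that collection's posterior-mean frequencies are recomputed
with the individual's two alleles removed — without this the benchmark is
optimistically biased, and the package's tests assert that disabling it
can only raise measured accuracy. Accuracy is MAP reporting unit versus
truth, reported both over all individuals and within the $>0.9$
confidence filter.

## Seasonal movement tests

Each summer mixture site is compared to its region's winter reference on a
2×2 season × (assigned-locally / not) table with Pearson's $X^2$ (no
continuity correction). When any expected count is below 5 — or when
forced — the p-value is simulated with 5000 replicates and the add-one
rule, so the smallest attainable p is $1/5001$, i.e. 0.0002 at four
decimals. Replicates fix both margins (`stats::r2dtable`), the convention
of `chisq.test(simulate.p.value = TRUE)`; an unconditional
multinomial-given-total sampler is available as an option, but it is not
the default because its $X^2$ reference is wider than $\chi^2_1$ and its
p-values do not track the asymptotic test on large tables. Significance
bands follow the reporting convention NS ($p > 0.05$), `*` ($p < 0.05$),
`**` ($p < 0.01$), `***` ($p < 0.001$).

## Numerical and testing choices

Tolerances: frequency vectors must sum to 1 within $10^{-9}$; posterior
vectors within $10^{-6}$. Ties are always broken deterministically
(position, then lexicographic id) so identical inputs and seeds give
byte-identical outputs. Every stochastic function takes an explicit
integer seed.

The calibration suites run at sizes chosen to keep Monte-Carlo error well
inside the asserted bands on a single CPU: FST bias is checked at 500 loci
and $n = 100$ per population across $F \in \{0.01, 0.05, 0.1\}$
(asserted $|\mathrm{bias}| < 0.02$); mixing-proportion recovery over 20
Dirichlet draws at $n = 400$ and 150 loci (RMSE $< 0.03$); HWE null
uniformity over 2000 multi-allelic locus tests with 800 permutations each;
the accuracy benchmark over 50 simulated mixtures of 200 individuals on
the 178-locus, 4-unit default baseline (2000 sweeps). At that information
content the filtered leave-one-out accuracy is effectively at ceiling
(≥ 99.9% across seeds), comfortably above the 97% working floor used as
the benchmark's pass line.

## Known limitations

* The model assumes Hardy–Weinberg and linkage equilibrium within
  collections; the linkage screen flags violations but the likelihood does
  not model them.
* Baseline allele frequencies are fixed at posterior means (conditional
  model); uncertainty in small collections is therefore understated, which
  mainly affects z-scores for individuals from thinly sampled collections.
* The synthetic read model omits several real amplicon failure modes (see
  above); genotype-caller concordance numbers from simulation are upper
  bounds on real-data performance.
* Windowed selection needs chromosome-anchored loci; unplaced scaffolds
  must be assigned pseudo-chromosomes by the user.
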
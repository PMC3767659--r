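---
title: "Colony sociogenetics and population structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony sociogenetics and population structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociogen)
```

## The biological model

`sociogen` analyses the sociogenetic organisation of ants (and other social
Hymenoptera) in which each colony is headed by a single, multiply mated
queen. Under haplodiploidy, females (queens, workers, alate gynes) are
diploid and males are haploid. Every worker therefore carries one maternal
allele and one paternal allele at each codominant locus, which makes three
inferences possible from colony genotype samples alone:

1. **Queen reconstruction.** Under strict monogyny every worker shares at
   least one allele with the queen at every locus. When the queen was not
   collected, her two-allele genotype per locus can be reconstructed from
   the workers.
2. **Patriline partitioning.** Removing the maternal contribution leaves
   each worker's paternal allele; workers sharing a compatible haploid
   paternal genotype across all loci form a patriline. The minimum number
   of haploid father genotypes explaining all workers is the observed
   mating frequency `M_p`.
3. **Parentage classification.** Haploid males carrying only queen alleles
   are queen's sons; a male with a non-queen allele is a worker's son
   (arrhenotoky). Diploid females identical to the queen everywhere are
   compatible with thelytokous (clonal) production; one non-queen allele
   proves sexual production.

## Estimators

**Effective paternity.** Because fathers contribute unequally, the absolute
count `M_p` overstates the genetically effective number of matings. The
package uses the sample-size-corrected estimator

$$M_{e,p} = \frac{(n-1)^2}{\sum_i p_i^2\,(n+1)(n-2) + 3 - n},$$

with `n` offspring scored and `p_i` the proportional contribution of father
`i`. With equal contributions and large `n` it converges to the father
count; for small `n` it can exceed it (bias correction), which the tests
check numerically at `n = 10^6`.

**Non-detection probabilities.** Two males carrying identical alleles at
all `J` loci are indistinguishable; that probability is
$\prod_j \sum_i f_{ij}^2$ over population allele frequencies `f`. A
worker's son mimics a queen's son when he inherits the queen-derived allele
at every informative locus, with probability $\sum_i p_i (1/2)^{l_i}$,
where `l_i` counts the loci at which patriline `i`'s paternal allele
differs from both queen alleles. The definition of "informative locus" is
not fixed by convention; this package's definition (paternal allele known
and absent from the queen genotype) is a recorded package decision.

**Relatedness.** Pairwise regression relatedness follows the symmetric
Queller-Goodnight estimator. Reference allele frequencies are estimated
from one randomly drawn diploid individual per colony — family structure
makes nestmates pseudo-replicates — and exclude the focal colony (bias
correction). Colonies are weighted equally: the point estimate is the mean
over colonies of the within-colony ratio of summed numerators to summed
denominators, and the standard error is a delete-one-colony jackknife.
Expected values under the pedigree model: queen-worker 0.5; full sisters
0.75; nestmate workers $0.25 + 0.5\sum_i p_i^2$; a queen's mates 0.

**F-statistics.** `weir_cockerham_fstats()` implements the Weir-Cockerham
(1984) variance-components estimators with nests as demes, summed over
alleles and loci; the jackknife is over loci and the 95% interval is a
seeded bootstrap over loci. With colonies as demes, family structure makes
F_IS strongly negative (an excess of heterozygotes relative to the nest
"population"), which is the sampling design this package mirrors; the test
suite asserts the sign, not a field magnitude, because raw field
genotypes of this kind are generally unpublished.

**Exact tests.** Hardy-Weinberg tests are conditional exact tests: full
enumeration of heterozygote counts for biallelic configurations, otherwise
a Monte-Carlo conditional-probability test. Linkage disequilibrium and
pairwise colony differentiation use permutation G tests on genotype
contingency tables, combined across loci by Fisher's method, with a
Bonferroni threshold of `alpha / n_pairs`. All permutation p-values use the
`(count + 1)/(N + 1)` convention, so a permutation p of exactly 0 is
impossible.

**Spatial statistics.** `clark_evans_R()` tests complete spatial
randomness of nest coordinates from the nearest-neighbour distance ratio.
"Sinclair's correction" in the field literature is implemented as the
Donnelly boundary correction — the correction Sinclair (1985) recommends —
because no formula is printed in the source material; both corrected and
uncorrected ratios are reported. Isolation by distance uses
`F_ST/(1-F_ST)` against `ln` distance, tested by a Spearman-rank Mantel
test with simultaneous row/column permutation. Because the statistic is
rank-based it is invariant to monotone transforms, so testing against raw
distance is equivalent to testing against `ln` distance; pairs at zero
distance or with `F_ST = 1` are excluded and counted.

**Haplotype analyses.** Sequences are collapsed to haplotypes by exact
identity (N-ambiguous sequences join the first compatible haplotype in
input order — a deterministic, order-dependent rule). Distances are
uncorrected p-distances over mutually non-N sites, reported at full
precision internally and rounded to two decimals for table parity.
The median-joining network uses the Bandelt scheme with `epsilon = 0` and
Hamming connection costs: iterated minimum-spanning-network construction,
majority-consensus median vectors for linked triplets (ties resolved
alphabetically), and pruning of unobserved nodes that are leaves or
equal-cost pass-throughs. AMOVA follows the Excoffier-Smouse-Quattro
framework on squared distances; substitution counts and
microsatellite allele-mismatch counts are used directly as squared
distances (the Arlequin convention). Negative variance components are
reported as computed, with an optional truncate-at-zero percentage mode.
Permutation schemes per level: individuals among populations (Phi_ST),
individuals among populations within groups (Phi_SC), whole populations
among groups (Phi_CT).

## The synthetic world

The generator emulates the kind of field system the analyses expect:

* 7 microsatellite loci with 4-13 alleles each; allele frequencies from a
  symmetric Dirichlet with concentration 1 (uninformative; configurable).
  Allele codes are integer "sizes" in base pairs and are labels only.
* Strictly monogynous colonies whose queens mate with 1-5 males with
  unequal contributions; 8-20 genotyped workers per colony; optional
  queen-son males, worker-son males (queenless colonies only), sexually
  produced alate females, and clonal females for degenerate-case tests.
* Nest coordinates under complete spatial randomness (or grid/Thomas
  cluster processes) in a square plot; colony genotypes are independent
  across nests, matching the no-viscosity finding the analyses assume.
* A two-group mitochondrial transect: group founders separated by
  `mutation_steps_between` substitutions at disjoint sites (default 14,
  a typical deep split between regional haplotype groups), each haplotype adding
  `mutation_steps_within` private substitutions, 622 bp, gap-free.

What a green test does **not** establish: the generator has no null
alleles, no genotyping error, no mutation within colonies, no polygyny, no
spatial autocorrelation of genotypes and no recombination structure, so
tests certify the estimators under the stated model, not robustness to
violations of it.

Design choices taken where the design was genuinely open:

* **Queen tie-break.** Among queen genotypes that are co-optimal under the
  minimum-`M_p` criterion, the published tie-break convention
  (lexicographic) selects wrong queens often enough to make simulation
  recovery poor. The package ranks co-optimal queens by a pedigree
  log-likelihood — queen genotype at Hardy-Weinberg proportions, one
  empirical-frequency draw per father haplotype (not per worker), and a
  binomial maternal-transmission term at heterozygous queen loci — and
  uses lexicographic order only as the final determinism guarantee. Exact
  recovery in simulation is ~95-98% with 12-16 workers and 7 loci.
* **Patriline search.** Exact minimisation by depth-first search with
  identical-profile deduplication, an admissible per-locus lower bound and
  iterative deepening; equal contributions across integer compositions
  cannot always hit a target skew exactly, so skew-targeted simulations
  draw per-worker fathers multinomially (the dyad-level probability of
  sharing a father then equals the target exactly).
* **Paternity shares at** $\sum p_i^2 = 0.365$ use `p = (0.45, 0.35,
  0.20)`, giving the closed-form nestmate expectation
  `0.25 + 0.5 * 0.365 = 0.4325`.
* **Permutation defaults** are 10,000 for Mantel, 10,000 for the G-test
  chains, 2,000 Monte-Carlo draws per multi-allelic HWE test; every
  stochastic stage of the pipeline requires an explicit seed and at least
  999 permutations.
* The Wilcoxon statistic `W` is the rank sum of the first sample, exact by
  enumeration up to a combined n of 25, then a tie-corrected normal
  approximation with continuity correction. The Yates correction is capped
  at `|O - E|` so an exactly independent table scores 0.

## A worked example

```{r example, eval = FALSE}
panel <- make_locus_panel(7, c(4, 13), seed = 1)
col <- simulate_colony(panel, colony_spec(16, c(8, 5, 3)), seed = 2,
                       colony_id = "N001")
ped <- colony_pedigree(col$genotypes, "N001",
                       panel_freqs = lapply(panel, `[[`, "frequencies"))
ped$m_p      # minimum father count
ped$m_e_p    # effective paternity
ped$p_nondetect_two_males
```

## Known limitations

* Queen reconstruction enumerates cross-locus candidate combinations; the
  exact search is capped (status `"not_solved"` beyond the cap) rather
  than falling back to a heuristic.
* The median-joining implementation targets the small haplotype sets of
  regional mtDNA surveys (tens of haplotypes); it is not tuned for
  hundreds of sequences, and the maximum-parsimony post-pruning step of
  some network programs is not implemented because it is not publicly
  specified.
* GENEPOP output covers the package's own dialect (title, locus lines,
  `Pop` blocks, 6-digit diploid codes); extended dialect variants are out
  of scope.
* The AMOVA treats haplotype distances as fixed quantities; no model-based
  distance corrections are applied.
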
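---
title: "Methods: pedigree-based genetic monitoring of a recolonizing wolf population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based genetic monitoring of a recolonizing wolf population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolfped)
```

## The problem

Wolves recolonizing a human-dominated landscape are monitored almost
entirely through non-invasive samples — scats, hair, urine, saliva traces —
whose DNA is degraded and dilute. Microsatellite genotypes called from such
material suffer allelic dropout (one allele of a heterozygote fails to
amplify) and occasional false alleles. The monitoring questions, however,
are pedigree questions: who bred with whom, where, in which monitoring
year; how related are the breeders; how fast is the population of
reproducing pairs growing; which sex disperses among packs. `wolfped`
implements this entire chain with explicit, testable rules, and ships a
simulator that generates populations with known truth so every stage can be
validated.

## Consensus genotyping (multiple-tube approach)

Each sample is amplified in several PCR replicates. At each locus a
heterozygote allele pair is accepted only if the identical pair was seen in
at least `het_min = 2` replicates; a homozygote only if seen in at least
`hom_min = 3` replicates with no accepted heterozygote at that locus; a
genotype is accepted only with at least `min_loci = 10` typed loci. These
are the standard thresholds of the multiple-tube protocol for scat-quality
DNA: a single dropout-affected replicate can never create a false
homozygote, because homozygotes need three concordant observations. Two
*distinct* supported heterozygotes at one locus indicate contamination or a
mixed sample; the locus is voided with a warning rather than resolved by
majority, because non-invasive data must never fabricate an allele.

## Individual identification

Accepted consensus genotypes are grouped into individuals by transitive
matching: two genotypes match when they are comparable (both typed) at no
fewer than 8 loci and mismatch at no more than `max_mismatch_loci = 1` of
them. The tolerance of one locus absorbs the dominant residual error mode —
a single dropout that survived consensus — which field data show operates
at the scale of one allele at one locus per genotype. Matching is computed
on the full pairwise graph and grouping takes connected components, so the
result is independent of input order by construction. A candidate match
that would imply three distinct alleles at one locus is refused and flagged
for manual review instead of merged.

With 13 loci of moderate diversity the multilocus probability of identity
(`probability_of_identity()`) is far below one over the population size,
and the sibling variant PIDsib is the conservative bound actually used to
justify the match criterion.

## Sex and mtDNA

Sex is called from two sex-chromosomal markers: male requires the Y-linked
marker in at least two replicates; female requires the X-linked marker in
two replicates and no Y amplification at all; everything else — including a
single Y observation — is UNKNOWN. The id suffix (`...m`/`...f`) is treated
as advisory; the marker call wins with a warning on conflict.

Control-region haplotypes are assigned by exact identity over the
overlapping window, because the two primer systems in routine use yield 250
bp and 390 bp fragments of the same region: a query matching a reference,
or contained in it, is assigned; one mismatch is NO_MATCH. No alignment or
distance threshold is used — the reference panel is small and curated, and
a non-matching sequence should be examined, not auto-assigned.

## Pedigree, kinship and inbreeding

Parentage is exclusion-based: a candidate breeding pair survives if the
offspring's alleles can be split so that one is transmissible from each
parent at all but at most `max_mendelian_mismatches = 1` of the comparable
loci, and candidates are pre-filtered by territory activity years and
(optionally) distance to the sampling site. A likelihood sibship model is
deliberately not used: in territorial, socially monogamous packs the
candidate set is small and monitoring data carry most of the information,
so transparent exclusion plus spatio-temporal constraints is both simpler
and auditable.

Kinship uses the tabular recursion (equivalent to the Meuwissen–Luo
algorithm for inbreeding): with individuals ordered parents-first,

$$f(i,i) = \tfrac12\,(1 + f(s_i, d_i)), \qquad
  f(i,j) = \tfrac12\,(f(s_i, j) + f(d_i, j)),$$

with unknown parents contributing zero. The inbreeding coefficient of a
pair's offspring is the kinship of the parents, $F_p = f(\text{sire},
\text{dam})$. Two conventions matter:

* **Unknown parents are distinct unrelated founders.** They are never
  merged, so $F_p$ is a lower bound — immigrants of unknown origin may in
  reality be related.
* **Reported values are rounded half-up to 3 decimals** (so 0.0625 prints
  as 0.063). All kinship values are dyadic rationals ($k/2^m$) and are
  represented *exactly* in double precision for any realistic pedigree
  depth, so no separate rational-arithmetic path is needed; tests compare
  exactly after rounding.

A monitoring year runs May 1 – April 30 (pups are born late April/May) and
is labeled by its starting calendar year. A litter is one pair in one
monitoring year; published year ranges expand to one litter per year, a
rule validated against the independently reported litter total of the
bundled dataset.

## The bundled German 2005–2015 fixture

The package ships the table of the 76 genotyped German breeding pairs
2005–2015 (`germany_breeding_pairs()`) and a pedigree
(`germany_pedigree()`) encoding each breeder's parentage. The table itself
only names each breeder's natal pack; where a pack had several successive
breeding pairs, the pedigree file assigns the breeder to the litter that is
(a) temporally consistent with its age at first breeding and (b) the unique
choice reproducing all 76 published inbreeding coefficients. The founder
generation (the first territory, active 2000–2004, whose female bred with
two successive males) is fixed the same way: two of the three breeders born
there must share both parents and the third only the mother — the only
split compatible with the published coefficients. `fixture_report()`
recomputes every summary (breeder counts by origin and sex, litter counts,
bond lengths, inbred-litter fractions, yearly pair counts, growth rate) and
compares them to the published values.

## Trends and growth

Mann–Kendall's S with tie-corrected variance, ±1 continuity correction and
a normal-approximation p-value, plus Sen's median-of-pairwise-slopes, serve
as the trend test for the short (11-point) yearly series; no autocorrelation
correction is applied at that length. `growth_fit()` fits
$N(t) = N_0 e^{rt}$ two ways: nonlinear least squares on the counts and OLS
on log counts, reporting both. On the bundled fixture these differ
materially (the late, large counts dominate the NLS objective), and only
the log-linear estimator — applied to the full series since the first
reproduction in 2000 — reproduces the published annual growth rate within
the stated fit-method tolerance; the acceptance checks therefore use the
log-linear value, and both remain available to the user.

## Dispersal and sex bias

Dispersal distance is the WGS84 Vincenty geodesic between the centroids of
the natal territory and the territory of first reproduction (later
reproductions are ignored); philopatric breeders (distance 0) can be
included or excluded. The sex ratio is tested against parity by the
closed-form chi-square $(n_f - n_m)^2/(n_f + n_m)$, df = 1, without
continuity correction; distances by the Wilcoxon rank-sum test with the
rank-sum-minus-$n_1(n_1{+}1)/2$ convention for W, midranks, and the
tie-corrected normal approximation.

Sex-biased dispersal among packs is tested with the corrected assignment
index: $AI_i$ is the log10 Hardy–Weinberg probability of individual $i$'s
multilocus genotype under the sample's own allele frequencies, centered to
$AIc$; the dispersing sex accumulates immigrants and shows a lower mean
$AIc$. The statistic $mAIc(F) - mAIc(M)$ gets a two-sided permutation
p-value with the add-one estimator $(b+1)/(n+1)$; the permutation seed is a
mandatory argument. Note the identifiability caveat verified in the test
suite: if *all* members of both sexes come from two cleanly separated
pools, the pooled-frequency AI carries no signal — the test detects
*asymmetric admixture* (one sex containing more immigrants), which is the
biological situation it is designed for.

## Core areas

Recolonization proceeded from a few distant founding territories.
`assign_core_areas()` formalizes the "smallest spatial and temporal
distance" idea as a greedy rule with temporal precedence: territories are
processed in founding order and join the area of the nearest
already-assigned territory not younger than themselves; distance ties break
by founding-year gap, then label order; a maximum-distance cutoff leaves
outliers unassigned. This is this package's own formalization of a rule the
field literature states only verbally; it is pluggable. Minimum convex
polygons are computed in an equirectangular projection about the regional
centroid — at sub-10° extents the projection error is negligible against
centroid uncertainty.

## The simulator: what it emulates, and what it does not

`simulate_recolonization()` generates the stated world used throughout the
tests: immigrants arrive as unrelated founders (default 2 per year), mature
dispersers pair and found territories (founding probability 0.5 per couple
per year, exponential dispersal kernel with mean 70 km), every complete
pair whelps one litter per year (truncated Poisson, mean 4), breeder
mortality 0.15 per year, and vacant breeding slots are refilled
male-biasedly (male slots from outside with probability 0.8; female slots
from outside with probability 0.4, else by a resident daughter with
probability 0.5) — encoding the observed pattern that males immigrate into
established packs while females are more philopatric. Genotypes descend by
Mendelian segregation from founder frequencies (13 loci, 4–8 uniform
alleles); mtDNA is maternal; no mutation is modeled at this timescale.
`simulate_sampling()` then applies the error process: per replicate and
locus, whole-locus failure (0.05), heterozygote dropout (0.1), and false
alleles shifted by one repeat unit (0.01) — a deliberately simple artifact
model.

The simulator does **not** model landscape resistance, prey availability,
variable territory sizes, multiple paternity, or genotyping artifacts
beyond dropout/false alleles (no stutter, no null alleles). A green
end-to-end test therefore establishes that the pipeline's rules are
mutually consistent and recover truth under the stated error model — not
that real samples behave this ideally. Parameter-recovery claims are
calibrated accordingly (100% recovery at zero noise, ≥95% at default
noise).

## Numerical choices

* Allele frequencies count gene copies (2 per typed genotype); unbiased
  expected heterozygosity uses the gene-copy correction
  $\frac{n}{n-1}(1-\sum p_i^2)$, which equals the probability that two
  copies drawn *without replacement* differ — the identity used as an
  independent oracle in the tests.
* Rarefied allelic richness uses the hypergeometric expectation
  $E[A(g)] = \sum_i \big(1 - \binom{n-n_i}{g}\big/\binom{n}{g}\big)$
  computed on the log scale, exact at $g = n$.
* The HWE test replaces the classical MCMC exact test with an
  allele-permutation Monte Carlo using the heterozygote count as statistic
  and a two-sided doubled-tail p-value: same null, fully specified, and
  deterministic given its seed.
* Permutation p-values everywhere use the add-one estimator, so they are
  valid at any permutation count.
* Mean-over-loci summaries are unweighted arithmetic means; multilocus
  identity probabilities are products over loci (independence assumption).
* p-values across loci and years are reported raw, without multiplicity
  correction, matching standard monitoring practice of reporting counts of
  raw p < 0.05.

## Known limitations

Fragmentary genotypes completed from relatives (a practice in real
monitoring for selected samples) are not replicated — such samples are
flagged for review instead. Mixed samples beyond the two-heterozygote
refusal rule are out of scope. Published genotype-level statistics of the
original monitoring dataset (multilocus PID, the rank-sum W, the mAIc
values) are not reproduced because the underlying raw genotypes are not
bundled; they are covered by closed-form and property-based checks
instead.
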
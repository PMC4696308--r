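---
title: "Methods: the SSR genomic landscape survey and its population-genetic companion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SSR genomic landscape survey and its population-genetic companion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

# Scope

`ssrscape` implements a two-part analysis of simple sequence repeats
(SSRs, microsatellites) in an annotated genome:

1. **Survey arm** — exhaustive detection of perfect 1–6 bp tandem repeats,
   classification of every locus into nine positional categories relative
   to gene models, size-standardized densities, a chi-square test of
   non-random placement, and gene-term over-representation among
   SSR-bearing genes.
2. **Population-genetics arm** — for haploid multilocus microsatellite
   genotypes scored in two species: allelic diversity, allele-difference
   distances, three-level hierarchical AMOVA with Φ-statistics and
   permutation tests, per-locus Fst and island-model gene flow, principal
   coordinates analysis, and variance-ratio comparisons of locus
   categories (OUT / UP / IN / DOWN).

Because the original genotype matrix of this kind of study is rarely
deposited machine-readably, the package ships simulators for both arms
that generate data with complete ground truth, so every stage is
verifiable end to end.

# Survey arm

## Perfect SSR detection

A locus is a maximal perfect tandem run of a primitive motif (one that is
not a whole-number power of a shorter string). The detector reports a run
when its number of *complete* motif copies reaches the per-unit-length
threshold; defaults are 14 (mono), 7 (di), 5 (tri) and 4
(tetra/penta/hexa) copies, the classic perfect-mode search profile for
fungal genome surveys. Conventions, chosen where a perfect-mode scanner
leaves latitude:

- A run qualifying under several periods is reported once, at its
  smallest primitive period (`ATATATAT` is an AT run, never an ATAT run).
  Primitivity of the motif plus the copy thresholds make the smallest
  period unique (a second, incompatible period over a span of at least
  four copies would force a shorter common period).
- Trailing partial copies are excluded from the span and the count —
  complete-copy counting is the conservative reading of "perfect".
- `N` and any other non-ACGT code break runs; soft-masked lowercase is
  uppercased and scanned.
- Adjacent distinct loci are reported independently; there is no
  compound-SSR merging. In the rare case where two same-period runs would
  share a base after truncation, the later run restarts after the earlier
  one, keeping same-period loci disjoint.
- Coordinates are 1-based inclusive throughout, matching GFF3.

Motifs are *fully standardized*: the canonical representative of a motif
class is the lexicographically smallest string among all cyclic rotations
of the motif and of its reverse complement. This collapses the 60
primitive trinucleotides into the familiar 10 families (AAC … CCG).

## Positional categories

Nine categories tile every scaffold position exactly once: `EXON`
(CDS-overlapping), `UTR5`, `UTR3`, `INTRON`, upstream/downstream flanks
within 50 bp (`UP_0_50`, `DOWN_0_50`) and within 50–500 bp (`UP_50_500`,
`DOWN_50_500`) of the transcript edge, and `DISTAL` beyond 500 bp.

Rules, in decreasing precedence:

- Genic sequence wins over any neighbouring gene's flank. Within genic
  sequence the precedence is EXON > UTR5 > UTR3 > INTRON; "exon" means
  CDS-overlapping sequence because exons and UTRs are scored as distinct
  regions. When UTR features are absent they are derived as exon minus
  CDS, split 5′/3′ around the CDS by strand. Introns are the transcript
  span minus its exons. Transcripts with no CDS are skipped with a
  warning — without a CDS the exon/UTR split is undefined.
- Flank bins are strand-aware (upstream is the 5′ direction of the
  transcript) and measured from the transcript's outermost coordinate,
  with closed bins d ∈ [1, 50] and d ∈ [51, 500].
- Where two transcripts' flanks meet, the *nearer* transcript edge claims
  the position; an exact distance tie resolves in favour of the upstream
  bin. We deliberately rank distance above bin identity: a position 20 bp
  downstream of one gene and 400 bp upstream of another is `DOWN_0_50`,
  not `UP_50_500`. A fixed bin-priority list that ignores distance would
  make the nearest-gene rule unreachable, which we consider an artefact
  rather than a design.
- SSRs spanning a boundary are classified by their midpoint
  (`(start + end) %/% 2`) — deterministic and symmetric.

Densities are standardized by category size (loci per Mbp, and SSR bp per
Mbp of region), so categories of very different extent are comparable.
The placement test is the textbook chi-square against expectations
proportional to category size, `E_i = n · bp_i / bp_total`, on k−1
degrees of freedom; it requires every expected count to be positive and
instructs merging categories otherwise. Gene-term enrichment is the
one-sided Fisher exact (hypergeometric upper-tail) test per term with
Benjamini–Hochberg control across terms; "FDR" is read as BH since no
specific procedure is mandated by convention in this setting.

# Population-genetics arm

## Distances and AMOVA

Each multilocus haploid genotype is one haplotype. The distance between
two haplotypes is the number of loci at which their alleles differ,
skipping loci missing in either individual. This count — a sum of
per-locus 0/1 mismatches — plays the role of the squared distance
`δ²` in the AMOVA sums of squares:

- `SS_total = (1/N) Σ_{i<j} δ²_ij`
- `SS_within-pop = Σ_p (1/n_p) Σ_{i<j∈p} δ²_ij` (and analogously within
  species); among-strata SS follow by subtraction.
- Degrees of freedom are (G−1, P−G, N−P) for G species, P populations and
  N individuals.

Variance components come from the mean squares with the standard
unbalanced-design coefficients
`n = (N − Σ_g Σ_{p∈g} n_p²/N_g)/(P−G)`,
`n′ = (Σ_g Σ_{p∈g} n_p²/N_g − Σ_p n_p²/N)/(G−1)`,
`n″ = (N − Σ_g N_g²/N)/(G−1)`, giving
`σ²_c = MS_WP`, `σ²_b = (MS_AP − σ²_c)/n`,
`σ²_a = (MS_AG − σ²_c − n′σ²_b)/n″`; in balanced designs these collapse
to `n′ = n` and `n″ = nP`. Φ-statistics:
`Φ_ST = (σ²_a + σ²_b)/σ²_tot`, `Φ_SC = σ²_b/(σ²_b + σ²_c)`,
`Φ_CT = σ²_a/σ²_tot`.

Numerical choices:

- Negative variance components are reported as-is (the Arlequin
  convention); `truncate_negative = TRUE` clamps them at zero.
- If all pairwise distances are zero the Φ-statistics are undefined and
  flagged, never reported as 0.
- Permutation schemes follow the standard hierarchy: Φ_ST permutes
  individuals among all populations, Φ_SC permutes individuals among
  populations within species, Φ_CT permutes whole populations among
  species. P-values use the `(#{perm ≥ obs} + 1)/(n_perm + 1)` estimator;
  the default is 10,000 permutations and a seed is mandatory whenever
  permutations run.

**A granularity caveat worth knowing.** With only a handful of
populations the Φ_CT permutation test is intrinsically coarse: permuting
whole populations between two species with 2 + 3 populations admits only
`C(5,2) = 10` distinct reassignments, and the identity reassignment recurs
with probability 1/10 per draw, so the achievable p-value is bounded near
0.1 *no matter how divergent the species are*. This is a property of the
design, not of the implementation; the Φ_ST and Φ_SC tests, which permute
individuals, do not share it and reach conventional significance easily
under real structure. Studies with few populations should read Φ_CT
significance accordingly.

## Per-locus statistics, gene flow, PCoA, category comparison

Per locus, the package reports the two-level Φ_ST across all populations
(ignoring the species grouping) as that locus's Fst — and, alongside, the
three-level percentage decomposition, since either reading of a
"per-locus Fst" is defensible. Gene flow uses the island-model identity
`Fst = 1/(4Nm + 1)`, inverted for haploids to `2Nm = (1/Fst − 1)/2`;
it is undefined at `Fst ≤ 0`.

PCoA Gower-centres the element-wise squared distance matrix
(`B = −½ J D² J`) and eigendecomposes it; coordinates are eigenvectors
scaled by the square roots of the positive eigenvalues. The decomposition
is delegated to `stats::cmdscale`, which implements exactly this
centering; negative eigenvalues (allele-count distances are generally
non-Euclidean) are excluded with a warning.

Category comparison uses two-sample variance-ratio F-tests on per-locus
variance percentages, with the larger variance in the numerator (so the
test is order-invariant), a two-tailed p-value, and BH adjustment across
the six category pairs; compact letter displays are derived from the
adjusted p-values at α = 0.05. A one-way ANOVA across the four categories
is provided as a companion mean-difference test, since a bare "F-test"
between groups can denote either.

Allelic diversity follows the usual definitions: Na is the count of
distinct alleles, Ne = 1/Σp²_i the effective number of alleles, private
alleles occur in one species only and shared alleles in both. Summary
tables report means with standard errors over loci (a ± value without a
stated convention is read as SE here).

# The simulators

## Genome with planted SSRs

`simulate_genome()` writes a small multi-scaffold genome (default two
30 kb scaffolds, six genes each; genes have a 150 bp 5′UTR, three 300 bp
CDS exons separated by 200 bp introns, and a 200 bp 3′UTR, on random
strands) whose background sequence is rejection-resampled until it
contains *no* SSR at the detection thresholds. Perfect repeats from the
planting table are then written into positions whose midpoint category is
known from the region model, flanking bases are adjusted so each run is
exactly maximal, and the finished genome is re-scanned to prove that the
detected loci equal the planted truth. The default planting covers all
nine categories with trinucleotide loci from the dominant motif families
(ACG, CCG, AGC) plus mono-, di- and tetranucleotide loci, 30 loci in
total. Everything is deterministic given the spec's seed.

What this does *not* emulate: real base composition and repeat-length
distributions, compound or interrupted repeats, nested gene models,
alternative transcripts. Passing the recovery test therefore shows the
scanner and classifier are exact under clean conditions; it says nothing
about mapping artefacts or imperfect repeats, which are out of scope.

## Two-species populations under a bounded SMM

`simulate_populations()` evolves haploid genotypes down a fixed lineage
tree under a strict stepwise mutation model: each branch applies a
Poisson(μ·t) number of ±1 repeat steps, reflecting at category-specific
bounds `[r_min, r_max]`. The default design mirrors the study layout the
popgen arm is built for: 39 trinucleotide loci (11 OUT, 9 UP, 13 IN,
6 DOWN) scored in 51 genotypes — an invasive species with 2 populations
(10 + 10) and a native species with 3 (10 + 10 + 11).

Parameters and defaults, chosen once as a realistic operating point:

| parameter | default | rationale |
|---|---|---|
| μ (steps/generation) | 0.002, all categories | upper range of microsatellite mutation rates; gives per-individual branch expectations of ~0.4 steps, so populations are polymorphic but not saturated |
| `t_species` | 2000 generations | deep enough that most loci differentiate between species (the between-species AMOVA share lands in the tens of percent) |
| `t_pops` | 400 generations | an order of magnitude shallower, giving a small among-population share |
| bounds | OUT [5,60], UP [8,30], IN [6,13], DOWN [5,50] | IN loci get a narrow reflecting range, modelling the size constraint expected inside reading frames; OUT/DOWN are nearly free |
| `founders` | 2 | the invasive species' introduction bottleneck: all its individuals descend from two lineages |
| allele size | repeats × 3 + 90 bp | trinucleotide loci with a constant flank, so all sizes are congruent to the flank modulo 3 |

Two structural choices deserve a note. First, the tree gives population
founders their own branch: species lineages run from `t_species` to
`t_pops`, population-founder lineages from `t_pops` to `t_pops/2`, and
individuals form a star from `t_pops/2` to the present. A three-level
variance hierarchy needs three branch tiers, and halving `t_pops` is the
simplest way to get one from two interpretable split times. Second,
constraint on IN/UP loci is modelled as a reflecting allele range rather
than a selection coefficient — the biological claim being emulated is an
inferred constraint on repeat number, not a fitness model. Narrow ranges
also produce size homoplasy (identical allele sizes of independent
origin), which is exactly why constrained loci understate divergence.

The star-shaped within-population genealogy (no coalescent) keeps the
simulator analytic and fast; it understates allele-frequency correlation
within populations, so the among-population variance share is driven by
founder drift alone. No recombination, admixture or migration is
simulated.

# Verification design and problem sizes

The test suite checks every operation against an independent route:
brute-force all-period scanning for the SSR detector (random sequences up
to 2 kb with permissive thresholds), per-position classification loops
for the region model, explicit-loop SS computation plus a linear solve of
the expected-mean-square system for AMOVA (designs up to 10 individuals),
closed forms for PCoA (equilateral configuration: eigenvalues d²/2, d²/2,
0), the chi-square statistic (counts [10, 30] on equal sizes: X² = 10),
the F(2,2) tail (`P(F > f) = 1/(1+f)`, so F = 4 gives a two-tailed 0.4),
and the hypergeometric tail for enrichment (the [[3,1],[1,3]] table:
p = 17/70). Where an installed package offers the same computation
(`chisq.test`, `fisher.test`, `var.test`, `ape::pcoa`) it serves as a
cross-check, never as the implementation.

Replicated stochastic checks use 100 replicates for permutation power and
200 for the diversity contrasts, with 199–999 permutations per AMOVA —
sizes at which the full suite and the acceptance script each run in a few
minutes on one CPU while leaving the directional conclusions far from
their decision boundaries.

# Known limitations

- The survey arm holds whole scaffolds in memory and the scanner is pure
  R; multi-hundred-Mbp genomes will work but take minutes, not seconds.
- Interrupted, compound and mismatch-tolerant SSR models are out of
  scope, as are primer design and homology-based term assignment (a
  gene-to-term mapping is consumed, not computed).
- Diploid/codominant genotypes, linkage statistics and stepwise-weighted
  (R_ST-style) distances are not implemented; distances are allele
  identity counts.
- The Φ_CT permutation test's granularity floor with few populations is
  discussed above; it is inherent to permuting whole populations.
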
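# ssrscape

Genomic landscape and population genetics of simple sequence repeats
(SSRs, microsatellites) — an R package for the two analyses that together
test whether SSRs are randomly placed in a genome and whether their
genomic context shapes how they evolve:

1. **Survey arm.** Detect every perfect 1–6 bp tandem repeat in an
   annotated genome at MISA-style thresholds (≥14 mono-, ≥7 di-, ≥5 tri-,
   ≥4 tetra/penta/hexanucleotide copies), standardize motifs under cyclic
   rotation and reverse complementation, partition every scaffold
   position into nine categories relative to gene models (exon, intron,
   5′/3′ UTR, flanks within 50 bp and 50–500 bp up/downstream, distal),
   and test placement against size-proportional expectations with a
   chi-square test, `E_i = n · bp_i / bp_total`. Gene-term
   over-representation among SSR-bearing genes uses one-sided Fisher
   exact tests with Benjamini–Hochberg control.
2. **Population-genetics arm.** For haploid multilocus genotypes from
   two species, with loci labelled by genomic context (OUT / UP / IN /
   DOWN): allele-difference distances (δ_ij = number of differing loci),
   three-level hierarchical AMOVA with variance components σ²a/σ²b/σ²c
   and Φ-statistics (Φ_CT, Φ_SC, Φ_ST) tested by the standard permutation
   schemes, per-locus Fst and island-model gene flow via
   Fst = 1/(4Nm + 1), allelic diversity (Na, Ne = 1/Σp²ᵢ, private/shared
   alleles), PCoA of the Gower-centred squared-distance matrix, and
   variance-ratio F-tests comparing locus categories.

Both arms come with simulators — an annotated-genome generator that
plants perfect SSRs with known coordinates and categories, and a
two-species bounded stepwise-mutation-model genotype simulator with a
founder bottleneck — so the whole pipeline runs and is verified without
any external data. See the methods vignette
(`vignettes/ssr-landscape-and-popgen.Rmd`) for the models, parameter
defaults and design decisions.

## Worked example

The numbered scripts under `analysis/` run the full workflow; the same
calls work interactively:

```r
library(ssrscape)

# --- survey arm on a simulated genome -----------------------------------
sim <- simulate_genome(genome_sim_spec(seed = 101))
survey <- run_survey(sim$sequences, sim$annotation)
survey$summary$total_ssrs     # 30
survey$summary$kb_per_ssr     # 2  (60 kb genome / 30 loci)
survey$summary$tally          # intragenic 13, intergenic 17
print(survey$chi_square)
#> Chi-square test of proportional placement: X^2 = 64.27, df = 8, p = 6.718e-11
```

The 30 detected loci equal the planted truth exactly (coordinates,
motifs and categories), and equal per-category planting over
very unequal region sizes is what the chi-square rejects: 3 loci in
1800 bp of 5′UTR is a density of 1667 SSRs/Mbp versus 278/Mbp in exons.

```r
# --- population-genetics arm --------------------------------------------
g <- simulate_populations(pop_sim_spec(seed = 202))$genotypes
pg <- run_popgen(g, n_perm = 10000, seed = 303)
print(pg$amova_overall)
#> Hierarchical AMOVA (species / populations / genotypes)
#>                             stratum df      SS variance    pct
#>                     Between species  1 166.138  5.26753  30.93
#>    Among populations within species  3 114.851  2.87818  16.90
#>  Among genotypes within populations 46 408.618  8.88300  52.16
#>                               Total 50 689.608 17.02871 100.00
#> Phi: PHI_ST = 0.4784, PHI_SC = 0.2447, PHI_CT = 0.3093
#> Permutation p (10000 perms): PHI_ST: 9.999e-05, PHI_SC: 9.999e-05, PHI_CT: 0.1024

mean(pg$locus_stats$fst, na.rm = TRUE)   # 0.394
```

Most variance lies among genotypes within populations, a third between
the species, and a modest share among populations — with mean per-locus
Fst ≈ 0.39. The Φ_CT permutation p of ~0.10 is the granularity floor of
permuting 5 whole populations between 2 species (only 10 distinct
reassignments exist); the individual-level Φ_ST and Φ_SC tests are
maximally significant. The vignette discusses this caveat.

## Layout

- `R/` — the implementation (detection, region model, survey statistics,
  genotype container, AMOVA, PCoA, variance tests, both simulators,
  orchestration).
- `analysis/01…05_*.R` — numbered drivers: simulate genome → survey →
  simulate populations → popgen → category comparison and figures;
  outputs land under `results/`.
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for the scanner, the region classifier and AMOVA.
- `scripts/acceptance.R` — the reproduction script described above.
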
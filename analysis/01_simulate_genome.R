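#!/usr/bin/env Rscript
# Generate the synthetic annotated genome used by the survey arm.
#
# Two 30 kb scaffolds, six protein-coding gene models each, and 30 perfect
# SSRs planted with known coordinates across all nine positional categories
# (trinucleotide ACG/CCG/AGC loci in every category, plus a mononucleotide
# and a dinucleotide locus in distal sequence and a tetranucleotide in an
# intron). Writes FASTA + GFF3 + a ground-truth table under
# results/simulated_genome/.

library(ssrscape)

spec <- genome_sim_spec(seed = 101L)
sim <- simulate_genome(spec, dir = "results/simulated_genome")

cat("Scaffolds:", length(sim$sequences), "x",
    unique(nchar(sim$sequences)), "bp\n")
cat("Planted SSR loci:", nrow(sim$truth), "\n")
print(table(sim$truth$category))
cat("Written to results/simulated_genome/ (genome.fasta, annotation.gff3,",
    "truth.tsv)\n")
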
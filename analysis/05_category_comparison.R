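#!/usr/bin/env Rscript
# Compare locus categories: variance-ratio F-tests on per-locus variance
# percentages, and figures (per-category SSR densities from the survey arm;
# PCoA scatter coloured by species/population from the popgen arm).
#
# Expects results/survey/ and results/popgen/ from the earlier steps.

library(ssrscape)
suppressPackageStartupMessages(library(ggplot2))

ls <- read.delim("results/popgen/locus_stats.tsv")
vt <- category_variance_test(ls$pct_between_species, ls$category)
cat("== Variance-ratio tests on per-locus between-species variance ==\n")
print(vt)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

dens <- read.delim("results/survey/density_by_category.tsv")
dens$category <- factor(dens$category, levels = region_categories())
p1 <- ggplot(dens, aes(category, density)) +
  geom_col(fill = "grey30") +
  labs(x = NULL, y = "SSRs per Mbp",
       title = "Size-standardized SSR density by genomic region") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 45, hjust = 1))
ggsave("results/figures/ssr_density_by_category.pdf", p1,
       width = 7, height = 4)

pc <- read.delim("results/popgen/pcoa_coordinates.tsv")
p2 <- ggplot(pc, aes(Axis1, Axis2, colour = species, shape = population)) +
  geom_point(size = 2.5, alpha = 0.85) +
  labs(title = "PCoA of allele-difference distances") +
  theme_minimal()
ggsave("results/figures/pcoa.pdf", p2, width = 6.5, height = 4.5)

box <- data.frame(category = factor(ls$category,
                                    c("OUT", "UP", "IN", "DOWN")),
                  pct = ls$pct_between_species)
p3 <- ggplot(box, aes(category, pct)) +
  geom_boxplot(fill = "grey80") +
  labs(x = NULL, y = "% variance between species",
       title = "Per-locus between-species variance by category") +
  theme_minimal()
ggsave("results/figures/variance_by_category.pdf", p3,
       width = 6, height = 4)

cat("Figures written under results/figures/\n")
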
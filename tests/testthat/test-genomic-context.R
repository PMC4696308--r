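test_that("region model reproduces the single-gene worked example", {
  # + strand transcript 1001-3000: UTR5 1001-1200, CDS 1201-2800,
  # UTR3 2801-3000 on a 5000 bp scaffold
  ann <- toy_annotation(list(toy_gene("s1", 1001L, "+", utr5 = 200L,
                                      cds = 1600L, utr3 = 200L)))
  model <- build_region_model(ann$gr, c(s1 = 5000L))
  up50 <- model$categories$UP_0_50
  expect_equal(GenomicRanges::start(up50), 951L)
  expect_equal(GenomicRanges::end(up50), 1000L)
  up500 <- model$categories$UP_50_500
  expect_equal(GenomicRanges::start(up500), 501L)
  expect_equal(GenomicRanges::end(up500), 950L)
  distal <- model$categories$DISTAL
  expect_equal(GenomicRanges::start(distal), c(1L, 3501L))
  expect_equal(GenomicRanges::end(distal), c(500L, 5000L))
  expect_equal(sum(model$category_bp), 5000)

  # same gene on the minus strand: upstream bins on the right side
  ann2 <- toy_annotation(list(toy_gene("s1", 1001L, "-", utr5 = 200L,
                                       cds = 1600L, utr3 = 200L)))
  model2 <- build_region_model(ann2$gr, c(s1 = 5000L))
  up50m <- model2$categories$UP_0_50
  expect_equal(GenomicRanges::start(up50m), 3001L)
  expect_equal(GenomicRanges::end(up50m), 3050L)

  # unannotated scaffold is entirely distal
  model3 <- build_region_model(ann$gr, c(s1 = 5000L, s2 = 700L))
  expect_equal(category_at(model3, "s2", 1), "DISTAL")
  expect_equal(category_at(model3, "s2", 700), "DISTAL")
  expect_equal(sum(model3$category_bp), 5700)
})

test_that("region categories tile randomized annotations and match the per-position oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n_genes <- sample(2:4, 1)
    L <- 12000L
    starts <- sort(sample(seq(200L, 9000L, by = 100L), n_genes))
    genes <- list()
    pos <- 100L
    for (i in seq_len(n_genes)) {
      pos <- pos + sample(c(120L, 400L, 900L, 1300L), 1)
      g <- toy_gene("chr", pos, sample(c("+", "-"), 1),
                    utr5 = sample(c(50L, 120L), 1),
                    cds = rep(150L, sample(1:3, 1)), introns = 90L,
                    utr3 = sample(c(40L, 100L), 1))
      if (g$end > L - 600L) break
      genes[[length(genes) + 1L]] <- g
      pos <- g$end
    }
    ann <- toy_annotation(genes)
    model <- build_region_model(ann$gr, c(chr = L))
    expect_equal(sum(model$category_bp), L)
    probe <- sort(unique(c(sample.int(L, 250),
                           unlist(lapply(genes, function(g)
                             c(g$start - 1L, g$start, g$end, g$end + 1L,
                               g$start - 50L, g$start - 51L,
                               g$end + 500L, g$end + 501L))))))
    probe <- probe[probe >= 1L & probe <= L]
    got <- vapply(probe, function(p) category_at(model, "chr", p),
                  character(1))
    want <- vapply(probe, function(p)
      oracle_position_category(p, "chr", ann$txs), character(1))
    expect_identical(got, want, info = paste("replicate", rep))
  }
})

test_that("classify_ssrs assigns by midpoint and tallies intragenic/intergenic", {
  ann <- toy_annotation(list(toy_gene("s1", 1001L, "+", utr5 = 200L,
                                      cds = 1600L, utr3 = 200L)))
  model <- build_region_model(ann$gr, c(s1 = 5000L))
  ssrs <- data.frame(scaffold = "s1",
                     start = c(1250L, 960L, 3090L),
                     end = c(1280L, 990L, 3110L),
                     motif = "ACG", canonical_motif = "ACG",
                     unit_length = 3L, repeat_count = 10L)
  got <- classify_ssrs(ssrs, model)
  expect_equal(got$category, c("EXON", "UP_0_50", "DOWN_50_500"))
  expect_equal(got$intragenic, c(TRUE, FALSE, FALSE))
  expect_equal(attr(got, "tally"),
               c(intragenic = 1L, intergenic = 2L))
  expect_error(classify_ssrs(transform(ssrs, scaffold = "nope"), model),
               "absent")
})

test_that("densities standardize by category size and respect invariants", {
  ann <- toy_annotation(list(toy_gene("s1", 1001L, "+", utr5 = 200L,
                                      cds = 1600L, utr3 = 200L)))
  model <- build_region_model(ann$gr, c(s1 = 5000L))
  ssrs <- classify_ssrs(
    data.frame(scaffold = "s1", start = c(1250L, 1301L), end = c(1279L, 1330L),
               motif = "ACG", canonical_motif = "ACG", unit_length = 3L,
               repeat_count = 10L), model)
  dens <- compute_densities(ssrs, model)
  exon <- dens[dens$category == "EXON", ]
  # 2 SSRs in a 1600 bp category
  expect_equal(exon$ssr_count, 2)
  expect_equal(exon$density, 2 / (1600 / 1e6))
  expect_equal(exon$bp_per_mbp, 60 / (1600 / 1e6))
  expect_equal(sum(dens$ssr_count), nrow(ssrs))
  expect_true(all(dens$density[dens$ssr_count == 0] == 0))

  # 10 SSRs in a 0.5 Mbp category -> 20 per Mbp (direct arithmetic check)
  expect_equal(10 / (5e5 / 1e6), 20)

  # empty SSR set: all densities zero
  empty <- classify_ssrs(ssrs[0, ], model)
  dens0 <- compute_densities(empty, model)
  expect_true(all(dens0$density == 0))
})

test_that("chi-square placement test matches hand computation and chisq.test", {
  # counts [10, 30] in equally sized categories
  r <- chi_square_uniformity(c(a = 10, b = 30), c(a = 1000, b = 1000))
  expect_equal(r$statistic, 10)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, 0.001565402, tolerance = 1e-6)

  # proportional counts give statistic 0, p = 1
  r0 <- chi_square_uniformity(c(a = 10, b = 30),
                              c(a = 1e6, b = 3e6))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # cross-check against stats::chisq.test on an unbalanced case
  counts <- c(a = 12, b = 7, c = 31)
  sizes <- c(a = 5e5, b = 2e5, c = 9e5)
  r2 <- chi_square_uniformity(counts, sizes)
  ref <- suppressWarnings(chisq.test(counts, p = sizes / sum(sizes)))
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p_value, unname(ref$p.value))

  # p decreases monotonically in the statistic at fixed df
  stats_seq <- c(1, 5, 10, 20)
  ps <- pchisq(stats_seq, df = 3, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  expect_error(chi_square_uniformity(c(a = 1), c(a = 10)), "two categories")
  expect_error(chi_square_uniformity(c(a = 1, b = 1), c(a = 10, b = 0)),
               "merge")
})

test_that("term enrichment reproduces hypergeometric tails and BH adjustment", {
  # 2x2 table [[3,1],[1,3]]: one-sided p = 17/70
  g2t <- data.frame(gene_id = c(paste0("g", 1:4), "g5"),
                    term_id = c(rep("T1", 4), "T1"))
  all_genes <- paste0("g", 1:8)
  g2t <- data.frame(gene_id = paste0("g", c(1, 2, 3, 5)),
                    term_id = "T1")
  res <- term_enrichment(paste0("g", 1:4), all_genes, g2t)
  expect_equal(res$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(res$count_in_set, 3L)
  expect_equal(res$count_in_background, 4L)
  # single term: fdr == p
  expect_equal(res$fdr, res$p_value)

  # cross-check against fisher.test one-sided greater
  ref <- fisher.test(matrix(c(3, 1, 1, 3), 2), alternative = "greater")
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)

  # identical frequency in set and background -> p = 1 direction-wise
  g2t_all <- data.frame(gene_id = all_genes, term_id = "T2")
  res2 <- term_enrichment(paste0("g", 1:4), all_genes, g2t_all)
  expect_equal(res2$p_value, 1)

  expect_error(term_enrichment(character(0), all_genes, g2t), "empty")
  expect_warning(term_enrichment(paste0("g", 1:4), all_genes,
                                 rbind(g2t, data.frame(gene_id = "zz",
                                                       term_id = "T9"))),
                 "skipped")
})
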
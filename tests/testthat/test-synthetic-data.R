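test_that("genome simulator is deterministic and recovers planted loci exactly", {
  spec <- genome_sim_spec(seed = 5)
  sim1 <- simulate_genome(spec)
  sim2 <- simulate_genome(spec)
  expect_identical(sim1$sequences, sim2$sequences)
  expect_identical(sim1$truth, sim2$truth)

  # 100% sensitivity, no false positives, exact category assignment
  det <- classify_ssrs(find_ssrs(sim1$sequences), sim1$model)
  expect_equal(nrow(det), nrow(sim1$truth))
  key <- function(df) sort(paste(df$scaffold, df$start, df$end, df$motif,
                                 df$category))
  expect_identical(key(det), key(sim1$truth))

  # per-category counts equal the planting table
  want <- table(sim1$truth$category)
  got <- table(det$category)
  expect_equal(as.list(got), as.list(want))
})

test_that("an empty planting spec yields a genome with no SSRs", {
  spec <- genome_sim_spec(planting = default_planting()[0, ], seed = 2,
                          n_scaffolds = 1L, scaffold_length = 12000L,
                          genes_per_scaffold = 2L)
  sim <- simulate_genome(spec)
  expect_equal(nrow(find_ssrs(sim$sequences)), 0L)
})

test_that("genome simulator round-trips through FASTA/GFF3 files", {
  dir <- withr::local_tempdir()
  spec <- genome_sim_spec(seed = 9, n_scaffolds = 1L,
                          scaffold_length = 20000L,
                          genes_per_scaffold = 4L)
  sim <- simulate_genome(spec, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fasta",
                                               "annotation.gff3",
                                               "truth.tsv")))))
  out <- run_survey(file.path(dir, "genome.fasta"),
                    file.path(dir, "annotation.gff3"))
  expect_equal(out$summary$total_ssrs, nrow(sim$truth))
  expect_equal(sort(paste(out$ssrs$scaffold, out$ssrs$start,
                          out$ssrs$category)),
               sort(paste(sim$truth$scaffold, sim$truth$start,
                          sim$truth$category)))
})

test_that("population simulator is deterministic and respects allele congruence", {
  spec <- pop_sim_spec(seed = 4)
  s1 <- simulate_populations(spec)
  s2 <- simulate_populations(spec)
  expect_identical(s1$genotypes$alleles, s2$genotypes$alleles)

  a <- s1$genotypes$alleles
  # sizes congruent to the flank constant modulo the unit length
  expect_true(all((a - spec$flank_bp) %% spec$unit_length == 0))
  # repeats within the category bounds
  cats <- s1$genotypes$locus_category
  reps <- (a - spec$flank_bp) / spec$unit_length
  for (cat in unique(cats)) {
    b <- spec$bounds[[cat]]
    expect_true(all(reps[, cats == cat] >= b[1] &
                      reps[, cats == cat] <= b[2]))
  }
  expect_equal(dim(a), c(51L, 39L))
  expect_equal(unname(table(cats)[c("OUT", "UP", "IN", "DOWN")]),
               c(11L, 9L, 13L, 6L), ignore_attr = TRUE)
})

test_that("zero mutation rate yields identical genotypes and flagged AMOVA", {
  spec <- pop_sim_spec(mu = c(OUT = 0, UP = 0, IN = 0, DOWN = 0), seed = 6)
  sim <- simulate_populations(spec)
  expect_equal(length(unique(apply(sim$genotypes$alleles, 1, paste,
                                   collapse = ","))), 1L)
  r <- amova(sim$genotypes)
  expect_true(r$flags[["zero_variance"]])
  expect_true(is.na(r$phi[["PHI_ST"]]))
})

test_that("narrow allele bounds depress diversity and founders depress the invasive species", {
  # moderate replicate count here; the acceptance suite runs the full design
  reps <- 40
  res <- vapply(seq_len(reps), function(r) {
    g <- simulate_populations(pop_sim_spec(seed = 7000 + r))$genotypes
    st <- allele_stats(g, "species")
    cat_of <- setNames(g$locus_category, colnames(g$alleles))
    st$category <- cat_of[st$locus]
    c(mean(st$na[st$category == "IN"]),
      mean(st$na[st$category == "OUT"]),
      mean(st$na[st$group == "species1"]),
      mean(st$na[st$group == "species2"]))
  }, numeric(4))
  expect_lt(mean(res[1, ]), mean(res[2, ]))  # IN < OUT
  expect_lt(mean(res[3, ]), mean(res[4, ]))  # bottlenecked < native
})

test_that("mean Phi_CT does not decrease with species divergence time", {
  ts_grid <- c(600L, 2000L, 6000L)
  mean_phi <- vapply(ts_grid, function(ts) {
    phis <- vapply(1:15, function(r) {
      g <- simulate_populations(pop_sim_spec(t_species = ts,
                                             seed = 100 * ts + r))$genotypes
      amova(g)$phi[["PHI_CT"]]
    }, numeric(1))
    mean(phis, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_phi) > -0.02))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(pop_sim_spec(mu = c(OUT = -1, UP = 0, IN = 0, DOWN = 0)),
               "non-negative")
  expect_error(pop_sim_spec(t_species = -5), "non-negative")
  expect_error(pop_sim_spec(ancestral_repeats = c(OUT = 100L, UP = 15L,
                                                  IN = 9L, DOWN = 18L)),
               "bounds")
  expect_error(genome_sim_spec(planting = data.frame(
    category = "EXON", motif = "ACG", repeats = 2L, count = 1L)),
    "thresholds")
  expect_error(genome_sim_spec(planting = data.frame(
    category = "NOPE", motif = "ACG", repeats = 6L, count = 1L)),
    "category")
})
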
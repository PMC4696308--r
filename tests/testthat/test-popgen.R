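make_gm <- function(alleles, pop, sp = NULL) {
  genotype_matrix(matrix(alleles, nrow = length(pop)), pop,
                  if (is.null(sp)) rep("s1", length(pop)) else sp)
}

test_that("allele_stats computes Na, Ne and private/shared partitions", {
  a <- matrix(c(180L, 180L, 183L, 186L), ncol = 1)
  g <- genotype_matrix(a, c("p1", "p1", "p2", "p2"),
                       c("A", "A", "B", "B"))
  st <- allele_stats(g, "species")
  stA <- st[st$group == "A", ]
  expect_equal(stA$na, 1)  # species A: 180, 180
  # all four alleles in one group: Na = 3, Ne = 1/0.375
  pooled <- allele_stats(genotype_matrix(a, c("p1", "p1", "p2", "p2"),
                                         c("A", "A", "A", "A")),
                         "species")
  expect_equal(pooled$na, 3)
  expect_equal(pooled$ne, 1 / 0.375, tolerance = 1e-12)
  # equifrequent alleles: Ne equals the allele count
  g2 <- genotype_matrix(matrix(c(10L, 12L, 10L, 12L), ncol = 1),
                        c("p1", "p1", "p2", "p2"), c("A", "A", "B", "B"))
  st2 <- allele_stats(g2, "population")
  expect_equal(st2$ne, c(2, 2))

  # private/shared partition: A = {180,183}, B = {183,186}
  g3 <- genotype_matrix(matrix(c(180L, 183L, 183L, 186L), ncol = 1),
                        c("p1", "p1", "p2", "p2"), c("A", "A", "B", "B"))
  st3 <- allele_stats(g3, "species")
  expect_equal(st3$private, c(1L, 1L))
  expect_equal(st3$shared, c(1L, 1L))
  # Ne <= Na always
  expect_true(all(st3$ne <= st3$na + 1e-12))
})

test_that("pairwise distances count differing loci with pairwise deletion", {
  a <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L), c(1L, 5L, 6L, 7L))
  g <- genotype_matrix(a, c("p1", "p1", "p2"), c("A", "A", "B"))
  d <- pairwise_distances(g)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 3)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  a[2, 2] <- NA
  gm <- genotype_matrix(a, c("p1", "p1", "p2"), c("A", "A", "B"))
  dm <- pairwise_distances(gm)
  expect_equal(dm[1, 2], 0)  # missing locus skipped
  expect_equal(dm[2, 3], 2)

  a_all_na <- rbind(c(1L, NA), c(NA, 2L))
  expect_error(pairwise_distances(
    genotype_matrix(a_all_na, c("p1", "p2"), c("A", "B"))), "no scored")
})

test_that("AMOVA reproduces the worked fixed-difference and two-population cases", {
  # 2 species x 1 pop x 2 inds, fixed difference: 100% between species
  d <- matrix(1, 4, 4) - kronecker(diag(2), matrix(1, 2, 2))
  r <- amova(d, population = c("p1", "p1", "p2", "p2"),
             species = c("A", "A", "B", "B"))
  expect_equal(r$table$pct[1], 100)
  expect_equal(r$phi[["PHI_ST"]], 1)
  expect_equal(r$phi[["PHI_CT"]], 1)

  # two populations {A,B} and {A,B}: sigma_among = -0.25, Phi_ST = -1
  g <- make_gm(c(180L, 183L, 180L, 183L), c("p1", "p1", "p2", "p2"))
  r2 <- amova(g, use_species = FALSE)
  expect_equal(r2$table$variance[1], -0.25)
  expect_equal(r2$table$variance[2], 0.5)
  expect_equal(r2$phi[["PHI_ST"]], -1)
  # truncation mode clamps the negative component
  r2t <- amova(g, use_species = FALSE, truncate_negative = TRUE)
  expect_equal(r2t$table$variance[1], 0)

  # all-identical genotypes: Phi undefined and flagged, not zero
  g0 <- make_gm(rep(100L, 4), c("p1", "p1", "p2", "p2"))
  r0 <- amova(g0, use_species = FALSE)
  expect_true(r0$flags[["zero_variance"]])
  expect_true(is.na(r0$phi[["PHI_ST"]]))
})

test_that("AMOVA components match the brute-force oracle on random small datasets", {
  set.seed(21)
  for (rep in 1:12) {
    n_pops <- sample(2:4, 1)
    n_sp <- sample(1:2, 1)
    n_ind <- sample(max(2 * n_pops, 5):10, 1)
    g <- random_genotypes(n_ind, sample(2:6, 1), n_pops,
                          if (n_sp > 1 && n_pops > 2) 2L else NULL)
    three <- length(unique(g$species)) > 1
    d <- pairwise_distances(g)
    got <- amova(g)
    want <- oracle_amova(d, g$population,
                         if (three) g$species else NULL)
    k <- length(want$sigma)
    expect_equal(got$table$df[seq_len(k)], want$df)
    expect_equal(got$table$SS[seq_len(k)], want$SS, tolerance = 1e-10)
    expect_equal(got$table$variance[seq_len(k)], unname(want$sigma),
                 tolerance = 1e-10)
    expect_equal(got$phi[!is.na(got$phi)],
                 want$phi[names(got$phi[!is.na(got$phi)])],
                 tolerance = 1e-10)
    # conservation: percentages sum to 100, d.f. to N-1
    expect_equal(sum(got$table$pct[seq_len(k)]), 100, tolerance = 1e-9)
    expect_equal(sum(got$table$df[seq_len(k)]), n_ind - 1L)
  }
})

test_that("balanced designs satisfy the closed-form mean-square coefficients", {
  # G=2 groups, P=2 pops/group, n=3 inds/pop: n' = n, n'' = nP
  set.seed(8)
  g <- random_genotypes(12, 4, 4, 2)
  d <- pairwise_distances(g)
  fit <- amova(g)
  sig <- fit$table$variance[1:3]
  df <- fit$table$df[1:3]
  SS <- fit$table$SS[1:3]
  MS <- SS / df
  n <- 3; P_per_g <- 2
  expect_equal(MS[3], sig[3], tolerance = 1e-10)
  expect_equal(MS[2], sig[3] + n * sig[2], tolerance = 1e-10)
  expect_equal(MS[1], sig[3] + n * sig[2] + n * P_per_g * sig[1],
               tolerance = 1e-10)
})

test_that("permutation p-values behave under structure and its absence", {
  set.seed(31)
  # strongly structured: two species fixed for distant allele sets
  a <- cbind(c(rep(10L, 10), rep(20L, 10)),
             c(rep(11L, 10), rep(25L, 10)),
             sample(c(5L, 6L), 20, replace = TRUE))
  g <- genotype_matrix(a, rep(c("p1", "p2", "p3", "p4"), each = 5),
                       rep(c("A", "B"), each = 10))
  r <- amova(g, n_perm = 199, seed = 4)
  expect_lt(r$p_values[["PHI_ST"]], 0.05)
  # permutations are reproducible given the seed
  r2 <- amova(g, n_perm = 199, seed = 4)
  expect_identical(r$p_values, r2$p_values)
  expect_error(amova(g, n_perm = 10), "seed")

  # unstructured data: p should not be systematically small
  g0 <- random_genotypes(16, 5, 4, 2)
  r0 <- amova(g0, n_perm = 99, seed = 9)
  expect_gt(r0$p_values[["PHI_ST"]], 0.01)
})

test_that("fst_to_2nm inverts the island-model formula", {
  expect_equal(fst_to_2nm(0.2), 2)
  expect_equal(fst_to_2nm(1), 0)
  expect_equal(fst_to_2nm(0.5), 0.5)
  # round trip 2Nm -> Fst -> 2Nm on (0, 1]
  fst <- c(0.01, 0.1, 0.25, 0.6, 1)
  nm2 <- fst_to_2nm(fst)
  expect_equal(1 / (4 * (nm2 / 2) + 1), fst, tolerance = 1e-12)
  expect_error(fst_to_2nm(0), "undefined")
  expect_error(fst_to_2nm(-0.1), "undefined")
  expect_error(fst_to_2nm(1.2), "exceed")
})

test_that("locus_stats emits per-locus Fst, gene flow and variance shares", {
  set.seed(12)
  sim <- simulate_populations(pop_sim_spec(seed = 3))
  g <- sim$genotypes
  ls <- locus_stats(g)
  expect_equal(nrow(ls), ncol(g$alleles))
  ok <- !is.na(ls$fst) & ls$fst > 0 & ls$fst <= 1
  expect_true(any(ok))
  expect_equal(ls$gene_flow_2nm[ok], (1 / ls$fst[ok] - 1) / 2)
  sums <- rowSums(ls[, c("pct_between_species", "pct_among_populations",
                         "pct_within_populations")])
  expect_equal(sums[!is.na(sums)],
               rep(100, sum(!is.na(sums))), tolerance = 1e-9,
               ignore_attr = TRUE)
})
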
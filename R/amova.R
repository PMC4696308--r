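#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Distance-based haplotypic AMOVA partitioning molecular variance among
#' species, among populations within species, and among genotypes within
#' populations, with Phi-statistics and permutation tests. The multilocus
#' allele-difference count between two haplotypes (see
#' [pairwise_distances()]) plays the role of the squared inter-individual
#' distance, consistent with per-locus 0/1 distances summed over loci.
#'
#' Sums of squares follow the standard definitions: the total SS is
#' `sum_{i<j} d_ij / N`; the within-population SS sums `1/n_p` times the
#' within-population pair totals (and analogously within species); the
#' among-strata SS follow by subtraction. Variance components come from the
#' mean squares with the usual unbalanced-design coefficients; negative
#' components are reported as-is unless `truncate_negative = TRUE`.
#'
#' Permutation schemes: Phi_ST permutes individuals among all populations;
#' Phi_SC permutes individuals among populations within species; Phi_CT
#' permutes whole populations among species. Each p-value is
#' `(#{perm >= observed} + 1) / (n_perm + 1)`.
#'
#' @param g A `genotype_matrix`, or a precomputed symmetric distance matrix
#'   (in which case `population`/`species` must be supplied).
#' @param loci Optional locus subset (see [subset_loci()]).
#' @param n_perm Number of permutations for the p-values (0 = skip).
#' @param seed Integer seed for the permutation stream (required when
#'   `n_perm > 0`).
#' @param population,species Grouping vectors when `g` is a distance matrix.
#' @param use_species If `FALSE` (or only one species is present), a
#'   two-level AMOVA (among/within populations) is computed.
#' @param truncate_negative Truncate negative variance components at zero.
#' @return Object of class `amova_result`: `table` (d.f., SS, variance
#'   component and percentage per stratum plus a Total row), `phi`
#'   (PHI_ST/PHI_SC/PHI_CT), `p_values`, `n_perm`, and `flags`.
#' @export
amova <- function(g, loci = NULL, n_perm = 0L, seed = NULL,
                  population = NULL, species = NULL, use_species = TRUE,
                  truncate_negative = FALSE) {
  if (inherits(g, "genotype_matrix")) {
    if (!is.null(loci)) g <- subset_loci(g, loci)
    d <- pairwise_distances(g)
    population <- g$population
    species <- g$species
  } else {
    d <- as.matrix(g)
    if (is.null(population)) stop("population labels required")
    if (is.null(species)) species <- rep("sp1", length(population))
  }
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  three_level <- use_species && length(unique(species)) >= 2L
  if (length(unique(population)) < 2L) stop("need at least two populations")

  obs <- .amova_fit(d, population, if (three_level) species else NULL)

  p_values <- c(PHI_ST = NA_real_, PHI_SC = NA_real_, PHI_CT = NA_real_)
  if (n_perm > 0L && !obs$flags["zero_variance"]) {
    if (is.null(seed)) stop("seed required when n_perm > 0")
    p_values <- .restore_seed(
      .amova_permutations(d, population,
                          if (three_level) species else NULL,
                          obs$phi, n_perm),
      seed)
  }
  tab <- obs$table
  if (truncate_negative) {
    tab$variance <- pmax(tab$variance, 0)
    tot <- sum(tab$variance[tab$stratum != "Total"])
    tab$variance[tab$stratum == "Total"] <- tot
    tab$pct <- if (tot > 0) 100 * tab$variance / tot else NA_real_
  }
  structure(list(table = tab, phi = obs$phi, p_values = p_values,
                 n_perm = n_perm, flags = obs$flags,
                 three_level = three_level),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (", if (x$three_level) "species / populations / genotypes"
      else "populations / genotypes", ")\n", sep = "")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$variance <- round(tab$variance, 5)
  tab$pct <- round(tab$pct, 2)
  print(tab, row.names = FALSE)
  phi <- x$phi[!is.na(x$phi)]
  cat("Phi:", paste(sprintf("%s = %.4f", names(phi), phi),
                    collapse = ", "), "\n")
  if (x$n_perm > 0) {
    pv <- x$p_values[!is.na(x$p_values)]
    cat("Permutation p (", x$n_perm, " perms): ",
        paste(sprintf("%s: %.4g", names(pv), pv), collapse = ", "),
        "\n", sep = "")
  }
  if (x$flags["zero_variance"])
    cat("NOTE: all pairwise distances are zero; Phi undefined\n")
  invisible(x)
}

# sum of delta over unordered within-group pairs, per group level
.within_pair_sums <- function(d, labels) {
  lv <- unique(labels)
  s <- vapply(lv, function(g) {
    idx <- which(labels == g)
    sum(d[idx, idx]) / 2
  }, numeric(1))
  names(s) <- lv
  s
}

.amova_fit <- function(d, pop, sp = NULL) {
  N <- nrow(d)
  total_pairs <- sum(d) / 2
  SS_total <- total_pairs / N
  n_p <- table(pop)
  P <- length(n_p)
  W_p <- .within_pair_sums(d, pop)
  SS_WP <- sum(W_p / as.numeric(n_p[names(W_p)]))
  flags <- c(zero_variance = total_pairs == 0)

  if (is.null(sp)) {
    df <- c(P - 1L, N - P)
    SS <- c(SS_total - SS_WP, SS_WP)
    MS <- ifelse(df > 0, SS / df, NA_real_)
    S2 <- sum(as.numeric(n_p)^2) / N
    n_c <- (N - S2) / (P - 1)
    sig_c <- MS[2]
    sig_a <- (MS[1] - sig_c) / n_c
    sigma <- c(sig_a, sig_c)
    tot <- sum(sigma)
    phi <- c(PHI_ST = if (tot != 0) sig_a / tot else NA_real_,
             PHI_SC = NA_real_, PHI_CT = NA_real_)
    strata <- c("Among populations", "Among genotypes within populations")
  } else {
    sp_of_pop <- setNames(sp[!duplicated(pop)], pop[!duplicated(pop)])
    G <- length(unique(sp))
    N_g <- table(sp)
    W_g <- .within_pair_sums(d, sp)
    SS_WG <- sum(W_g / as.numeric(N_g[names(W_g)]))
    df <- c(G - 1L, P - G, N - P)
    SS <- c(SS_total - SS_WG, SS_WG - SS_WP, SS_WP)
    MS <- ifelse(df > 0, SS / df, NA_real_)
    S1 <- sum(as.numeric(n_p)^2 / as.numeric(N_g[sp_of_pop[names(n_p)]]))
    S2 <- sum(as.numeric(n_p)^2) / N
    S3 <- sum(as.numeric(N_g)^2) / N
    n_c <- (N - S1) / (P - G)
    n_1 <- (S1 - S2) / (G - 1)
    n_2 <- (N - S3) / (G - 1)
    sig_c <- MS[3]
    sig_b <- if (P - G > 0) (MS[2] - sig_c) / n_c else 0
    sig_a <- (MS[1] - sig_c - n_1 * sig_b) / n_2
    sigma <- c(sig_a, sig_b, sig_c)
    tot <- sum(sigma)
    phi <- c(PHI_ST = if (tot != 0) (sig_a + sig_b) / tot else NA_real_,
             PHI_SC = if ((sig_b + sig_c) != 0) sig_b / (sig_b + sig_c)
               else NA_real_,
             PHI_CT = if (tot != 0) sig_a / tot else NA_real_)
    strata <- c("Between species", "Among populations within species",
                "Among genotypes within populations")
  }
  tot <- sum(sigma)
  pct <- if (tot != 0) 100 * sigma / tot else rep(NA_real_, length(sigma))
  table <- data.frame(
    stratum = c(strata, "Total"),
    df = c(df, sum(df)),
    SS = c(SS, sum(SS)),
    variance = c(sigma, tot),
    pct = c(pct, if (tot != 0) 100 else NA_real_),
    stringsAsFactors = FALSE)
  list(table = table, phi = phi, sigma = sigma, flags = flags)
}

.amova_permutations <- function(d, pop, sp, phi_obs, n_perm) {
  N <- length(pop)
  count <- c(PHI_ST = 0L, PHI_SC = 0L, PHI_CT = 0L)
  have <- !is.na(phi_obs)
  for (r in seq_len(n_perm)) {
    # Phi_ST: individuals among all populations
    if (have["PHI_ST"]) {
      perm <- sample.int(N)
      phi <- .amova_fit(d, pop[perm], if (!is.null(sp)) sp[perm])$phi
      if (!is.na(phi["PHI_ST"]) && phi["PHI_ST"] >= phi_obs["PHI_ST"])
        count["PHI_ST"] <- count["PHI_ST"] + 1L
    }
    if (!is.null(sp)) {
      # Phi_SC: individuals among populations within species
      if (have["PHI_SC"]) {
        perm <- seq_len(N)
        for (s in unique(sp)) {
          idx <- which(sp == s)
          perm[idx] <- idx[sample.int(length(idx))]
        }
        phi <- .amova_fit(d, pop[perm], sp)$phi
        if (!is.na(phi["PHI_SC"]) && phi["PHI_SC"] >= phi_obs["PHI_SC"])
          count["PHI_SC"] <- count["PHI_SC"] + 1L
      }
      # Phi_CT: whole populations among species
      if (have["PHI_CT"]) {
        pops <- unique(pop)
        sp_of_pop <- setNames(sp[!duplicated(pop)], pop[!duplicated(pop)])
        new_map <- setNames(sample(unname(sp_of_pop)), pops)
        sp_perm <- unname(new_map[pop])
        phi <- .amova_fit(d, pop, sp_perm)$phi
        if (!is.na(phi["PHI_CT"]) && phi["PHI_CT"] >= phi_obs["PHI_CT"])
          count["PHI_CT"] <- count["PHI_CT"] + 1L
      }
    }
  }
  p <- (count + 1) / (n_perm + 1)
  p[!have] <- NA_real_
  if (is.null(sp)) p[c("PHI_SC", "PHI_CT")] <- NA_real_
  p
}

#' Island-model gene flow from Fst
#'
#' Inverts `Fst = 1 / (4 Nm + 1)` to the expected number of migrants per
#' generation for haploids: `2Nm = (1/Fst - 1) / 2`.
#'
#' @param fst Numeric vector of fixation indices in (0, 1].
#' @return Numeric vector of 2Nm values.
#' @examples
#' fst_to_2nm(0.2)  # 2
#' @export
fst_to_2nm <- function(fst) {
  if (any(!is.finite(fst))) stop("fst must be finite")
  if (any(fst <= 0))
    stop("fst <= 0 implies unbounded gene flow; 2Nm undefined")
  if (any(fst > 1)) stop("fst cannot exceed 1")
  (1 / fst - 1) / 2
}

#' Per-locus differentiation, gene flow, and variance decomposition
#'
#' For each locus: the two-level Phi_ST across all populations (ignoring
#' the species grouping) reported as `fst`, the island-model gene flow
#' `2Nm`, and the three-level variance percentages (between species, among
#' populations within species, among genotypes within populations).
#' Individuals missing the locus are dropped for that locus.
#'
#' @param g A `genotype_matrix`.
#' @return Data frame, one row per locus.
#' @export
locus_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  loci <- colnames(g$alleles)
  rows <- lapply(loci, function(loc) {
    col <- g$alleles[, loc]
    keep <- !is.na(col)
    pop <- g$population[keep]
    sp <- g$species[keep]
    al <- col[keep]
    d <- outer(al, al, "!=") * 1
    diag(d) <- 0
    fst <- .amova_fit(d, pop, NULL)$phi[["PHI_ST"]]
    fit3 <- if (length(unique(sp)) >= 2L) .amova_fit(d, pop, sp) else NULL
    pct <- if (!is.null(fit3))
      fit3$table$pct[seq_len(3)] else rep(NA_real_, 3)
    two_nm <- if (!is.na(fst) && fst > 0 && fst <= 1) fst_to_2nm(fst)
      else NA_real_
    data.frame(locus = loc,
               category = if (!is.null(g$locus_category))
                 g$locus_category[match(loc, colnames(g$alleles))]
                 else NA_character_,
               fst = fst, gene_flow_2nm = two_nm,
               pct_between_species = pct[1],
               pct_among_populations = pct[2],
               pct_within_populations = pct[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
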
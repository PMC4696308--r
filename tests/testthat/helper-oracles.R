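# Independent brute-force oracles used by the property-style tests.
# These deliberately re-derive results from first principles (explicit
# loops, linear solves) rather than reusing any package internals.

# --- SSR scanner oracle ----------------------------------------------------

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(unit, 1L, d), k / d), collapse = "") == unit)
      return(FALSE)
  }
  TRUE
}

# enumerate every (start, period) maximal perfect run; report complete
# copies only, at the smallest primitive period; same-period loci are kept
# disjoint by restarting after the previously reported locus
oracle_find_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  acgt <- c("A", "C", "G", "T")
  out <- list()
  for (k in 1:6) {
    thr <- thresholds[[as.character(k)]]
    prev_end <- 0L
    i <- 1L
    while (i + k <= n) {
      matches <- function(x) x + k <= n && s[x] %in% acgt &&
        s[x + k] %in% acgt && s[x] == s[x + k]
      if (matches(i) && (i == 1L || !matches(i - 1L))) {
        j <- i
        while (matches(j)) j <- j + 1L
        full_end <- j + k - 1L
        lo <- max(i, prev_end + 1L)
        copies <- (full_end - lo + 1L) %/% k
        unit <- paste(s[lo:(lo + k - 1L)], collapse = "")
        if (copies >= thr && oracle_primitive(unit)) {
          end <- lo + copies * k - 1L
          out[[length(out) + 1L]] <- data.frame(
            scaffold = "x", start = lo, end = end, motif = unit,
            unit_length = k, repeat_count = copies,
            stringsAsFactors = FALSE)
          prev_end <- end
        }
        i <- j
      } else i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_length = integer(), repeat_count = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

oracle_canonical <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(motif, "")[[1]]
  rc <- paste(rev(unname(comp[ch])), collapse = "")
  cands <- character()
  for (src in c(motif, rc)) {
    v <- strsplit(src, "")[[1]]
    for (r in seq_along(v))
      cands <- c(cands, paste(c(v[r:length(v)], v[seq_len(r - 1L)]),
                              collapse = ""))
  }
  sort(cands)[1]
}

random_dna <- function(n, p_n = 0) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, n, replace = TRUE)
  if (p_n > 0) s[runif(n) < p_n] <- "N"
  paste(s, collapse = "")
}

# --- AMOVA oracle ----------------------------------------------------------

# variance components from the sums-of-squares definitions, solving the
# expected-mean-square system numerically
oracle_amova <- function(d, pop, sp = NULL) {
  n <- nrow(d)
  ss_among_pairs <- function(members) {
    tot <- 0
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        if (members[i] && members[j]) tot <- tot + d[i, j]
    tot
  }
  SS_total <- ss_among_pairs(rep(TRUE, n)) / n
  pops <- unique(pop)
  P <- length(pops)
  SS_WP <- 0
  for (p in pops)
    SS_WP <- SS_WP + ss_among_pairs(pop == p) / sum(pop == p)
  if (is.null(sp)) {
    df <- c(P - 1L, n - P)
    SS <- c(SS_total - SS_WP, SS_WP)
    MS <- SS / df
    nc <- (n - sum(table(pop)^2) / n) / (P - 1L)
    A <- rbind(c(nc, 1), c(0, 1))
    sigma <- solve(A, MS)
    phi_st <- sigma[1] / sum(sigma)
    list(df = df, SS = SS, sigma = sigma, phi = c(PHI_ST = phi_st))
  } else {
    sps <- unique(sp)
    G <- length(sps)
    SS_WG <- 0
    for (g in sps)
      SS_WG <- SS_WG + ss_among_pairs(sp == g) / sum(sp == g)
    df <- c(G - 1L, P - G, n - P)
    SS <- c(SS_total - SS_WG, SS_WG - SS_WP, SS_WP)
    n_p <- sapply(pops, function(p) sum(pop == p))
    N_g <- sapply(sps, function(g) sum(sp == g))
    g_of_p <- sapply(pops, function(p) sp[pop == p][1])
    S1 <- sum(n_p^2 / N_g[g_of_p])
    S2 <- sum(n_p^2) / n
    S3 <- sum(N_g^2) / n
    nc <- (n - S1) / (P - G)
    n1 <- (S1 - S2) / (G - 1)
    n2 <- (n - S3) / (G - 1)
    if (P - G > 0) {
      MS <- SS / df
      A <- rbind(c(n2, n1, 1),  # E[MS among groups]
                 c(0, nc, 1),   # E[MS among pops within groups]
                 c(0, 0, 1))    # E[MS within pops]
      sigma <- solve(A, MS)
    } else {
      MS <- c(SS[1] / df[1], NA, SS[3] / df[3])
      sigma <- c((MS[1] - MS[3]) / n2, 0, MS[3])
    }
    tot <- sum(sigma)
    list(df = df, SS = SS, sigma = sigma,
         phi = c(PHI_ST = (sigma[1] + sigma[2]) / tot,
                 PHI_SC = sigma[2] / (sigma[2] + sigma[3]),
                 PHI_CT = sigma[1] / tot))
  }
}

# random small multi-population genotype datasets for oracle comparisons
random_genotypes <- function(n_ind, n_loci, n_pops, n_species = NULL,
                             n_alleles = 3L) {
  pop <- sort(rep_len(paste0("p", seq_len(n_pops)), n_ind))
  species <- if (is.null(n_species)) rep("s1", n_ind) else {
    sp_of_pop <- setNames(rep_len(paste0("s", seq_len(n_species)), n_pops),
                          paste0("p", seq_len(n_pops)))
    unname(sp_of_pop[pop])
  }
  a <- matrix(sample(100L + 3L * seq_len(n_alleles), n_ind * n_loci,
                     replace = TRUE), n_ind, n_loci)
  genotype_matrix(a, pop, species)
}

# --- region-category oracle ------------------------------------------------

# per-position classification from a plain transcript table
# (scaffold, start, end, strand, cds list, utr5 list, utr3 list, exon list)
oracle_position_category <- function(pos, scaf, txs, flank_near = 50,
                                     flank_far = 500) {
  in_any <- function(ir, p) any(p >= ir[, 1] & p <= ir[, 2])
  mine <- Filter(function(t) t$scaffold == scaf, txs)
  for (t in mine) if (in_any(t$cds, pos)) return("EXON")
  for (t in mine) if (in_any(t$utr5, pos)) return("UTR5")
  for (t in mine) if (in_any(t$utr3, pos)) return("UTR3")
  for (t in mine) if (pos >= t$start && pos <= t$end) return("INTRON")
  # nearest transcript edge wins; distance tie favours the upstream bin
  best <- NULL
  for (t in mine) {
    if (pos < t$start) {
      dist <- t$start - pos
      side <- if (t$strand == "+") "UP" else "DOWN"
    } else if (pos > t$end) {
      dist <- pos - t$end
      side <- if (t$strand == "+") "DOWN" else "UP"
    } else next
    if (is.null(best) || dist < best$dist ||
        (dist == best$dist && side == "UP" && best$side != "UP"))
      best <- list(dist = dist, side = side)
  }
  if (is.null(best) || best$dist > flank_far) return("DISTAL")
  if (best$dist <= flank_near) paste0(best$side, "_0_", flank_near)
  else paste0(best$side, "_", flank_near, "_", flank_far)
}
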
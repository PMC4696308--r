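#' Size-standardized SSR densities per region category
#'
#' Standardizes SSR counts by the genomic size of each positional category:
#' loci per Mbp, and total SSR bp per Mbp of region. Optionally broken down
#' by motif unit length and/or canonical motif.
#'
#' @param classified Data frame from [classify_ssrs()].
#' @param model A `region_model` from [build_region_model()].
#' @param by Optional extra grouping columns, any of `"unit_length"`,
#'   `"canonical_motif"`.
#' @return Data frame with columns `category`, the optional grouping
#'   columns, `ssr_count`, `ssr_bp`, `category_bp`, `density`
#'   (SSRs per Mbp) and `bp_per_mbp`.
#' @export
compute_densities <- function(classified, model, by = character()) {
  stopifnot(inherits(model, "region_model"),
            all(by %in% c("unit_length", "canonical_motif")))
  cats <- names(model$category_bp)
  if (nrow(classified)) {
    bad <- classified$category[!(classified$category %in% cats)]
    if (length(bad)) stop("unknown category: ", paste(unique(bad),
                                                      collapse = ", "))
    if (any(model$category_bp[classified$category] == 0))
      stop("impossible state: SSRs assigned to a zero-bp category")
  }
  if (length(by) == 0L) {
    grid <- data.frame(category = cats, stringsAsFactors = FALSE)
  } else {
    vals <- lapply(by, function(b) sort(unique(classified[[b]])))
    names(vals) <- by
    grid <- expand.grid(c(list(category = cats), vals),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }
  key <- function(df) do.call(paste, c(df[c("category", by)], sep = "\r"))
  if (nrow(classified)) {
    classified$.bp <- classified$end - classified$start + 1L
    agg_n <- tapply(rep(1L, nrow(classified)), key(classified), sum)
    agg_bp <- tapply(classified$.bp, key(classified), sum)
  } else {
    agg_n <- agg_bp <- numeric(0)
  }
  k <- key(grid)
  grid$ssr_count <- ifelse(k %in% names(agg_n), agg_n[k], 0L)
  grid$ssr_bp <- ifelse(k %in% names(agg_bp), agg_bp[k], 0L)
  grid$category_bp <- as.numeric(model$category_bp[grid$category])
  mb <- grid$category_bp / 1e6
  grid$density <- ifelse(mb > 0, grid$ssr_count / mb, 0)
  grid$bp_per_mbp <- ifelse(mb > 0, grid$ssr_bp / mb, 0)
  rownames(grid) <- NULL
  grid
}

#' Chi-square test of random SSR placement
#'
#' Tests the null hypothesis that SSRs fall into the positional categories
#' in proportion to category size: `expected_i = total * bp_i / genome_bp`,
#' `X^2 = sum (obs - exp)^2 / exp` on `k - 1` degrees of freedom, with the
#' p-value from the upper chi-square tail.
#'
#' @param counts Named numeric vector of observed SSR counts per category.
#' @param category_bp Named numeric vector of category sizes (bp), same
#'   names as `counts`.
#' @return List of class `chisq_uniformity` with `statistic`, `df`,
#'   `p_value`, and the `observed`/`expected` vectors.
#' @export
chi_square_uniformity <- function(counts, category_bp) {
  if (length(counts) < 2L) stop("need at least two categories")
  if (!setequal(names(counts), names(category_bp)))
    stop("counts and category_bp must cover the same categories")
  category_bp <- category_bp[names(counts)]
  total <- sum(counts)
  if (total <= 0) stop("total SSR count must be positive")
  expected <- total * category_bp / sum(category_bp)
  if (any(expected == 0))
    stop("a category has expected count 0; merge it with a neighbour ",
         "before testing")
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 observed = counts, expected = expected),
            class = "chisq_uniformity")
}

#' @export
print.chisq_uniformity <- function(x, ...) {
  cat(sprintf("Chi-square test of proportional placement: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Gene-term over-representation among SSR-bearing genes
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per term on the
#' 2x2 table of term membership inside versus outside the SSR-bearing gene
#' set, with Benjamini-Hochberg adjustment across terms.
#'
#' @param ssr_gene_ids Character vector: genes carrying at least one SSR.
#'   Must be a subset of `all_gene_ids`.
#' @param all_gene_ids Character vector: the background gene universe.
#' @param gene_to_terms Data frame with columns `gene_id` and `term_id`
#'   (optionally `term_name`).
#' @return Data frame, one row per term, sorted by p-value: `term_id`,
#'   `count_in_set`, `count_in_background`, `p_value`, `fdr`.
#' @export
term_enrichment <- function(ssr_gene_ids, all_gene_ids, gene_to_terms) {
  ssr_gene_ids <- unique(ssr_gene_ids)
  all_gene_ids <- unique(all_gene_ids)
  if (length(ssr_gene_ids) == 0L) stop("empty SSR gene set")
  if (!all(ssr_gene_ids %in% all_gene_ids))
    stop("ssr_gene_ids must be a subset of all_gene_ids")
  stray <- !(gene_to_terms$gene_id %in% all_gene_ids)
  if (any(stray)) {
    warning(sum(stray), " term annotation(s) for genes outside the ",
            "background were skipped")
    gene_to_terms <- gene_to_terms[!stray, , drop = FALSE]
  }
  gene_to_terms <- unique(gene_to_terms[c("term_id", "gene_id")])
  N <- length(all_gene_ids)
  n <- length(ssr_gene_ids)
  terms <- unique(gene_to_terms$term_id)
  rows <- lapply(terms, function(tm) {
    genes <- gene_to_terms$gene_id[gene_to_terms$term_id == tm]
    K <- length(genes)
    k <- sum(genes %in% ssr_gene_ids)
    # P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, count_in_set = k, count_in_background = K,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
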
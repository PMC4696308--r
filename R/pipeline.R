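#' Run the genome-wide SSR survey
#'
#' Orchestrates the survey arm: SSR detection, region-model construction,
#' positional classification, size-standardized densities, the chi-square
#' test of proportional placement, and (when a gene-term mapping is given)
#' gene-term over-representation among SSR-bearing genes. All tables are
#' written as TSV together with a JSON run manifest.
#'
#' @param fasta Path to a genome FASTA, or a named character vector /
#'   `DNAStringSet` of sequences.
#' @param gff Path to the GFF3 annotation (or a GRanges).
#' @param out_dir Output directory (created if needed).
#' @param thresholds Repeat-count thresholds, see [ssr_thresholds()].
#' @param gene_terms Optional path to a gene-to-term TSV (columns
#'   `gene_id`, `term_id`) or an equivalent data frame; enrichment uses
#'   genes whose transcript span contains an SSR midpoint, against all
#'   annotated genes.
#' @param overwrite Refuse to write into a non-empty `out_dir` unless TRUE.
#' @return List with `ssrs` (classified table), `model`, `densities`,
#'   `chi_square`, `enrichment` (or NULL), and `summary` (total count,
#'   kb per SSR, intergenic/intragenic tally).
#' @export
run_survey <- function(fasta, gff, out_dir = NULL,
                       thresholds = ssr_thresholds(), gene_terms = NULL,
                       overwrite = FALSE) {
  sequences <- if (is.character(fasta) && length(fasta) == 1L &&
                   file.exists(fasta))
    as.character(Biostrings::readDNAStringSet(fasta)) else fasta
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  lens <- setNames(nchar(sequences), names(sequences))

  model <- build_region_model(gff, lens)
  ssrs <- classify_ssrs(find_ssrs(sequences, thresholds), model)
  densities <- compute_densities(ssrs, model,
                                 by = c("unit_length", "canonical_motif"))
  density_by_cat <- compute_densities(ssrs, model)

  chi <- NULL
  if (nrow(ssrs) > 0L) {
    counts <- table(factor(ssrs$category, levels = names(model$category_bp)))
    chi <- chi_square_uniformity(setNames(as.numeric(counts), names(counts)),
                                 model$category_bp)
  } else {
    message("no SSRs detected; chi-square test skipped")
  }

  enrichment <- NULL
  if (!is.null(gene_terms)) {
    g2t <- if (is.character(gene_terms)) read.delim(gene_terms,
                                                    stringsAsFactors = FALSE)
      else gene_terms
    tx <- model$transcripts
    all_genes <- unique(tx$id)
    mid <- (ssrs$start + ssrs$end) %/% 2L
    carries <- vapply(seq_len(nrow(tx)), function(i)
      any(ssrs$scaffold == tx$scaffold[i] & mid >= tx$start[i] &
            mid <= tx$end[i]), logical(1))
    ssr_genes <- unique(tx$id[carries])
    if (length(ssr_genes))
      enrichment <- term_enrichment(ssr_genes, all_genes, g2t)
  }

  summary <- list(total_ssrs = nrow(ssrs),
                  genome_bp = model$genome_bp,
                  kb_per_ssr = if (nrow(ssrs) > 0)
                    model$genome_bp / 1000 / nrow(ssrs) else NA_real_,
                  tally = attr(ssrs, "tally"))

  out <- list(ssrs = ssrs, model = model, densities = densities,
              density_by_category = density_by_cat, chi_square = chi,
              enrichment = enrichment, summary = summary)
  if (!is.null(out_dir))
    .write_survey(out, out_dir, overwrite)
  out
}

.check_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory ", out_dir,
         " is not empty; pass overwrite = TRUE to replace its contents")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
}

.write_survey <- function(out, out_dir, overwrite) {
  .check_out_dir(out_dir, overwrite)
  write_ssr_tsv(out$ssrs, file.path(out_dir, "ssrs_classified.tsv"))
  write.table(out$densities, file.path(out_dir, "densities.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out$density_by_category,
              file.path(out_dir, "density_by_category.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$chi_square))
    write.table(data.frame(statistic = out$chi_square$statistic,
                           df = out$chi_square$df,
                           p_value = out$chi_square$p_value),
                file.path(out_dir, "chi_square.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$enrichment))
    write.table(out$enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(stage = "survey",
                   total_ssrs = out$summary$total_ssrs,
                   genome_bp = out$summary$genome_bp,
                   kb_per_ssr = out$summary$kb_per_ssr,
                   tally = as.list(out$summary$tally),
                   r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("ssrscape")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the population-genetics arm
#'
#' Computes, overall and per locus category (OUT/UP/IN/DOWN), the
#' three-level AMOVA with permutation tests, per-locus Fst / gene flow /
#' variance decomposition, allelic diversity summaries, PCoA coordinates,
#' and pairwise variance-ratio tests comparing the per-locus
#' between-species variance percentages across categories. Writes TSV
#' tables and a JSON manifest; identical config and seed give identical
#' outputs.
#'
#' @param g A `genotype_matrix` (see [read_genotypes()]).
#' @param out_dir Output directory (optional).
#' @param n_perm Permutations for AMOVA p-values (default 10000).
#' @param seed Integer seed (required when `n_perm > 0`).
#' @param overwrite Refuse to write into a non-empty `out_dir` unless TRUE.
#' @return List with `amova_overall`, `amova_by_category`, `locus_stats`,
#'   `allele_summary`, `pcoa`, `variance_test`.
#' @export
run_popgen <- function(g, out_dir = NULL, n_perm = 10000L, seed = NULL,
                       overwrite = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  amova_overall <- amova(g, n_perm = n_perm, seed = seed)
  cats <- intersect(c("OUT", "UP", "IN", "DOWN"),
                    unique(g$locus_category))
  amova_by_category <- lapply(setNames(cats, cats), function(cat)
    amova(g, loci = cat, n_perm = n_perm, seed = seed))
  ls <- locus_stats(g)
  allele_summary <- if (!is.null(g$locus_category)) summarize_alleles(g)
    else NULL
  pc <- suppressWarnings(pcoa(pairwise_distances(g), n_axes = 2L))
  vt <- if (length(cats) >= 2L &&
            all(table(ls$category[!is.na(ls$pct_between_species)]) >= 2L))
    category_variance_test(ls$pct_between_species, ls$category) else NULL
  out <- list(amova_overall = amova_overall,
              amova_by_category = amova_by_category,
              locus_stats = ls, allele_summary = allele_summary,
              pcoa = pc, variance_test = vt,
              genotypes = g, n_perm = n_perm, seed = seed)
  if (!is.null(out_dir)) .write_popgen(out, out_dir, overwrite)
  out
}

.amova_tsv <- function(results) {
  phi_of <- c("Between species" = "PHI_CT",
              "Among populations within species" = "PHI_SC",
              "Among populations" = "PHI_ST",
              "Among genotypes within populations" = "PHI_ST")
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    tab <- cbind(subset = nm, r$table)
    key <- phi_of[tab$stratum]
    tab$phi <- ifelse(is.na(key), NA_real_, r$phi[key])
    tab$p_perm <- ifelse(is.na(key), NA_real_, r$p_values[key])
    tab
  }))
}

.write_popgen <- function(out, out_dir, overwrite) {
  .check_out_dir(out_dir, overwrite)
  all_amova <- c(list(ALL = out$amova_overall), out$amova_by_category)
  write.table(.amova_tsv(all_amova), file.path(out_dir, "amova.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out$locus_stats, file.path(out_dir, "locus_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$allele_summary))
    write.table(out$allele_summary, file.path(out_dir, "allele_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- data.frame(individual = rownames(out$pcoa$coordinates),
                       population = out$genotypes$population,
                       species = out$genotypes$species,
                       out$pcoa$coordinates)
  write.table(coords, file.path(out_dir, "pcoa_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$variance_test))
    write.table(out$variance_test$pairs,
                file.path(out_dir, "variance_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(stage = "popgen",
                   n_individuals = nrow(out$genotypes$alleles),
                   n_loci = ncol(out$genotypes$alleles),
                   n_perm = out$n_perm, seed = out$seed,
                   warnings = list(
                     negative_components = any(
                       out$amova_overall$table$variance < 0)),
                   r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("ssrscape")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
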
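#' Haploid multilocus genotype matrix
#'
#' Container for a haploid individuals x loci table of integer allele sizes
#' (bp), with population and species labels per individual and a positional
#' category (OUT/UP/IN/DOWN) per locus. Missing alleles are `NA`.
#'
#' @param alleles Integer matrix, individuals in rows (rownames = individual
#'   ids), loci in columns (colnames = locus ids).
#' @param population Character/factor vector, one population label per
#'   individual.
#' @param species Character/factor vector, one species label per individual.
#'   Every population must belong to exactly one species.
#' @param locus_category Character vector, one of `"OUT"`, `"UP"`, `"IN"`,
#'   `"DOWN"` per locus.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, population, species,
                            locus_category = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  if (length(population) != n || length(species) != n)
    stop("population and species must have one entry per individual")
  population <- as.character(population)
  species <- as.character(species)
  map <- unique(data.frame(population, species))
  if (anyDuplicated(map$population))
    stop("every population must belong to exactly one species")
  if (length(unique(population)) < 2L)
    stop("need at least two populations")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0("ind", seq_len(n))
  if (is.null(colnames(alleles)))
    colnames(alleles) <- paste0("L", seq_len(ncol(alleles)))
  if (!is.null(locus_category)) {
    if (length(locus_category) != ncol(alleles))
      stop("locus_category must have one entry per locus")
    bad <- setdiff(unique(locus_category), c("OUT", "UP", "IN", "DOWN"))
    if (length(bad))
      stop("unknown locus category: ", paste(bad, collapse = ", "),
           " (valid: OUT, UP, IN, DOWN)")
  }
  structure(list(alleles = alleles, population = population,
                 species = species, locus_category = locus_category),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Haploid genotype matrix:", nrow(x$alleles), "individuals x",
      ncol(x$alleles), "loci;", length(unique(x$population)),
      "populations in", length(unique(x$species)), "species\n")
  if (!is.null(x$locus_category))
    print(table(x$locus_category))
  invisible(x)
}

#' Subset loci of a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @param loci Locus ids, column indices, or a category name
#'   ("OUT"/"UP"/"IN"/"DOWN").
#' @return A `genotype_matrix` restricted to the selected loci.
#' @export
subset_loci <- function(g, loci) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(loci) && length(loci) == 1L &&
      loci %in% c("OUT", "UP", "IN", "DOWN")) {
    if (is.null(g$locus_category)) stop("genotype matrix has no locus categories")
    keep <- which(g$locus_category == loci)
  } else if (is.character(loci)) {
    keep <- match(loci, colnames(g$alleles))
    if (anyNA(keep)) stop("unknown locus id")
  } else keep <- loci
  genotype_matrix(g$alleles[, keep, drop = FALSE], g$population, g$species,
                  if (!is.null(g$locus_category)) g$locus_category[keep])
}

#' Read a genotype table and locus metadata from TSV
#'
#' The genotype TSV has columns `individual_id`, `population`, `species`,
#' then one column per locus holding integer allele sizes (blank/NA =
#' missing). The locus metadata TSV has columns `locus_id` and `category`.
#'
#' @param genotype_path,locus_path File paths.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(genotype_path, locus_path = NULL) {
  df <- read.delim(genotype_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("individual_id", "population", "species")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  loci <- setdiff(names(df), need)
  alleles <- as.matrix(df[loci])
  rownames(alleles) <- df$individual_id
  category <- NULL
  if (!is.null(locus_path)) {
    li <- read.delim(locus_path, stringsAsFactors = FALSE)
    category <- li$category[match(loci, li$locus_id)]
    if (anyNA(category))
      stop("locus metadata missing for: ",
           paste(loci[is.na(category)], collapse = ", "))
  }
  genotype_matrix(alleles, df$population, df$species, category)
}

#' Write a genotype matrix (and locus metadata) to TSV
#'
#' @param g A `genotype_matrix`.
#' @param genotype_path,locus_path Output paths (`locus_path` optional).
#' @return `genotype_path`, invisibly.
#' @export
write_genotypes <- function(g, genotype_path, locus_path = NULL) {
  df <- data.frame(individual_id = rownames(g$alleles),
                   population = g$population, species = g$species,
                   g$alleles, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, genotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(locus_path) && !is.null(g$locus_category))
    write.table(data.frame(locus_id = colnames(g$alleles),
                           category = g$locus_category),
                locus_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genotype_path)
}

#' Pairwise allele-difference distances
#'
#' For haplotypes i and j, the distance is the number of loci at which their
#' alleles differ, skipping loci missing in either individual (pairwise
#' deletion).
#'
#' @param g A `genotype_matrix`.
#' @param loci Optional locus subset (see [subset_loci()]).
#' @return Symmetric numeric matrix of counts of differing loci.
#' @export
pairwise_distances <- function(g, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(loci)) g <- subset_loci(g, loci)
  a <- g$alleles
  n <- nrow(a)
  if (n < 2L) stop("need at least two individuals")
  d <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(a[i, ]) & !is.na(a[j, ])
      if (!any(ok))
        stop("individuals ", rownames(a)[i], " and ", rownames(a)[j],
             " share no scored locus")
      d[i, j] <- d[j, i] <- sum(a[i, ok] != a[j, ok])
    }
  }
  d
}

#' Per-locus, per-group allelic diversity
#'
#' For each locus and group (population or species): the number of distinct
#' alleles Na, the effective number of alleles Ne = 1 / sum(p_i^2) computed
#' from within-group allele frequencies, and - at species level - counts of
#' private alleles (seen in this species only) and shared alleles (seen in
#' both species). Missing alleles are excluded from frequencies; a locus
#' with no scored individual in a group reports `NA`.
#'
#' @param g A `genotype_matrix`.
#' @param grouping `"population"` or `"species"`.
#' @return Data frame with columns `locus`, `group`, `na`, `ne`, and (for
#'   species grouping) `private`, `shared`.
#' @export
allele_stats <- function(g, grouping = c("population", "species")) {
  stopifnot(inherits(g, "genotype_matrix"))
  grouping <- match.arg(grouping)
  labels <- g[[grouping]]
  groups <- unique(labels)
  loci <- colnames(g$alleles)
  rows <- list()
  for (loc in loci) {
    col <- g$alleles[, loc]
    by_group <- lapply(groups, function(grp) col[labels == grp &
                                                   !is.na(col)])
    names(by_group) <- groups
    for (grp in groups) {
      al <- by_group[[grp]]
      if (length(al) == 0L) {
        na <- ne <- NA_real_
      } else {
        p <- as.vector(table(al)) / length(al)
        na <- length(p)
        ne <- 1 / sum(p^2)
      }
      row <- data.frame(locus = loc, group = grp, na = na, ne = ne,
                        stringsAsFactors = FALSE)
      if (grouping == "species") {
        others <- unlist(by_group[setdiff(groups, grp)])
        row$private <- if (length(al)) sum(!(unique(al) %in% others))
          else NA_integer_
        row$shared <- if (length(al)) sum(unique(al) %in% others)
          else NA_integer_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize allelic diversity by species and locus category
#'
#' Mean (+/- standard error over loci) of per-population Na and Ne and of
#' species-level private/shared allele counts, by species x locus category.
#'
#' @param g A `genotype_matrix` with locus categories.
#' @return Data frame with one row per species x category.
#' @export
summarize_alleles <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$locus_category)) stop("genotype matrix has no locus categories")
  pop_stats <- allele_stats(g, "population")
  sp_stats <- allele_stats(g, "species")
  pop2sp <- setNames(g$species[!duplicated(g$population)],
                     g$population[!duplicated(g$population)])
  pop_stats$species <- pop2sp[pop_stats$group]
  cat_of <- setNames(g$locus_category, colnames(g$alleles))
  pop_stats$category <- cat_of[pop_stats$locus]
  sp_stats$category <- cat_of[sp_stats$locus]
  se <- function(x) { x <- x[!is.na(x)]; stats::sd(x) / sqrt(length(x)) }
  rows <- list()
  for (sp in unique(g$species)) {
    for (cat in unique(g$locus_category)) {
      ps <- pop_stats[pop_stats$species == sp & pop_stats$category == cat, ]
      # per-locus mean over that species' populations, then across loci
      na_loc <- tapply(ps$na, ps$locus, mean, na.rm = TRUE)
      ne_loc <- tapply(ps$ne, ps$locus, mean, na.rm = TRUE)
      ss <- sp_stats[sp_stats$group == sp & sp_stats$category == cat, ]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, category = cat, n_loci = length(na_loc),
        na_mean = mean(na_loc), na_se = se(na_loc),
        ne_mean = mean(ne_loc), ne_se = se(ne_loc),
        private_mean = mean(ss$private, na.rm = TRUE),
        private_se = se(ss$private),
        shared_mean = mean(ss$shared, na.rm = TRUE),
        shared_se = se(ss$shared),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
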
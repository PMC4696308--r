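#' Specification for a synthetic annotated genome with planted SSRs
#'
#' Describes a small multi-scaffold genome with regularly spaced
#' protein-coding gene models (5'UTR, three CDS exons split by two introns,
#' 3'UTR) and a planting table of perfect SSRs targeted at specific
#' positional categories. The default layout spaces genes so that every one
#' of the nine categories exists on every scaffold, and the default planting
#' table places trinucleotide loci from the genome's dominant motif families
#' (ACG, CCG, AGC) in every category plus a mono- and a dinucleotide locus
#' in distal sequence.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold (bp).
#' @param genes_per_scaffold Gene models per scaffold.
#' @param utr5_len,utr3_len,cds_exon_len,intron_len Gene template lengths
#'   (bp); each gene has three CDS exons and two introns.
#' @param p_plus_strand Probability a gene lies on the + strand.
#' @param gc GC content of the background sequence.
#' @param planting Data frame with columns `category`, `motif` (planted
#'   as-is), `repeats`, `count`.
#' @param seed Integer seed; the simulation is deterministic given the spec.
#' @return List of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_scaffolds = 2L, scaffold_length = 30000L,
                            genes_per_scaffold = 6L,
                            utr5_len = 150L, utr3_len = 200L,
                            cds_exon_len = 300L, intron_len = 200L,
                            p_plus_strand = 0.5, gc = 0.5,
                            planting = default_planting(), seed = 1L) {
  need <- c("category", "motif", "repeats", "count")
  if (!all(need %in% names(planting)))
    stop("planting table needs columns ", paste(need, collapse = ", "))
  bad <- setdiff(planting$category, REGION_CATEGORIES)
  if (length(bad)) stop("unknown planting category: ",
                        paste(bad, collapse = ", "))
  thr <- ssr_thresholds()
  k <- nchar(planting$motif)
  if (any(planting$repeats < thr[as.character(k)]))
    stop("planted repeat counts must meet the detection thresholds")
  structure(list(n_scaffolds = n_scaffolds,
                 scaffold_length = scaffold_length,
                 genes_per_scaffold = genes_per_scaffold,
                 utr5_len = utr5_len, utr3_len = utr3_len,
                 cds_exon_len = cds_exon_len, intron_len = intron_len,
                 p_plus_strand = p_plus_strand, gc = gc,
                 planting = planting, seed = seed),
            class = "genome_sim_spec")
}

#' Default SSR planting table
#'
#' @return Data frame with columns `category`, `motif`, `repeats`, `count`.
#' @export
default_planting <- function() {
  tri <- data.frame(category = rep(REGION_CATEGORIES, each = 3),
                    motif = rep(c("ACG", "CCG", "AGC"),
                                length(REGION_CATEGORIES)),
                    repeats = rep(c(6L, 5L, 7L), length(REGION_CATEGORIES)),
                    count = 1L, stringsAsFactors = FALSE)
  extra <- data.frame(category = c("DISTAL", "DISTAL", "INTRON"),
                      motif = c("A", "AC", "AAGT"),
                      repeats = c(15L, 8L, 5L),
                      count = 1L, stringsAsFactors = FALSE)
  rbind(tri, extra)
}

#' Simulate an annotated genome with planted SSRs
#'
#' Generates background sequence free of accidental SSRs at the detection
#' thresholds (rejection-resampled), lays out gene models, and overwrites
#' target-category positions with perfect motif repeats. Flanking bases of
#' each planted locus are set so the run is exactly maximal, and the whole
#' genome is re-scanned to verify that the detected loci equal the planted
#' truth. Deterministic given the spec (including its seed).
#'
#' @param spec A `genome_sim_spec`.
#' @param dir Optional directory; when given, writes `genome.fasta`,
#'   `annotation.gff3` and `truth.tsv` there.
#' @return List with `sequences` (named character vector), `annotation`
#'   (GRanges in GFF3 layout), `truth` (data frame: scaffold, start, end,
#'   motif, canonical_motif, unit_length, repeat_count, category), `model`
#'   (the `region_model`), and `scaffold_lengths`.
#' @export
simulate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  .restore_seed(.simulate_genome_impl(spec, dir), spec$seed)
}

.simulate_genome_impl <- function(spec, dir) {
  thr <- ssr_thresholds()
  lens <- setNames(rep(spec$scaffold_length, spec$n_scaffolds),
                   paste0("scaffold_", seq_len(spec$n_scaffolds)))
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
             T = (1 - spec$gc) / 2)
  rand_bases <- function(n) sample(names(probs), n, replace = TRUE,
                                   prob = probs)

  # background free of accidental SSRs: resample any detected span
  seqs <- lapply(lens, function(L) {
    s <- rand_bases(L)
    for (iter in 1:50) {
      found <- find_ssrs(setNames(paste(s, collapse = ""), "x"), thr)
      if (nrow(found) == 0L) break
      for (r in seq_len(nrow(found)))
        s[found$start[r]:found$end[r]] <-
          rand_bases(found$end[r] - found$start[r] + 1L)
    }
    s
  })

  ann <- .layout_genes(spec, lens)
  model <- build_region_model(ann$gr, lens)

  truth <- .plant_ssrs(spec, seqs, model, thr)
  seqs <- truth$seqs

  sequences <- vapply(seqs, paste, character(1), collapse = "")
  detected <- classify_ssrs(find_ssrs(sequences, thr), model)
  if (!.same_loci(detected, truth$table))
    stop("internal error: detected SSRs do not match the planted truth")

  out <- list(sequences = sequences, annotation = ann$gr,
              truth = truth$table, model = model, scaffold_lengths = lens)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences),
                                file.path(dir, "genome.fasta"))
    rtracklayer::export(ann$gr, file.path(dir, "annotation.gff3"),
                        format = "gff3")
    write.table(truth$table, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

.same_loci <- function(detected, truth) {
  key <- function(df) sort(paste(df$scaffold, df$start, df$end, df$motif,
                                 df$category))
  nrow(detected) == nrow(truth) && all(key(detected) == key(truth))
}

.layout_genes <- function(spec, lens) {
  gene_len <- spec$utr5_len + 3L * spec$cds_exon_len +
    2L * spec$intron_len + spec$utr3_len
  rows <- list()
  for (scaf in names(lens)) {
    L <- lens[[scaf]]
    pitch <- L %/% (spec$genes_per_scaffold + 1L)
    if (pitch < gene_len + 1200L)
      stop("scaffold too short for the requested gene count: flank and ",
           "distal categories would vanish")
    for (gi in seq_len(spec$genes_per_scaffold)) {
      gstart <- (gi - 1L) * pitch + (pitch - gene_len) %/% 2L + 1L
      strand <- if (runif(1) < spec$p_plus_strand) "+" else "-"
      gid <- sprintf("%s.g%d", scaf, gi)
      # physical segment order left->right; 5'UTR on the strand's 5' side
      seg_len <- c(spec$utr5_len, spec$cds_exon_len, spec$intron_len,
                   spec$cds_exon_len, spec$intron_len, spec$cds_exon_len,
                   spec$utr3_len)
      seg_type <- c("five_prime_UTR", "CDS", "intron", "CDS", "intron",
                    "CDS", "three_prime_UTR")
      if (strand == "-") { seg_len <- rev(seg_len); seg_type <- rev(seg_type) }
      ends <- gstart - 1L + cumsum(seg_len)
      starts <- ends - seg_len + 1L
      gend <- ends[length(ends)]
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = scaf, start = gstart, end = gend, type = "gene",
        strand = strand, ID = gid, Parent = NA_character_)
      mid <- paste0(gid, ".m1")
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = scaf, start = gstart, end = gend, type = "mRNA",
        strand = strand, ID = mid, Parent = gid)
      keep <- seg_type != "intron"
      # exon features: UTR+CDS runs merged where contiguous
      exon_ir <- IRanges::reduce(IRanges::IRanges(starts[keep], ends[keep]))
      for (e in seq_along(exon_ir))
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = scaf, start = IRanges::start(exon_ir)[e],
          end = IRanges::end(exon_ir)[e], type = "exon", strand = strand,
          ID = sprintf("%s.exon%d", mid, e), Parent = mid)
      for (si in which(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = scaf, start = starts[si], end = ends[si],
          type = seg_type[si], strand = strand,
          ID = sprintf("%s.%s.%d", mid, seg_type[si], si), Parent = mid)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$scaffold, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    Parent = IRanges::CharacterList(
      lapply(df$Parent, function(p) if (is.na(p)) character(0) else p)),
    phase = ifelse(df$type == "CDS", 0L, NA_integer_),
    source = "ssrscape")
  list(gr = gr, table = df)
}

.plant_ssrs <- function(spec, seqs, model, thr) {
  plan <- spec$planting[rep(seq_len(nrow(spec$planting)),
                            spec$planting$count), , drop = FALSE]
  occupied <- data.frame(scaffold = character(), lo = integer(),
                         hi = integer())
  truth <- list()
  for (r in seq_len(nrow(plan))) {
    motif <- toupper(plan$motif[r]); reps <- plan$repeats[r]
    k <- nchar(motif); len <- k * reps
    target <- model$categories[[plan$category[r]]]
    # need the locus plus 1 bp of controllable flank inside the interval
    cand <- target[GenomicRanges::width(target) >= len + 2L]
    placed <- FALSE
    for (attempt in 1:200) {
      if (length(cand) == 0L) break
      ci <- sample.int(length(cand), 1L)
      lo <- GenomicRanges::start(cand)[ci] + 1L
      hi <- GenomicRanges::end(cand)[ci] - len
      if (hi < lo) next
      start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      scaf <- as.character(GenomicRanges::seqnames(cand))[ci]
      site_lo <- start - 6L; site_hi <- start + len + 5L
      if (any(occupied$scaffold == scaf & occupied$hi >= site_lo &
                occupied$lo <= site_hi)) next
      s <- seqs[[scaf]]
      bases <- strsplit(strrep(motif, reps), "")[[1]]
      s[start:(start + len - 1L)] <- bases
      # break perfect-run extension on both sides for every period
      s <- .break_flanks(s, start, start + len - 1L)
      win_lo <- max(1L, start - 40L)
      win_hi <- min(length(s), start + len + 39L)
      local <- find_ssrs(setNames(paste(s[win_lo:win_hi], collapse = ""),
                                  scaf), thr)
      hit <- local$start == start - win_lo + 1L &
        local$end == start + len - win_lo &
        local$motif == motif
      if (nrow(local) == 1L && any(hit)) {
        seqs[[scaf]] <- s
        occupied <- rbind(occupied,
                          data.frame(scaffold = scaf, lo = site_lo,
                                     hi = site_hi))
        truth[[length(truth) + 1L]] <- data.frame(
          scaffold = scaf, start = start, end = start + len - 1L,
          motif = motif, canonical_motif = canonical_motif(motif),
          unit_length = k, repeat_count = reps,
          category = plan$category[r], stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a ", plan$motif[r], " x", reps,
           " locus in category ", plan$category[r],
           " (region too small or too crowded)")
  }
  table <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               motif = character(), canonical_motif = character(),
               unit_length = integer(), repeat_count = integer(),
               category = character(), stringsAsFactors = FALSE)
  table <- table[order(table$scaffold, table$start), , drop = FALSE]
  rownames(table) <- NULL
  list(seqs = seqs, table = table)
}

# rewrite up to 6 bp on each side of [start, end] so no period 1..6
# continues across the boundary
.break_flanks <- function(s, start, end) {
  n <- length(s)
  for (off in 1:6) {
    i <- start - off
    if (i >= 1L) {
      forbidden <- unique(c(s[i + 1:6][seq_len(min(6L, n - i))],
                            if (i > 1L) s[i - 1L]))
      choices <- setdiff(c("A", "C", "G", "T"), forbidden)
      if (length(choices) && s[i] %in% s[i + 1:6])
        s[i] <- choices[sample.int(length(choices), 1L)]
    }
    j <- end + off
    if (j <= n) {
      forbidden <- unique(c(s[j - 1:6][seq_len(min(6L, j - 1L))],
                            if (j < n) s[j + 1L]))
      choices <- setdiff(c("A", "C", "G", "T"), forbidden)
      if (length(choices) && s[j] %in% s[j - 1:6])
        s[j] <- choices[sample.int(length(choices), 1L)]
    }
  }
  s
}
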
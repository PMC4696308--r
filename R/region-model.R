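#' Build a positional region model from a gene annotation
#'
#' Partitions every scaffold position into exactly one of the nine positional
#' categories (see [region_categories()]). Genic categories are assigned with
#' precedence EXON (CDS-overlapping) > UTR5 > UTR3 > INTRON; introns are the
#' transcript span minus its exons. Intergenic positions are binned by
#' distance to the nearest transcript edge, strand-aware (upstream = the 5'
#' direction of that transcript): 1-50 bp, 51-500 bp, or DISTAL beyond
#' 500 bp. Where two transcripts' flanks meet, the nearer transcript wins;
#' an exact distance tie resolves in favour of the upstream bin.
#'
#' UTR features are used where present; otherwise UTRs are derived as
#' exon-minus-CDS, split 5'/3' around the CDS by strand. Transcripts without
#' CDS features are skipped with a warning.
#'
#' @param annotation Path to a GFF3 file, or a [GenomicRanges::GRanges] as
#'   returned by [rtracklayer::import()], with `type`, `ID` and `Parent`
#'   metadata columns.
#' @param scaffold_lengths Named integer vector of scaffold lengths (bp).
#' @param flank_near,flank_far Flank bin edges in bp (defaults 50 and 500;
#'   bins are closed, i.e. d in [1, flank_near] and
#'   (flank_near, flank_far]).
#' @return An object of class `region_model`: a list with `categories`
#'   (named list of `GRanges`, one per category), `category_bp`,
#'   `genome_bp`, `scaffold_lengths` and a `transcripts` data frame.
#' @export
build_region_model <- function(annotation, scaffold_lengths,
                               flank_near = 50L, flank_far = 500L) {
  gr <- if (is.character(annotation))
    rtracklayer::import(annotation, format = "gff3") else annotation
  if (is.null(names(scaffold_lengths)))
    stop("scaffold_lengths must be a named vector")
  scaffold_lengths <- vapply(scaffold_lengths, as.integer, integer(1))

  tx <- .collect_transcripts(gr, scaffold_lengths)
  cats <- .assemble_categories(tx, scaffold_lengths, flank_near, flank_far)

  category_bp <- vapply(cats, function(g) sum(as.numeric(IRanges::width(g))),
                        numeric(1))
  genome_bp <- sum(as.numeric(scaffold_lengths))
  if (abs(sum(category_bp) - genome_bp) > 0)
    stop("internal error: region categories do not tile the genome")
  structure(list(categories = cats,
                 category_bp = category_bp,
                 genome_bp = genome_bp,
                 scaffold_lengths = scaffold_lengths,
                 transcripts = tx$table,
                 flank_near = flank_near, flank_far = flank_far),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat("Region model:", length(x$scaffold_lengths), "scaffold(s),",
      format(x$genome_bp, big.mark = ","), "bp,",
      nrow(x$transcripts), "transcript(s)\n")
  df <- data.frame(category = names(x$category_bp),
                   bp = as.integer(x$category_bp),
                   pct = round(100 * x$category_bp / x$genome_bp, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

.collect_transcripts <- function(gr, scaffold_lengths) {
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_,
                                                          length(gr))
  parent <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))

  if (any(!as.character(GenomicRanges::seqnames(gr)) %in%
            names(scaffold_lengths)))
    stop("annotation references scaffolds absent from scaffold_lengths")
  lens <- scaffold_lengths[as.character(GenomicRanges::seqnames(gr))]
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > lens))
    stop("annotation feature outside scaffold bounds")

  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- id[is_tx]
  # genes with direct exon/CDS children act as their own transcript
  child_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  gene_ids <- id[type == "gene"]
  direct <- setdiff(intersect(parent[type %in% child_types], gene_ids),
                    parent[is_tx])
  tx_ids <- c(tx_ids, direct)

  txs <- list()
  tab <- list()
  for (t in tx_ids) {
    sel_self <- !is.na(id) & id == t
    sel_child <- !is.na(parent) & parent == t
    feats <- gr[sel_self | sel_child]
    ftype <- as.character(feats$type)
    get_ir <- function(what) {
      f <- feats[ftype %in% what]
      IRanges::reduce(IRanges::IRanges(GenomicRanges::start(f),
                                       GenomicRanges::end(f)))
    }
    exons <- get_ir("exon")
    cds <- get_ir("CDS")
    utr5 <- get_ir("five_prime_UTR")
    utr3 <- get_ir("three_prime_UTR")
    if (length(exons) == 0L && length(cds) == 0L) {
      warning("transcript '", t, "' has no exons; skipped")
      next
    }
    if (length(cds) == 0L) {
      warning("transcript '", t, "' has no CDS; skipped")
      next
    }
    strand <- as.character(GenomicRanges::strand(feats))
    strand <- setdiff(strand, "*")
    strand <- if (length(strand)) strand[[1]] else "+"
    scaf <- as.character(GenomicRanges::seqnames(feats))[1]
    if (length(exons) == 0L) exons <- IRanges::reduce(c(cds, utr5, utr3))
    span <- range(c(IRanges::start(exons), IRanges::end(exons),
                    GenomicRanges::start(feats),
                    GenomicRanges::end(feats)))
    if (length(utr5) == 0L && length(utr3) == 0L) {
      noncds <- IRanges::setdiff(exons, cds)
      if (length(noncds)) {
        left <- noncds[IRanges::end(noncds) < min(IRanges::start(cds))]
        right <- noncds[IRanges::start(noncds) > max(IRanges::end(cds))]
        if (strand == "-") { utr5 <- right; utr3 <- left }
        else { utr5 <- left; utr3 <- right }
      }
    }
    txs[[t]] <- list(id = t, scaffold = scaf, strand = strand,
                     start = span[1], end = span[2],
                     exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
    tab[[t]] <- data.frame(id = t, scaffold = scaf, start = span[1],
                           end = span[2], strand = strand,
                           stringsAsFactors = FALSE)
  }
  table <- if (length(tab)) do.call(rbind, tab) else
    data.frame(id = character(), scaffold = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
  rownames(table) <- NULL
  list(txs = txs, table = table)
}

.assemble_categories <- function(tx, scaffold_lengths, flank_near,
                                 flank_far) {
  ir_by_cat <- setNames(vector("list", length(REGION_CATEGORIES)),
                        REGION_CATEGORIES)
  pieces <- list()
  add <- function(scaf, start, end, category) {
    if (length(start) && any(end >= start))
      pieces[[length(pieces) + 1L]] <<- data.frame(
        scaffold = scaf, start = start[end >= start], end = end[end >= start],
        category = category, stringsAsFactors = FALSE)
  }

  for (scaf in names(scaffold_lengths)) {
    L <- scaffold_lengths[[scaf]]
    txs <- Filter(function(t) t$scaffold == scaf, tx$txs)
    whole <- IRanges::IRanges(1L, L)
    if (length(txs) == 0L) {
      add(scaf, 1L, L, "DISTAL")
      next
    }
    un <- function(lst) if (length(lst)) IRanges::reduce(
      do.call(c, unname(lst))) else IRanges::IRanges()
    exon_all <- un(lapply(txs, `[[`, "exons"))
    EXON <- un(lapply(txs, `[[`, "cds"))
    UTR5 <- IRanges::setdiff(un(lapply(txs, `[[`, "utr5")), EXON)
    UTR3 <- IRanges::setdiff(un(lapply(txs, `[[`, "utr3")),
                             IRanges::reduce(c(EXON, UTR5)))
    spans <- IRanges::reduce(IRanges::IRanges(
      vapply(txs, `[[`, integer(1), "start"),
      vapply(txs, `[[`, integer(1), "end")))
    genic_named <- IRanges::reduce(c(EXON, UTR5, UTR3))
    INTRON <- IRanges::setdiff(spans, IRanges::reduce(c(exon_all,
                                                        genic_named)))
    # any residual genic sequence (odd annotations) folds into INTRON so the
    # partition always tiles
    residual <- IRanges::setdiff(spans, IRanges::reduce(c(genic_named,
                                                          INTRON)))
    INTRON <- IRanges::reduce(c(INTRON, residual))
    for (cat in c("EXON", "UTR5", "UTR3", "INTRON")) {
      ir <- get(cat)
      add(scaf, IRanges::start(ir), IRanges::end(ir), cat)
    }

    gaps <- IRanges::setdiff(whole, spans)
    tstart <- vapply(txs, `[[`, integer(1), "start")
    tend <- vapply(txs, `[[`, integer(1), "end")
    tstrand <- vapply(txs, `[[`, character(1), "strand")
    for (i in seq_along(gaps)) {
      a <- IRanges::start(gaps)[i]; b <- IRanges::end(gaps)[i]
      g <- b - a + 1L
      # side of the neighbouring transcript facing this gap:
      # right side of a "+" transcript is its downstream, of "-" upstream
      left_sides <- tstrand[tend == a - 1L]
      side_left <- if (length(left_sides) == 0L) NA_character_
        else if (any(left_sides == "-")) "UP"
        else "DOWN"
      right_sides <- tstrand[tstart == b + 1L]
      side_right <- if (length(right_sides) == 0L) NA_character_
        else if (any(right_sides == "+")) "UP"
        else "DOWN"
      if (is.na(side_left) && is.na(side_right)) {
        add(scaf, a, b, "DISTAL")
      } else if (is.na(side_right)) {
        .add_flank_bins(add, scaf, a, b, side_left, from_left = TRUE,
                        flank_near, flank_far)
      } else if (is.na(side_left)) {
        .add_flank_bins(add, scaf, a, b, side_right, from_left = FALSE,
                        flank_near, flank_far)
      } else {
        n_left <- g %/% 2L
        if (g %% 2L == 1L) {
          # distance tie at the centre position: upstream bin wins
          tie_left <- (side_left == "UP") ||
            (side_left == side_right)  # same side: either owner, same bin
          if (side_right == "UP" && side_left != "UP") tie_left <- FALSE
          n_left <- n_left + as.integer(tie_left)
        }
        if (n_left > 0L)
          .add_flank_bins(add, scaf, a, a + n_left - 1L, side_left,
                          from_left = TRUE, flank_near, flank_far)
        if (g - n_left > 0L)
          .add_flank_bins(add, scaf, a + n_left, b, side_right,
                          from_left = FALSE, flank_near, flank_far)
      }
    }
  }

  df <- do.call(rbind, pieces)
  out <- lapply(setNames(REGION_CATEGORIES, REGION_CATEGORIES),
                function(cat) {
    d <- df[df$category == cat, , drop = FALSE]
    if (nrow(d) == 0L)
      return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
        names(scaffold_lengths), scaffold_lengths)))
    GenomicRanges::reduce(GenomicRanges::GRanges(
      d$scaffold, IRanges::IRanges(d$start, d$end),
      seqinfo = GenomeInfoDb::Seqinfo(names(scaffold_lengths),
                                      scaffold_lengths)))
  })
  out
}

# bins a one-sided stretch of intergenic sequence by distance from the
# transcript edge it abuts
.add_flank_bins <- function(add, scaf, a, b, side, from_left, flank_near,
                            flank_far) {
  g <- b - a + 1L
  near <- paste0(side, "_0_", flank_near)
  far <- paste0(side, "_", flank_near, "_", flank_far)
  if (from_left) {
    add(scaf, a, min(a + flank_near - 1L, b), near)
    if (g > flank_near)
      add(scaf, a + flank_near, min(a + flank_far - 1L, b), far)
    if (g > flank_far) add(scaf, a + flank_far, b, "DISTAL")
  } else {
    add(scaf, max(b - flank_near + 1L, a), b, near)
    if (g > flank_near)
      add(scaf, max(b - flank_far + 1L, a), b - flank_near, far)
    if (g > flank_far) add(scaf, a, b - flank_far, "DISTAL")
  }
}

#' Classify SSR loci into positional categories
#'
#' Assigns each SSR the category containing its midpoint
#' (`(start + end) %/% 2`), and tallies intragenic (EXON, INTRON, UTR5,
#' UTR3) versus intergenic loci.
#'
#' @param ssrs Data frame from [find_ssrs()].
#' @param model A `region_model` from [build_region_model()].
#' @return The input data frame with added `category` and `intragenic`
#'   columns; the intergenic/intragenic tally is attached as
#'   `attr(, "tally")`.
#' @export
classify_ssrs <- function(ssrs, model) {
  stopifnot(inherits(model, "region_model"))
  if (nrow(ssrs) == 0L) {
    ssrs$category <- character(0)
    ssrs$intragenic <- logical(0)
    attr(ssrs, "tally") <- c(intragenic = 0L, intergenic = 0L)
    return(ssrs)
  }
  unknown <- setdiff(unique(ssrs$scaffold), names(model$scaffold_lengths))
  if (length(unknown))
    stop("SSR(s) on scaffold(s) absent from the region model: ",
         paste(unknown, collapse = ", "))
  mid <- (ssrs$start + ssrs$end) %/% 2L
  pts <- GenomicRanges::GRanges(ssrs$scaffold, IRanges::IRanges(mid, mid))
  category <- rep(NA_character_, nrow(ssrs))
  for (cat in names(model$categories)) {
    hit <- GenomicRanges::findOverlaps(pts, model$categories[[cat]])
    category[S4Vectors::queryHits(hit)] <- cat
  }
  stopifnot(!anyNA(category))
  ssrs$category <- category
  ssrs$intragenic <- category %in% INTRAGENIC_CATEGORIES
  attr(ssrs, "tally") <- c(intragenic = sum(ssrs$intragenic),
                           intergenic = sum(!ssrs$intragenic))
  ssrs
}
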
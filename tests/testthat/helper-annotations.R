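# build a toy GFF3-style GRanges (gene/mRNA/exon/CDS/UTR features) plus the
# plain transcript table consumed by oracle_position_category()

toy_gene <- function(scaffold, start, strand = "+", utr5 = 100L,
                     cds = c(200L, 200L), introns = 150L, utr3 = 80L) {
  seg_len <- utr5
  seg_type <- "five_prime_UTR"
  for (i in seq_along(cds)) {
    seg_len <- c(seg_len, cds[i])
    seg_type <- c(seg_type, "CDS")
    if (i < length(cds)) {
      seg_len <- c(seg_len, introns[min(i, length(introns))])
      seg_type <- c(seg_type, "intron")
    }
  }
  seg_len <- c(seg_len, utr3)
  seg_type <- c(seg_type, "three_prime_UTR")
  if (strand == "-") { seg_len <- rev(seg_len); seg_type <- rev(seg_type) }
  ends <- start - 1L + cumsum(seg_len)
  starts <- ends - seg_len + 1L
  list(scaffold = scaffold, start = start, end = ends[length(ends)],
       strand = strand, starts = starts, ends = ends, types = seg_type)
}

toy_annotation <- function(genes) {
  rows <- list()
  txs <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    gid <- paste0("g", gi); mid <- paste0("m", gi)
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = g$scaffold, start = g$start, end = g$end, type = "gene",
      strand = g$strand, ID = gid, Parent = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = g$scaffold, start = g$start, end = g$end, type = "mRNA",
      strand = g$strand, ID = mid, Parent = gid)
    keep <- g$types != "intron"
    exon_ir <- IRanges::reduce(IRanges::IRanges(g$starts[keep],
                                                g$ends[keep]))
    for (e in seq_along(exon_ir))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = g$scaffold, start = IRanges::start(exon_ir)[e],
        end = IRanges::end(exon_ir)[e], type = "exon", strand = g$strand,
        ID = paste0(mid, ".e", e), Parent = mid)
    for (si in which(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = g$scaffold, start = g$starts[si], end = g$ends[si],
        type = g$types[si], strand = g$strand,
        ID = paste0(mid, ".", si), Parent = mid)
    iv <- function(type) {
      m <- g$types == type
      cbind(g$starts[m], g$ends[m])
    }
    txs[[length(txs) + 1L]] <- list(
      scaffold = g$scaffold, start = g$start, end = g$end,
      strand = g$strand, cds = iv("CDS"), utr5 = iv("five_prime_UTR"),
      utr3 = iv("three_prime_UTR"))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$scaffold, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    Parent = IRanges::CharacterList(lapply(df$Parent, function(p)
      if (is.na(p)) character(0) else p)))
  list(gr = gr, txs = txs)
}

category_at <- function(model, scaf, pos) {
  for (cat in names(model$categories)) {
    g <- model$categories[[cat]]
    g <- g[as.character(GenomicRanges::seqnames(g)) == scaf]
    if (length(g) &&
        any(pos >= GenomicRanges::start(g) & pos <= GenomicRanges::end(g)))
      return(cat)
  }
  NA_character_
}
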
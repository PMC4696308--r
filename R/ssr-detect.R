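#' MISA-style minimum repeat thresholds
#'
#' Minimum number of complete motif copies a perfect run must reach to be
#' reported, by motif length. Defaults follow the perfect-MISA search set
#' used for the genome survey: 14 mononucleotide, 7 dinucleotide,
#' 5 trinucleotide and 4 tetra-/penta-/hexanucleotide copies.
#'
#' @param mono,di,tri,tetra,penta,hexa Integer minimum complete copies for
#'   unit lengths 1 through 6. All must be at least 2.
#' @return Named integer vector of length 6 (names "1".."6").
#' @examples
#' ssr_thresholds()
#' ssr_thresholds(tri = 4)
#' @export
ssr_thresholds <- function(mono = 14L, di = 7L, tri = 5L,
                           tetra = 4L, penta = 4L, hexa = 4L) {
  thr <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (anyNA(thr) || any(thr < 2L))
    stop("all repeat-count thresholds must be integers >= 2")
  names(thr) <- as.character(1:6)
  thr
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.rotations <- function(s) {
  n <- nchar(s)
  ss <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(ss, i, i + n - 1L), character(1))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not a whole-number power of any shorter
#' string (e.g. "ACG" is primitive, "ATAT" is not).
#'
#' @param motif Character vector of nucleotide motifs.
#' @return Logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(s) {
    n <- nchar(s)
    if (n == 1L) return(TRUE)
    divs <- seq_len(n - 1L)
    divs <- divs[n %% divs == 0L]
    !any(vapply(divs, function(d)
      strrep(substr(s, 1L, d), n %/% d) == s, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical (fully standardized) SSR motif
#'
#' Maps a motif to the representative of its equivalence class under cyclic
#' rotation and reverse complementation: the lexicographically smallest
#' string among all rotations of the motif and all rotations of its reverse
#' complement. This is the "fully standardized" motif convention under which,
#' for example, CGT, GTA and CGA all report as ACG, and the 60 primitive
#' trinucleotides collapse to 10 classes.
#'
#' @param motif Character vector of motifs over A/C/G/T (case-insensitive).
#'   Each motif must be primitive.
#' @return Character vector of canonical motifs, same length as the input.
#' @examples
#' canonical_motif(c("CGT", "GGC", "A"))  # "ACG" "CCG" "A"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (any(!nzchar(motif)))
    stop("motif must be non-empty")
  if (any(grepl("[^ACGT]", motif)))
    stop("motif contains characters outside the A/C/G/T alphabet")
  if (!all(is_primitive_motif(motif)))
    stop("motif is not primitive (a whole-number power of a shorter string)")
  vapply(motif, function(s) {
    min(c(.rotations(s), .rotations(.revcomp(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Find perfect simple sequence repeats
#'
#' Scans nucleotide sequences for maximal perfect tandem repeats of 1-6 bp
#' motifs whose complete-copy count meets the per-unit-length threshold.
#' Each run is reported once, at the smallest primitive period that explains
#' it; the reported span covers complete copies only (a trailing partial
#' copy is excluded). `N` (and any other non-ACGT IUPAC code) breaks runs;
#' lowercase (soft-masked) bases are uppercased and scanned.
#'
#' @param sequences A named character vector of sequences, a single unnamed
#'   sequence, or a [Biostrings::DNAStringSet].
#' @param thresholds Named vector from [ssr_thresholds()].
#' @return A `data.frame` with one row per SSR locus: `scaffold`, `start`,
#'   `end` (1-based inclusive), `motif` (as found on the forward strand),
#'   `canonical_motif`, `unit_length`, `repeat_count`. Sorted by scaffold
#'   then start.
#' @examples
#' find_ssrs(c(chr = "ACGACGACGACGACG"))
#' @export
find_ssrs <- function(sequences, thresholds = ssr_thresholds()) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (!is.character(sequences))
    stop("sequences must be a character vector or DNAStringSet")
  if (is.null(names(sequences)) && length(sequences))
    names(sequences) <- if (length(sequences) == 1L) "seq1" else
      paste0("seq", seq_along(sequences))
  if (!all(as.character(1:6) %in% names(thresholds)))
    stop("thresholds must provide a minimum copy number for unit lengths 1-6")
  out <- lapply(names(sequences), function(id)
    .scan_one(toupper(sequences[[id]]), id, thresholds))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_motif = character(),
                      unit_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.scan_one <- function(seq, id, thresholds) {
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  x <- utf8ToInt(seq)
  ok <- x %in% utf8ToInt("ACGT")  # anything else (N, IUPAC) breaks runs
  rows <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    thr <- as.integer(thresholds[[as.character(k)]])
    m <- x[seq_len(n - k)] == x[(k + 1L):n] &
      ok[seq_len(n - k)] & ok[(k + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    prev_end <- 0L  # rightmost base already reported at this period
    for (b in which(r$values)) {
      i <- starts[b]; t <- r$lengths[b]
      full_end <- i + t + k - 1L
      # keep same-period loci disjoint: restart after the previous one
      lo <- max(i, prev_end + 1L)
      copies <- (full_end - lo + 1L) %/% k
      if (copies < thr) next
      unit <- substr(seq, lo, lo + k - 1L)
      if (!is_primitive_motif(unit)) next
      end <- lo + copies * k - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = id, start = lo, end = end, motif = unit,
        canonical_motif = canonical_motif(unit),
        unit_length = k, repeat_count = copies,
        stringsAsFactors = FALSE)
      prev_end <- end
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Write an SSR table to TSV
#'
#' @param ssrs Data frame from [find_ssrs()] (optionally with extra columns,
#'   e.g. the `category` added by [classify_ssrs()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(ssrs, path) {
  write.table(ssrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
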
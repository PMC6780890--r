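# IUPAC nucleotide codes -> the set of bases each matches
IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

#' Primer pair for merged amplicon reads
#'
#' The reverse primer is given as it appears at the 3' end of the merged
#' read, i.e. already reverse-complemented.  Defaults are the published
#' 515F/926R 16S pair.
#'
#' @param forward,reverse IUPAC strings.
#' @return A `primer_pair`.
#' @export
primer_pair <- function(forward = "GTGYCAGCMGCCGCGGTAA",
                        reverse = reverse_complement("CCGYCAATTYMTTTRAGTTT")) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  ok <- function(p) nchar(p) > 0 &&
    all(strsplit(p, "")[[1]] %in% names(IUPAC))
  if (!ok(forward) || !ok(reverse))
    stop("primers must be non-empty IUPAC strings")
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Reverse-complement an IUPAC sequence
#' @param x character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

# mismatch count of an anchored IUPAC primer against read windows;
# reads shorter than the primer get NA
anchored_mismatches <- function(bases, primer, from_end = FALSE) {
  np <- nchar(primer)
  nb <- nchar(bases)
  mm <- integer(length(bases))
  pch <- strsplit(primer, "")[[1]]
  for (i in seq_len(np)) {
    pos <- if (from_end) nb - np + i else rep.int(i, length(bases))
    rch <- substr(bases, pos, pos)
    allowed <- IUPAC[[pch[i]]]
    mm <- mm + as.integer(!(rch %in% allowed) | rch == "N")
  }
  mm[nb < np] <- NA_integer_
  mm
}

#' Locate and excise primers from merged reads
#'
#' The forward primer is expected at the 5' start and the (already
#' reverse-complemented) reverse primer at the 3' end; each may carry up to
#' `max_mismatch` mismatches under IUPAC-aware matching.  Reads lacking
#' either site are rejected.
#'
#' @param reads a [seq_set()].
#' @param primers a [primer_pair()].
#' @param max_mismatch maximum mismatches tolerated per primer (default 2).
#' @return List with `passed` (a `seq_set` of excised inserts, qualities
#'   trimmed in step) and `rejected` (read ids that lacked a primer).
#' @export
strip_primers <- function(reads, primers, max_mismatch = 2L) {
  stopifnot(inherits(reads, "seq_set"), inherits(primers, "primer_pair"))
  if (length(reads) == 0L)
    return(list(passed = reads, rejected = character(0)))
  nf <- nchar(primers$forward); nr <- nchar(primers$reverse)
  mmf <- anchored_mismatches(reads$bases, primers$forward, from_end = FALSE)
  mmr <- anchored_mismatches(reads$bases, primers$reverse, from_end = TRUE)
  long_enough <- nchar(reads$bases) >= nf + nr
  ok <- long_enough & !is.na(mmf) & !is.na(mmr) &
    mmf <= max_mismatch & mmr <= max_mismatch
  ins <- substr(reads$bases[ok], nf + 1L, nchar(reads$bases[ok]) - nr)
  quals <- lapply(which(ok), function(i) {
    q <- reads$quals[[i]]
    if (length(q) - nr < nf + 1L) integer(0)
    else q[seq.int(nf + 1L, length(q) - nr)]
  })
  list(passed = seq_set(reads$read_id[ok], ins, quals),
       rejected = reads$read_id[!ok])
}

#' Truncate reads at the first low-quality base
#'
#' A base whose Phred error probability `10^(-Q/10)` exceeds `p_err` ends
#' the read: it and everything after it are discarded.  The default
#' `p_err = 0.01` corresponds to Q20, so any base with Q < 20 truncates.
#' Truncation to length zero is allowed; the length filter removes such
#' reads later.
#'
#' @param reads a [seq_set()].
#' @param p_err error-probability threshold (default 0.01).
#' @return A truncated [seq_set()] (possibly containing empty reads).
#' @export
quality_truncate <- function(reads, p_err = 0.01) {
  stopifnot(inherits(reads, "seq_set"))
  cut_at <- vapply(reads$quals, function(q) {
    bad <- which(10^(-q / 10) > p_err)
    if (length(bad)) bad[1] - 1L else length(q)
  }, integer(1))
  bases <- substr(reads$bases, 1L, cut_at)
  quals <- lapply(seq_along(cut_at), function(i)
    reads$quals[[i]][seq_len(cut_at[i])])
  structure(list(read_id = reads$read_id, bases = bases, quals = quals),
            class = "seq_set")
}

#' Reject reads containing ambiguous bases
#'
#' A read is rejected if any base is not A/C/G/T (empty reads are rejected
#' here too, as they carry no unambiguous base).
#'
#' @param reads a [seq_set()].
#' @return Logical vector, `TRUE` = pass.
#' @export
remove_ambiguous <- function(reads) {
  stopifnot(inherits(reads, "seq_set"))
  nchar(reads$bases) > 0L & !grepl("[^ACGT]", reads$bases)
}

#' Minimum-length filter
#'
#' Pass iff the read length is at least `min_len` (300 bp for the 16S
#' marker, 100 bp for ITS).
#'
#' @param reads a [seq_set()].
#' @param min_len minimum length in bp.
#' @return Logical vector, `TRUE` = pass.
#' @export
length_filter <- function(reads, min_len) {
  stopifnot(inherits(reads, "seq_set"))
  nchar(reads$bases) >= min_len
}

#' Full read-preparation pipeline
#'
#' Applies, in fixed order: optional chimera drop (ids supplied by an
#' external tool), primer excision, quality truncation, ambiguity rejection
#' and length filtering.  Every input read lands in exactly one report
#' bucket.
#'
#' @param reads a [seq_set()].
#' @param primers a [primer_pair()].
#' @param max_mismatch per-primer mismatch tolerance.
#' @param p_err quality-truncation threshold.
#' @param min_len minimum insert length.
#' @param chimera_ids optional character vector of read ids to drop before
#'   any other step (pluggable chimera-removal hook).
#' @return List with `passed` (clean `seq_set`) and `report`, a one-row
#'   data.frame with `n_input`, `n_no_primer`, `n_too_short`, `n_ambiguous`,
#'   `n_passed` (and `n_chimera`, counted before `n_input`).
#' @export
prep_reads <- function(reads, primers = primer_pair(), max_mismatch = 2L,
                       p_err = 0.01, min_len = 300L, chimera_ids = NULL) {
  stopifnot(inherits(reads, "seq_set"))
  n_chim <- 0L
  if (!is.null(chimera_ids)) {
    keep <- !(reads$read_id %in% chimera_ids)
    n_chim <- sum(!keep)
    reads <- reads[keep]
  }
  n_input <- length(reads)
  sp <- strip_primers(reads, primers, max_mismatch)
  n_no_primer <- length(sp$rejected)
  tr <- quality_truncate(sp$passed, p_err)
  amb_ok <- remove_ambiguous(tr)
  n_ambiguous <- sum(!amb_ok)
  tr <- tr[amb_ok]
  len_ok <- length_filter(tr, min_len)
  n_too_short <- sum(!len_ok)
  passed <- tr[len_ok]
  report <- data.frame(n_input = n_input, n_no_primer = n_no_primer,
                       n_too_short = n_too_short, n_ambiguous = n_ambiguous,
                       n_passed = length(passed), n_chimera = n_chim)
  stopifnot(report$n_input ==
              report$n_no_primer + report$n_too_short +
              report$n_ambiguous + report$n_passed)
  list(passed = passed, report = report)
}
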
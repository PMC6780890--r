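#' Construct a set of sequence records
#'
#' A `seq_set` holds merged amplicon reads as three parallel vectors: read
#' identifiers, base strings over `{A,C,G,T,N}` and per-base Phred quality
#' scores.  It is the in-memory form of a FASTQ file; single records are
#' length-one sets.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of base strings (upper-cased on input; `U`
#'   is mapped to `T`).
#' @param quals list of integer vectors of Phred scores, one per read, each
#'   the same length as its base string.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(read_id, bases, quals) {
  read_id <- as.character(read_id)
  bases <- chartr("u", "t", toupper(as.character(bases)))
  bases <- chartr("U", "T", bases)
  if (length(read_id) != length(bases) || length(bases) != length(quals))
    stop("read_id, bases and quals must have equal length")
  nb <- nchar(bases)
  nq <- vapply(quals, length, integer(1))
  bad <- which(nb != nq)
  if (length(bad))
    stop(sprintf("base/quality length mismatch for read '%s' (%d bases, %d quality scores)",
                 read_id[bad[1]], nb[bad[1]], nq[bad[1]]))
  if (any(vapply(quals, function(q) any(q < 0L), logical(1))))
    stop("Phred scores must be non-negative")
  structure(list(read_id = read_id, bases = bases, quals = quals),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$read_id)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d read(s)\n", length(x)))
  n <- min(3L, length(x))
  for (i in seq_len(n))
    cat(sprintf("  %s  %s%s (%d bp)\n", x$read_id[i],
                substr(x$bases[i], 1, 40),
                if (nchar(x$bases[i]) > 40) "..." else "",
                nchar(x$bases[i])))
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Subset a seq_set
#' @param x a `seq_set`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.seq_set` <- function(x, i, ...) {
  seq_set(x$read_id[i], x$bases[i], x$quals[i])
}

seq_set_empty <- function() seq_set(character(0), character(0), list())
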
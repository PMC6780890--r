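#' Pairwise global-alignment identity
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1 and
#' gap -2 per column; identity is matches divided by alignment columns.
#' Among equal-score alignments the one with the most matches defines the
#' identity, which makes the value unique and the function symmetric.
#'
#' @param a,b non-empty nucleotide strings (case-insensitive; U = T).
#' @return Identity as a fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  a <- norm_seq(a); b <- norm_seq(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequence identity is undefined for empty sequences")
  .nw_identity(a, b)
}

#' Identity of every query against every target
#'
#' @param queries,targets character vectors of sequences.
#' @param threshold optional screening threshold: pairs that provably cannot
#'   reach it (by a shared 8-mer bound) are returned as `NA` without running
#'   the alignment; values at or above the threshold are always exact.
#'   `NULL` (default) computes every pair.
#' @return Numeric matrix, `length(queries)` x `length(targets)`.
#' @export
identity_matrix <- function(queries, targets, threshold = NULL) {
  queries <- norm_seq(queries); targets <- norm_seq(targets)
  if (is.null(threshold))
    .nw_identity_matrix(queries, targets)
  else
    .screened_identity_matrix(queries, targets, threshold)
}

norm_seq <- function(x) chartr("uU", "tT", toupper(as.character(x)))

# ---- dereplication --------------------------------------------------------

#' Dereplicate reads into unique sequences
#'
#' Exact-string grouping (case-insensitive, U mapped to T, no length
#' tolerance) with per-sample counts retained.  Output is sorted by
#' abundance (descending), then sequence id (ascending, C locale).
#'
#' @param bases character vector of read sequences, or a [seq_set()].
#' @param sample_id character vector assigning each read to a sample.
#' @param read_id optional read ids; the first read id seen for a sequence
#'   becomes its stable `seq_id` (defaults to `u<k>` in order of first
#'   appearance).
#' @return A `unique_seqs` object: parallel `seq_id`, `bases`, `abundance`
#'   plus a `counts` integer matrix (unique sequences x samples).
#' @export
dereplicate <- function(bases, sample_id, read_id = NULL) {
  if (inherits(bases, "seq_set")) {
    if (is.null(read_id)) read_id <- bases$read_id
    bases <- bases$bases
  }
  bases <- norm_seq(bases)
  if (length(bases) != length(sample_id))
    stop("bases and sample_id must have equal length")
  if (length(bases) == 0L)
    return(unique_seqs(character(0), character(0),
                       matrix(integer(0), 0, 0,
                              dimnames = list(NULL, character(0)))))
  f <- factor(bases)
  s <- factor(sample_id)
  counts <- unclass(table(f, s))
  dimnames(counts) <- list(NULL, levels(s))
  first <- match(levels(f), bases)
  ids <- if (is.null(read_id)) {
    ord_first <- rank(first)  # order of first appearance
    paste0("u", ord_first)
  } else as.character(read_id)[first]
  if (anyDuplicated(ids)) stop("derived sequence ids are not unique")
  unique_seqs(ids, levels(f), counts)
}

unique_seqs <- function(seq_id, bases, counts) {
  abundance <- as.integer(rowSums(counts))
  ord <- order(-abundance, seq_id, method = "radix")
  structure(list(seq_id = seq_id[ord], bases = bases[ord],
                 abundance = abundance[ord],
                 counts = counts[ord, , drop = FALSE]),
            class = "unique_seqs")
}

#' @export
length.unique_seqs <- function(x) length(x$seq_id)

#' @export
print.unique_seqs <- function(x, ...) {
  cat(sprintf("<unique_seqs> %d unique sequence(s), %d read(s), %d sample(s)\n",
              length(x), sum(x$abundance), ncol(x$counts)))
  invisible(x)
}

#' Subset unique sequences
#' @param x a `unique_seqs`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.unique_seqs` <- function(x, i, ...) {
  structure(list(seq_id = x$seq_id[i], bases = x$bases[i],
                 abundance = x$abundance[i],
                 counts = x$counts[i, , drop = FALSE]),
            class = "unique_seqs")
}

#' Split unique sequences into seeds and non-seeds
#'
#' Sequences with total abundance of at least `min_abundance` (across all
#' samples) become seed sequences; the partition is exhaustive and disjoint.
#'
#' @param uniques a `unique_seqs` from [dereplicate()].
#' @param min_abundance seed abundance threshold (default 10).
#' @return List with `seeds` and `non_seeds`, both `unique_seqs`.
#' @export
designate_seeds <- function(uniques, min_abundance = 10L) {
  stopifnot(inherits(uniques, "unique_seqs"))
  is_seed <- uniques$abundance >= min_abundance
  list(seeds = uniques[is_seed], non_seeds = uniques[!is_seed])
}

# ---- seed mapping ---------------------------------------------------------

#' Bin non-seed sequences onto their nearest seed
#'
#' Each non-seed is compared against every seed; if its best identity
#' reaches `threshold` its per-sample counts are merged into that seed's
#' counts, otherwise it remains an independent feature.  Assignment is
#' independent per non-seed (a non-seed never merges into another
#' non-seed) and the table is built in a single pass, without re-seeding.
#' Exact identity ties go to the higher-abundance seed, then to the
#' lexicographically smaller seed id.
#'
#' @param non_seeds,seeds `unique_seqs` partitions from [designate_seeds()]
#'   (`seeds` may be empty).
#' @param threshold minimum identity for merging (default 0.98).
#' @return A `subotu_result`: `features` (a `unique_seqs` of representatives
#'   with merged per-sample counts) and `mapping`, a data.frame with
#'   `seq_id`, `representative` and `role`
#'   (`"seed"`, `"merged"` or `"independent"`).
#' @export
map_to_seeds <- function(non_seeds, seeds, threshold = 0.98) {
  stopifnot(inherits(non_seeds, "unique_seqs"), inherits(seeds, "unique_seqs"))
  total_in <- sum(non_seeds$abundance) + sum(seeds$abundance)

  # align both partitions on the union of sample columns
  samples <- union(colnames(seeds$counts), colnames(non_seeds$counts))
  expand <- function(cm) {
    m <- matrix(0L, nrow(cm), length(samples),
                dimnames = list(NULL, samples))
    if (ncol(cm)) m[, colnames(cm)] <- cm
    m
  }
  seeds$counts <- expand(seeds$counts)
  non_seeds$counts <- expand(non_seeds$counts)

  ns <- length(non_seeds)
  rep_of <- character(ns)
  if (length(seeds) == 0L) {
    rep_of[] <- non_seeds$seq_id
  } else if (ns > 0L) {
    idm <- identity_matrix(non_seeds$bases, seeds$bases, threshold = threshold)
    for (i in seq_len(ns)) {
      row <- idm[i, ]
      elig <- which(!is.na(row) & row >= threshold)
      if (length(elig) == 0L) {
        rep_of[i] <- non_seeds$seq_id[i]
      } else {
        best <- elig[order(-row[elig], -seeds$abundance[elig],
                           seeds$seq_id[elig], method = "radix")[1]]
        rep_of[i] <- seeds$seq_id[best]
      }
    }
  }

  merged_counts <- seeds$counts
  if (length(seeds) && ns) {
    to_seed <- which(rep_of %in% seeds$seq_id)
    if (length(to_seed)) {
      tgt <- match(rep_of[to_seed], seeds$seq_id)
      for (u in seq_along(to_seed))
        merged_counts[tgt[u], ] <- merged_counts[tgt[u], ] +
          non_seeds$counts[to_seed[u], ]
    }
  }
  indep <- which(rep_of == non_seeds$seq_id)
  feats <- unique_seqs(c(seeds$seq_id, non_seeds$seq_id[indep]),
                       c(seeds$bases, non_seeds$bases[indep]),
                       rbind(merged_counts, non_seeds$counts[indep, , drop = FALSE]))
  mapping <- data.frame(
    seq_id = c(seeds$seq_id, non_seeds$seq_id),
    representative = c(seeds$seq_id, rep_of),
    role = c(rep("seed", length(seeds)),
             ifelse(rep_of == non_seeds$seq_id, "independent", "merged")),
    stringsAsFactors = FALSE)
  stopifnot(sum(feats$abundance) == total_in)
  structure(list(features = feats, mapping = mapping), class = "subotu_result")
}

#' @export
print.subotu_result <- function(x, ...) {
  cat(sprintf("<subotu_result> %d feature(s): %d seed(s), %d independent; %d merged\n",
              length(x$features), sum(x$mapping$role == "seed"),
              sum(x$mapping$role == "independent"),
              sum(x$mapping$role == "merged")))
  invisible(x)
}

#' Feature table from a sub-OTU result
#' @param result a `subotu_result`.
#' @param metadata optional sample metadata (see [feature_table()]).
#' @return A [feature_table()] of representative counts per sample.
#' @export
subotu_feature_table <- function(result, metadata = NULL) {
  stopifnot(inherits(result, "subotu_result"))
  counts <- result$features$counts
  rownames(counts) <- result$features$seq_id
  feature_table(counts, metadata = metadata)
}
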
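#' Identity thresholds for tiered taxonomy assignment
#'
#' Hits must reach the 90% floor to be collected at all; genus and species
#' assignment additionally require 97% and 99% identity respectively
#' (kingdom through family share the floor).
#'
#' @param floor minimum identity for any hit (default 0.90).
#' @param genus minimum identity for genus assignment (default 0.97).
#' @param species minimum identity for species assignment (default 0.99).
#' @return A `rank_thresholds` object.
#' @export
rank_thresholds <- function(floor = 0.90, genus = 0.97, species = 0.99) {
  if (!(floor <= genus && genus <= species))
    stop("thresholds must satisfy floor <= genus <= species")
  if (floor < 0 || species > 1) stop("thresholds must lie in [0, 1]")
  structure(list(floor = floor, genus = genus, species = species),
            class = "rank_thresholds")
}

#' Collect reference hits for a query sequence
#'
#' Every reference entry whose global-alignment identity to the query
#' reaches `floor` becomes a hit; hits are sorted by identity (descending)
#' with ties broken by reference id so that reference order never matters.
#'
#' @param query nucleotide string.
#' @param reference a `taxonomy_reference` from [read_reference()].
#' @param floor minimum identity (default 0.90).
#' @param identities optional precomputed identity vector over the
#'   reference entries (used by [assign_taxonomy()] to batch the
#'   alignments); computed here when `NULL`.
#' @return A `tax_hits` data.frame with columns `ref_id`, `identity` and the
#'   hit lineages in `attr(, "lineage")` (rows parallel to the data.frame).
#' @export
search_hits <- function(query, reference, floor = 0.90, identities = NULL) {
  stopifnot(inherits(reference, "taxonomy_reference"))
  if (length(reference$ref_id) == 0L) stop("reference is empty")
  if (is.null(identities))
    identities <- as.numeric(identity_matrix(query, reference$bases))
  keep <- which(identities >= floor)
  ord <- keep[order(-identities[keep], reference$ref_id[keep],
                    method = "radix")]
  hits <- data.frame(ref_id = reference$ref_id[ord],
                     identity = identities[ord],
                     stringsAsFactors = FALSE)
  attr(hits, "lineage") <- reference$lineage[ord, , drop = FALSE]
  class(hits) <- c("tax_hits", "data.frame")
  hits
}

rank_gate <- function(rank, thresholds) {
  switch(rank,
         genus = thresholds$genus,
         species = thresholds$species,
         thresholds$floor)
}

#' Tiered named-rank lineage assignment
#'
#' For each rank from kingdom to species, only hits that are *named* at
#' that rank are eligible, and the hit must reach the rank's identity gate
#' (the 90% floor for kingdom-family, 97% for genus, 99% for species).
#' The rank is assigned from the highest-identity eligible hit; ranks with
#' no eligible hit stay unnamed.  A reference named only down to family can
#' therefore supply kingdom-family while a slightly weaker, fully named hit
#' supplies the genus.
#'
#' @param hits a `tax_hits` from [search_hits()] (may have zero rows).
#' @param thresholds a [rank_thresholds()].
#' @return Named character vector of length 7 (`NA` = unnamed).
#' @export
assign_lineage <- function(hits, thresholds = rank_thresholds()) {
  lin <- attr(hits, "lineage")
  out <- rep(NA_character_, 7L)
  names(out) <- TAX_RANKS
  if (is.null(lin) || nrow(hits) == 0L) return(out)
  for (r in seq_along(TAX_RANKS)) {
    gate <- rank_gate(TAX_RANKS[r], thresholds)
    elig <- which(hits$identity >= gate & !is.na(lin[, r]))
    if (length(elig)) out[r] <- lin[elig[1], r]  # hits already sorted
  }
  out
}

#' Assign lineages to a set of feature representatives
#'
#' @param bases named character vector of representative sequences (names =
#'   feature ids), or a `unique_seqs`.
#' @param reference a `taxonomy_reference`.
#' @param thresholds a [rank_thresholds()].
#' @return Character matrix, features x 7 ranks, `NA` = unnamed.
#' @export
assign_taxonomy <- function(bases, reference, thresholds = rank_thresholds()) {
  if (inherits(bases, "unique_seqs")) {
    ids <- bases$seq_id
    bases <- bases$bases
  } else {
    ids <- names(bases)
    if (is.null(ids)) stop("bases must be named by feature id")
  }
  if (length(reference$ref_id) == 0L) stop("reference is empty")
  out <- matrix(NA_character_, length(bases), 7L,
                dimnames = list(ids, TAX_RANKS))
  if (length(bases) == 0L) return(out)
  idm <- identity_matrix(bases, reference$bases,
                         threshold = thresholds$floor)
  for (i in seq_along(bases)) {
    ident <- idm[i, ]
    ident[is.na(ident)] <- 0  # screened out: provably below the floor
    hits <- search_hits(bases[i], reference, floor = thresholds$floor,
                        identities = ident)
    out[i, ] <- assign_lineage(hits, thresholds)
  }
  out
}

#' Collapse a feature table at a taxonomic rank
#'
#' Features sharing a name at `rank` are summed; features unnamed at that
#' rank pool into the `"other"` category.  Counts are conserved.
#'
#' @param table a [feature_table()].
#' @param assignments lineage matrix from [assign_taxonomy()] (rows must
#'   cover the table's features).
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param other_label label for the unnamed pool (default `"other"`).
#' @return A [feature_table()] with taxa as features.
#' @export
collapse_table <- function(table, assignments, rank, other_label = "other") {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank, TAX_RANKS)
  feats <- rownames(table$counts)
  if (!all(feats %in% rownames(assignments)))
    stop("assignments missing features: ",
         paste(setdiff(feats, rownames(assignments)), collapse = ", "))
  grp <- assignments[feats, rank]
  grp[is.na(grp)] <- other_label
  agg <- rowsum(table$counts, group = grp)
  # named taxa sorted, 'other' last
  named <- sort(setdiff(rownames(agg), other_label))
  agg <- agg[c(named, intersect(other_label, rownames(agg))), , drop = FALSE]
  ft_replace_counts(table, agg)
}
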
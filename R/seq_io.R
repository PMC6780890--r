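#' Read a FASTQ file
#'
#' Parses Sanger (Phred+33) FASTQ.  Each record must be exactly four lines;
#' malformed records are reported with the offending line number rather than
#' silently skipped.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return A [seq_set()] in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # ignore a trailing blank line
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) return(seq_set_empty())
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record starting at line %d in %s",
                 4L * (length(lines) %/% 4L) + 1L, path))
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad))
    stop(sprintf("expected '@' header at line %d in %s", idx[bad[1]], path))
  plus <- lines[idx + 2L]
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad))
    stop(sprintf("expected '+' separator at line %d in %s", idx[bad[1]] + 2L, path))
  bases <- lines[idx + 1L]
  qstr <- lines[idx + 3L]
  bad <- which(nchar(bases) != nchar(qstr))
  if (length(bad))
    stop(sprintf("sequence/quality length mismatch at line %d in %s",
                 idx[bad[1]] + 3L, path))
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  quals <- lapply(qstr, function(s)
    if (nchar(s)) utf8ToInt(s) - 33L else integer(0))
  seq_set(ids, bases, quals)
}

#' Write a FASTQ file
#' @param x a [seq_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  qstr <- vapply(x$quals, function(q)
    if (length(q)) intToUtf8(q + 33L) else "", character(1))
  out <- character(4L * length(x))
  if (length(x)) {
    out[seq(1, length(out), 4)] <- paste0("@", x$read_id)
    out[seq(2, length(out), 4)] <- x$bases
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qstr
  }
  writeLines(out, path)
  invisible(path)
}

# ---- lineage-annotated reference FASTA ------------------------------------

#' Parse one semicolon-delimited lineage string
#'
#' Seven rank tokens (kingdom through species), optionally carrying
#' `k__`/`p__`/... prefixes.  An empty token after its prefix, or the
#' literal `unidentified`, marks the rank as unnamed (`NA`).
#'
#' @param s lineage string, e.g.
#'   `"k__Bacteria;p__Proteobacteria;c__;o__;f__;g__;s__"`.
#' @return Named character vector of length 7 with `NA` at unnamed ranks.
#' @export
parse_lineage <- function(s) {
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  # a trailing ';' yields an empty last token only when fewer than 7 present
  if (length(toks) == 8L && toks[8] == "") toks <- toks[1:7]
  if (length(toks) != 7L)
    stop(sprintf("expected 7 lineage ranks, got %d in: %s", length(toks), s))
  toks <- sub("^[kpcofgs]__", "", toks)
  toks[toks == "" | tolower(toks) == "unidentified"] <- NA_character_
  names(toks) <- TAX_RANKS
  toks
}

format_lineage <- function(lin) {
  pre <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  v <- ifelse(is.na(lin), "", lin)
  paste0(pre, v, collapse = ";")
}

#' Read a lineage-annotated reference FASTA
#'
#' Headers carry the entry id followed by a space or tab and a 7-rank
#' semicolon-delimited lineage, Silva/UNITE style.
#'
#' @param path FASTA path.
#' @return A `taxonomy_reference`: list with `ref_id`, `bases` and a
#'   7-column `lineage` character matrix (`NA` = unnamed rank).
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  m <- regexpr("[ \t]", hdr)
  if (any(m < 0))
    stop("reference header lacks a lineage: ", hdr[which(m < 0)[1]])
  ids <- substr(hdr, 1, m - 1)
  lin_str <- trimws(substring(hdr, m + 1))
  if (anyDuplicated(ids))
    stop("duplicate reference ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lin <- t(vapply(lin_str, parse_lineage, character(7)))
  rownames(lin) <- ids
  bases <- chartr("Uu", "Tt", toupper(as.character(ss)))
  structure(list(ref_id = ids, bases = unname(bases), lineage = lin),
            class = "taxonomy_reference")
}

#' @export
print.taxonomy_reference <- function(x, ...) {
  cat(sprintf("<taxonomy_reference> %d entries, %d genus-named\n",
              length(x$ref_id), sum(!is.na(x$lineage[, "genus"]))))
  invisible(x)
}

#' Write a lineage-annotated reference FASTA
#' @param ref a `taxonomy_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  hdr <- paste(ref$ref_id,
               apply(ref$lineage, 1, format_lineage))
  ss <- Biostrings::DNAStringSet(ref$bases)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write representative sequences as FASTA
#' @param ids,bases parallel character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, bases, path) {
  ss <- Biostrings::DNAStringSet(bases)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- feature table TSV ----------------------------------------------------

#' Write / read a feature table as TSV
#'
#' First column `feature_id`, remaining columns samples.  Integer tables
#' round-trip exactly.  Metadata is not serialised here; re-attach it on
#' read if needed.
#'
#' @param table a [feature_table()].
#' @param path TSV path.
#' @return `path` invisibly for the writer; a [feature_table()] for the
#'   reader.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  ids <- rownames(table$counts)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(feature_id = ids, table$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param metadata optional metadata to attach (see [feature_table()]).
#' @param normalised logical; whether values are relative abundances.
#' @export
read_feature_table <- function(path, metadata = NULL, normalised = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("feature table must start with a 'feature_id' column")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  if (any(counts < 0)) stop("negative counts in ", path)
  feature_table(counts, metadata = metadata, normalised = normalised)
}

# ---- sample manifest ------------------------------------------------------

#' Read a sample manifest
#'
#' TSV with columns `sample_id`, `chamber` (DC/MT), `generation` (1-3) and
#' `fastq_path` (resolved relative to the manifest's directory).
#'
#' @param path manifest TSV.
#' @param check_paths verify that every FASTQ exists (default `TRUE`).
#' @return data.frame with absolute `fastq_path`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chamber", "generation", "fastq_path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in manifest")
  if (!all(df$chamber %in% c("DC", "MT"))) stop("chamber must be DC or MT")
  if (!all(df$generation %in% 1:3)) stop("generation must be 1, 2 or 3")
  rel <- !grepl("^(/|[A-Za-z]:)", df$fastq_path)
  df$fastq_path[rel] <- file.path(dirname(normalizePath(path)),
                                  df$fastq_path[rel])
  if (check_paths) {
    missing <- df$fastq_path[!file.exists(df$fastq_path)]
    if (length(missing))
      stop("manifest FASTQ not found: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a sample manifest
#' @param manifest data.frame as returned by [read_manifest()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dendrogram in newick format
#' @param hc an `hclust` object (e.g. from [ward_dendrogram()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
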
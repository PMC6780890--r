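# End-to-end orchestration: read preparation -> sub-OTU binning ->
# taxonomy -> per-sample run report, over a sample manifest.

PIPELINE_KEYS <- c("marker", "max_mismatch", "p_err", "min_len",
                   "primer_forward", "primer_reverse",
                   "min_abundance", "identity_threshold",
                   "tax_floor", "tax_genus", "tax_species",
                   "seed")

#' Default pipeline configuration
#'
#' @param marker `"16S"` or `"ITS"`; sets the minimum insert length (300 /
#'   100 bp) and the default primer pair.
#' @return Named list of pipeline parameters.
#' @export
default_config <- function(marker = c("16S", "ITS")) {
  marker <- match.arg(marker)
  primers <- marker_primers(marker)
  list(marker = marker, max_mismatch = 2L, p_err = 0.01,
       min_len = marker_min_len(marker),
       primer_forward = primers$forward, primer_reverse = primers$reverse,
       min_abundance = 10L, identity_threshold = 0.98,
       tax_floor = 0.90, tax_genus = 0.97, tax_species = 0.99,
       seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a named list; unknown keys are rejected and
#' missing keys fall back to [default_config()] for the configured marker
#' (which itself is required).
#'
#' @param config path to a YAML file, or a named list.
#' @return A complete validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$marker)) stop("config must set 'marker'")
  if (!config$marker %in% c("16S", "ITS"))
    stop("marker must be '16S' or 'ITS'")
  full <- default_config(config$marker)
  full[names(config)] <- config
  fracs <- c(identity_threshold = full$identity_threshold,
             tax_floor = full$tax_floor, tax_genus = full$tax_genus,
             tax_species = full$tax_species, p_err = full$p_err)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad))
    stop("config values out of [0, 1]: ", paste(bad, collapse = ", "))
  if (full$min_abundance < 1) stop("min_abundance must be at least 1")
  if (full$min_len < 1) stop("min_len must be at least 1")
  if (full$max_mismatch < 0) stop("max_mismatch must be non-negative")
  rank_thresholds(full$tax_floor, full$tax_genus, full$tax_species)
  primer_pair(full$primer_forward, full$primer_reverse)
  full
}

#' Run the full amplicon pipeline over a manifest
#'
#' For every sample: FASTQ ingest and read preparation; then pooled
#' dereplication, seed designation and sub-OTU binning; tiered taxonomy
#' assignment of the feature representatives; phylum- and genus-level
#' collapsed tables; and a per-sample run report (total reads, reads
#' passing preparation, features observed, reads annotated at phylum and
#' genus).  All intermediates are written under `outdir` and every
#' threshold actually used is logged in the effective config dumped there.
#'
#' @param manifest manifest data.frame or TSV path (see [read_manifest()]).
#' @param reference a `taxonomy_reference` or FASTA path.
#' @param config configuration list or YAML path (see [validate_config()]).
#' @param outdir output directory.
#' @param chimera_ids optional read ids to drop before preparation
#'   (external chimera-detection hook).
#' @return A `pipeline_result`: `report` (per-sample run report),
#'   `table` (sub-OTU [feature_table()]), `assignments` (lineage matrix),
#'   `genus_table`, `phylum_table`, `subotu` (the full `subotu_result`)
#'   and `prep_reports`.
#' @export
run_pipeline <- function(manifest, reference, config = default_config(),
                         outdir, chimera_ids = NULL) {
  config <- validate_config(config)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(reference)) reference <- read_reference(reference)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(outdir, "run_state.tsv")
  writeLines("stage\tstatus", state_path)
  mark <- function(stage) cat(stage, "\tdone\n", sep = "",
                              file = state_path, append = TRUE)
  stage <- function(name, sample = NULL, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                   if (is.null(sample)) "" else paste0(" (sample ", sample, ")"),
                   conditionMessage(e)), call. = FALSE))
  }
  primers <- primer_pair(config$primer_forward, config$primer_reverse)

  clean_bases <- character(0)
  clean_samples <- character(0)
  clean_ids <- character(0)
  prep_reports <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    reads <- stage("read_fastq", s, read_fastq(manifest$fastq_path[i]))
    pr <- stage("read_prep", s,
                prep_reads(reads, primers,
                           max_mismatch = config$max_mismatch,
                           p_err = config$p_err,
                           min_len = config$min_len,
                           chimera_ids = chimera_ids))
    prep_reports[[s]] <- cbind(sample_id = s, pr$report)
    clean_bases <- c(clean_bases, pr$passed$bases)
    clean_samples <- c(clean_samples, rep(s, length(pr$passed)))
    clean_ids <- c(clean_ids, pr$passed$read_id)
  }
  prep_report <- do.call(rbind, c(prep_reports, make.row.names = FALSE))
  write.table(prep_report, file.path(outdir, "prep_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mark("read_prep")

  uniques <- stage("dereplicate", NULL,
                   dereplicate(clean_bases, clean_samples, clean_ids))
  parts <- designate_seeds(uniques, config$min_abundance)
  sub <- stage("map_to_seeds", NULL,
               map_to_seeds(parts$non_seeds, parts$seeds,
                            config$identity_threshold))
  meta <- manifest[, c("sample_id", "chamber", "generation")]
  # samples that lost every read would otherwise drop out of the table
  counts <- sub$features$counts
  missing <- setdiff(manifest$sample_id, colnames(counts))
  if (length(missing)) {
    pad <- matrix(0L, nrow(counts), length(missing),
                  dimnames = list(NULL, missing))
    counts <- cbind(counts, pad)[, manifest$sample_id, drop = FALSE]
  }
  rownames(counts) <- sub$features$seq_id
  table <- feature_table(counts, metadata = meta)
  write_feature_table(table, file.path(outdir, "feature_table.tsv"))
  write_fasta(sub$features$seq_id, sub$features$bases,
              file.path(outdir, "representatives.fasta"))
  write.table(sub$mapping, file.path(outdir, "subotu_mapping.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mark("subotu")

  thresholds <- rank_thresholds(config$tax_floor, config$tax_genus,
                                config$tax_species)
  assignments <- stage("taxonomy", NULL,
                       assign_taxonomy(sub$features, reference, thresholds))
  lin_df <- data.frame(feature_id = rownames(assignments), assignments,
                       stringsAsFactors = FALSE)
  write.table(lin_df, file.path(outdir, "lineage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  genus_table <- collapse_table(table, assignments, "genus")
  phylum_table <- collapse_table(table, assignments, "phylum")
  write_feature_table(genus_table, file.path(outdir, "genus_table.tsv"))
  write_feature_table(phylum_table, file.path(outdir, "phylum_table.tsv"))
  mark("taxonomy")

  named_phylum <- !is.na(assignments[, "phylum"])
  named_genus <- !is.na(assignments[, "genus"])
  report <- data.frame(
    sample_id = manifest$sample_id,
    total_reads = vapply(manifest$sample_id, function(s)
      prep_report$n_input[prep_report$sample_id == s] +
        prep_report$n_chimera[prep_report$sample_id == s], numeric(1)),
    passed_prep = vapply(manifest$sample_id, function(s)
      prep_report$n_passed[prep_report$sample_id == s], numeric(1)),
    features = colSums(table$counts > 0)[manifest$sample_id],
    phylum_annotated = colSums(table$counts[named_phylum, , drop = FALSE]
                               )[manifest$sample_id],
    genus_annotated = colSums(table$counts[named_genus, , drop = FALSE]
                              )[manifest$sample_id],
    row.names = NULL, stringsAsFactors = FALSE)
  stopifnot(all(report$genus_annotated <= report$phylum_annotated),
            all(report$phylum_annotated <= report$passed_prep),
            all(report$passed_prep <= report$total_reads))
  write.table(report, file.path(outdir, "run_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(config), file.path(outdir, "effective_config.yaml"))
  mark("report")

  structure(list(report = report, table = table, assignments = assignments,
                 genus_table = genus_table, phylum_table = phylum_table,
                 subotu = sub, uniques = uniques, prep_reports = prep_report,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d sample(s), %d sub-OTU feature(s), %d genus-level taxa\n",
              nrow(x$report), nrow(x$table$counts),
              nrow(x$genus_table$counts)))
  invisible(x)
}
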
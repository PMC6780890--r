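# Ground-truthed DC/MT enrichment-culture simulator.  Emits a lineage-
# annotated reference, per-sample true compositions across chambers x
# generations with core-taxon enrichment, and error-bearing merged reads
# with Phred qualities, so every pipeline stage can be exercised offline
# against a known truth.

#' Simulation configuration
#'
#' Defaults describe a two-chamber (DC/MT), three-generation enrichment
#' design: per-chamber log-normal baseline compositions, a designated set
#' of core genera whose weights are multiplied by `enrichment_factor` at
#' each later generation (then renormalised), and an MT chamber whose
#' non-filamentous genera are strongly down-weighted, mimicking a 0.2 um
#' membrane that only filamentous organisms (and their hitch-hikers) cross.
#'
#' @param n_genera number of genera in the community (default 24).
#' @param n_core number of designated core genera (default 3).
#' @param enrichment_factor per-generation weight multiplier for core
#'   genera (default 5).
#' @param core_baseline_share designed total generation-1 relative
#'   abundance of the core genera in each chamber, before MT depletion
#'   (default 0.35): chamber conditions favour the core taxa from the
#'   first generation on, so they start abundant rather than emerging
#'   from nothing, and the generation-1 community sits far enough from
#'   the enriched generations that the first generation clusters apart
#'   from generations 2-3.  The split of this share among the core
#'   genera, and of the remainder among the others, stays log-normally
#'   random.
#' @param base_lognormal_sigma sdlog of baseline genus weights (default 1.5).
#' @param depth_per_sample nominal reads per sample (default 20000); actual
#'   depths are drawn uniformly from `depth_jitter` times this.
#' @param depth_jitter two-element range for per-sample depth variation
#'   (default `c(0.8, 1.2)`).
#' @param error_rate per-base substitution probability on the insert
#'   (default 0.005).
#' @param unnamed_rank_fraction fraction of (non-core) reference entries
#'   left unnamed at genus and species (default 0.2).
#' @param mt_depletion multiplier applied to non-filamentous genus weights
#'   in the MT chamber baseline (default 0.02).
#' @param filamentous_fraction fraction of non-core genera flagged
#'   filamentous (core genera always are) (default 0.25).
#' @param low_qual_tail_fraction fraction of reads given a low-quality 3'
#'   tail (Q12) to exercise quality truncation (default 0.1).
#' @param marker `"16S"` (inserts 350-400 bp) or `"ITS"` (150-250 bp).
#' @param decidable_margin logical (default `TRUE`): push every non-core
#'   genus abundance out of the ambiguous band around the 0.2%
#'   core-abundance threshold (0.5x-2x, i.e. 0.1%-0.4%) to the nearest
#'   band edge on its own side of the threshold.  At the simulated depths
#'   an abundance inside that band cannot be classified against the
#'   threshold from count data, so without the margin the true core set is
#'   not recoverable by any detector; the repair keeps each genus's
#'   qualification status and moves the (tiny) probability difference onto
#'   the sample's most abundant genus.
#' @param seed RNG seed; all outputs are byte-identical under the same seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genera = 24L, n_core = 3L, enrichment_factor = 5,
                       core_baseline_share = 0.35,
                       base_lognormal_sigma = 1.5, depth_per_sample = 20000L,
                       depth_jitter = c(0.8, 1.2), error_rate = 0.005,
                       unnamed_rank_fraction = 0.2, mt_depletion = 0.02,
                       filamentous_fraction = 0.25,
                       low_qual_tail_fraction = 0.1,
                       marker = c("16S", "ITS"), decidable_margin = TRUE,
                       seed = 1L) {
  marker <- match.arg(marker)
  cfg <- list(n_genera = as.integer(n_genera), n_core = as.integer(n_core),
              enrichment_factor = enrichment_factor,
              core_baseline_share = core_baseline_share,
              base_lognormal_sigma = base_lognormal_sigma,
              depth_per_sample = as.integer(depth_per_sample),
              depth_jitter = depth_jitter, error_rate = error_rate,
              unnamed_rank_fraction = unnamed_rank_fraction,
              mt_depletion = mt_depletion,
              filamentous_fraction = filamentous_fraction,
              low_qual_tail_fraction = low_qual_tail_fraction,
              marker = marker,
              decidable_margin = isTRUE(decidable_margin),
              seed = as.integer(seed))
  if (cfg$n_core > cfg$n_genera) stop("n_core must not exceed n_genera")
  if (cfg$n_core < 0 || cfg$n_genera < 1) stop("invalid community sizes")
  probs <- c(error_rate, unnamed_rank_fraction, mt_depletion,
             filamentous_fraction, low_qual_tail_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (enrichment_factor <= 0) stop("enrichment_factor must be positive")
  if (n_core > 0 && (core_baseline_share <= 0 || core_baseline_share >= 1))
    stop("core_baseline_share must lie in (0, 1)")
  if (length(depth_jitter) != 2 || depth_jitter[1] > depth_jitter[2] ||
      depth_jitter[1] <= 0)
    stop("depth_jitter must be an increasing positive range")
  structure(cfg, class = "sim_config")
}

insert_length_range <- function(marker) {
  if (marker == "16S") c(350L, 400L) else c(150L, 250L)
}

#' Default primer pair for a marker
#'
#' The published 515F/926R pair for 16S and ITS1F/ITS2R for ITS, with the
#' reverse primer reverse-complemented as it appears on merged reads.
#'
#' @param marker `"16S"` or `"ITS"`.
#' @return A [primer_pair()].
#' @export
marker_primers <- function(marker = c("16S", "ITS")) {
  marker <- match.arg(marker)
  if (marker == "16S")
    primer_pair("GTGYCAGCMGCCGCGGTAA",
                reverse_complement("CCGYCAATTYMTTTRAGTTT"))
  else
    primer_pair("CTTGGTCATTTAGAGGAAGTAA",
                reverse_complement("GCTGCGTTCTTCATCGATGC"))
}

#' Marker-specific minimum insert length
#' @param marker `"16S"` or `"ITS"`.
#' @return 300 for 16S, 100 for ITS.
#' @export
marker_min_len <- function(marker = c("16S", "ITS")) {
  if (match.arg(marker) == "16S") 300L else 100L
}

genus_names <- function(n) sprintf("Genus%02d", seq_len(n))

#' Generate a synthetic lineage-annotated reference
#'
#' One random template (primer-free insert) per genus, with pairwise
#' identity between genera forced to at most 0.95; a configured fraction
#' of non-core entries is left unnamed at genus and species to exercise
#' the named-rank assignment rules.
#'
#' @param config a [sim_config()].  Uses the current RNG state; seed it via
#'   [simulate_dataset()] or `set.seed()`.
#' @return List with `reference` (a `taxonomy_reference`), `genus` (genus
#'   of every entry, including unnamed ones), `core_genera` and
#'   `filamentous` (logical per genus).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genera
  gn <- genus_names(n)
  lr <- insert_length_range(config$marker)
  lens <- sample(seq.int(lr[1], lr[2]), n, replace = TRUE)
  bases <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  # reject templates closer than 95% identity to an earlier one
  for (tries in 1:25) {
    if (n < 2) break
    idm <- identity_matrix(bases, bases, threshold = 0.951)
    diag(idm) <- NA
    close_pairs <- which(!is.na(idm) & idm > 0.95, arr.ind = TRUE)
    if (nrow(close_pairs) == 0L) break
    redo <- unique(pmax(close_pairs[, 1], close_pairs[, 2]))
    for (i in redo)
      bases[i] <- paste(sample(c("A", "C", "G", "T"), lens[i],
                               replace = TRUE), collapse = "")
  }

  core <- gn[seq_len(config$n_core)]
  phyla <- sprintf("Phylum%s", LETTERS[((seq_len(n) - 1) %% 4) + 1])
  lineage <- cbind(kingdom = rep("Bacteria", n),
                   phylum = phyla,
                   class = paste0(phyla, "_class"),
                   order = paste0(phyla, "_order"),
                   family = paste0(gn, "_family"),
                   genus = gn,
                   species = paste0(gn, "_sp"))
  non_core_idx <- which(!(gn %in% core))
  n_unnamed <- round(config$unnamed_rank_fraction * n)
  n_unnamed <- min(n_unnamed, length(non_core_idx))
  if (n_unnamed > 0) {
    unnamed <- sample(non_core_idx, n_unnamed)
    lineage[unnamed, c("genus", "species")] <- NA_character_
  }
  ids <- paste0("ref_", gn)
  rownames(lineage) <- ids
  reference <- structure(list(ref_id = ids, bases = bases, lineage = lineage),
                         class = "taxonomy_reference")
  filamentous <- gn %in% core
  if (length(non_core_idx)) {
    n_fil <- round(config$filamentous_fraction * length(non_core_idx))
    if (n_fil > 0)
      filamentous[sample(non_core_idx, n_fil)] <- TRUE
  }
  names(filamentous) <- gn
  list(reference = reference, genus = gn, core_genera = core,
       filamentous = filamentous)
}

#' Simulate true community compositions
#'
#' Generation-1 compositions come from per-chamber log-normal weights,
#' with the core genera rescaled to their designed
#' `core_baseline_share` (chamber conditions favour them from the start)
#' and the MT chamber's non-filamentous
#' weights multiplied by `mt_depletion` before normalisation.  Each later
#' generation multiplies the core-genus weights by `enrichment_factor`
#' and renormalises, so an `enrichment_factor` of 1 leaves all
#' generations identical.
#'
#' @param config a [sim_config()] (uses the current RNG state).
#' @param ref result of [make_reference()].
#' @return List with `compositions` (genera x samples matrix of fractions
#'   summing to 1), `metadata` (sample_id, chamber, generation) and
#'   `true_core` (genera meeting the core thresholds in the true
#'   compositions, at the package defaults of 20% prevalence / 0.2%
#'   abundance).
#' @export
simulate_compositions <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"))
  gn <- ref$genus
  n <- length(gn)
  is_core <- gn %in% ref$core_genera
  chambers <- c("DC", "MT")
  gens <- 1:3
  samples <- as.vector(outer(chambers, gens, function(c, g)
    sprintf("%s_gen%d", c, g)))
  comp <- matrix(0, n, length(samples), dimnames = list(gn, samples))
  meta <- data.frame(sample_id = samples,
                     chamber = rep(chambers, times = length(gens)),
                     generation = rep(gens, each = length(chambers)),
                     stringsAsFactors = FALSE)
  for (ch in chambers) {
    w <- rlnorm(n, meanlog = 0, sdlog = config$base_lognormal_sigma)
    if (any(is_core) && !all(is_core)) {
      # rescale core weights so their designed generation-1 share holds
      share <- config$core_baseline_share
      w[is_core] <- w[is_core] * (share / (1 - share)) *
        sum(w[!is_core]) / sum(w[is_core])
    }
    if (ch == "MT")
      w[!ref$filamentous] <- w[!ref$filamentous] * config$mt_depletion
    for (g in gens) {
      wg <- w
      wg[is_core] <- wg[is_core] * config$enrichment_factor^(g - 1)
      comp[, sprintf("%s_gen%d", ch, g)] <- wg / sum(wg)
    }
  }
  if (config$decidable_margin)
    comp <- enforce_core_margin(comp, core = gn[is_core])
  frac <- rowMeans(comp >= 0.002)
  true_core <- gn[frac >= 0.20]
  list(compositions = comp, metadata = meta, true_core = true_core)
}

# Push non-core abundances out of the (0.5x, 2x) band around the core
# threshold to the band edge on their own side, so that core membership in
# the true compositions is decidable from finite count data; the residual
# probability mass goes to the sample's most abundant genus (always far
# from the band).
enforce_core_margin <- function(comp, core, threshold = 0.002,
                                band = c(0.5, 2)) {
  lo <- band[1] * threshold
  hi <- band[2] * threshold
  for (s in colnames(comp)) {
    x <- comp[, s]
    absorber <- names(x)[which.max(x)]
    adjustable <- setdiff(names(x), c(core, absorber))
    inside <- adjustable[x[adjustable] > lo & x[adjustable] < hi]
    if (length(inside)) {
      x[inside] <- ifelse(x[inside] < threshold, lo, hi)
      x[absorber] <- x[absorber] + (1 - sum(x))
      comp[, s] <- x
    }
  }
  comp
}

# resolve IUPAC ambiguity codes to concrete bases, independently per read
concrete_primers <- function(primer, n) {
  ch <- strsplit(primer, "")[[1]]
  cols <- lapply(ch, function(c) {
    opts <- IUPAC[[c]]
    if (length(opts) == 1) rep(opts, n) else sample(opts, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

mutate_insert <- function(template_chars, n_reads, error_rate) {
  L <- length(template_chars)
  k <- rbinom(n_reads, L, error_rate)
  out <- character(n_reads)
  base_str <- paste(template_chars, collapse = "")
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in seq_len(n_reads)) {
    if (k[i] == 0L) { out[i] <- base_str; next }
    ch <- template_chars
    pos <- sample.int(L, k[i])
    for (p in pos) ch[p] <- sample(alts[[ch[p]]], 1)
    out[i] <- paste(ch, collapse = "")
  }
  out
}

#' Simulate error-bearing merged reads for every sample
#'
#' Per sample, the read count is the jittered depth; source genera are
#' multinomial draws from the true composition; each read is its genus
#' template with iid substitutions at `error_rate`, flanked by the marker
#' primers (IUPAC positions resolved per read).  Qualities are constant
#' Q35 except for a configured fraction of reads that receive a Q12 3'
#' tail.
#'
#' @param compositions result of [simulate_compositions()].
#' @param ref result of [make_reference()].
#' @param config a [sim_config()] (uses the current RNG state).
#' @return List of per-sample [seq_set()]s plus `read_truth`, a data.frame
#'   mapping every read id to its sample and source genus.
#' @export
simulate_reads <- function(compositions, ref, config) {
  stopifnot(inherits(config, "sim_config"))
  primers <- marker_primers(config$marker)
  comp <- compositions$compositions
  tmpl_chars <- strsplit(ref$reference$bases, "")
  names(tmpl_chars) <- ref$genus
  reads <- list()
  truth <- list()
  for (s in colnames(comp)) {
    depth <- as.integer(round(config$depth_per_sample *
                                runif(1, config$depth_jitter[1],
                                      config$depth_jitter[2])))
    n_per_genus <- as.integer(rmultinom(1, depth, comp[, s]))
    src <- rep(ref$genus, n_per_genus)
    bases <- character(depth)
    pos <- 1L
    for (gi in which(n_per_genus > 0L)) {
      ng <- n_per_genus[gi]
      bases[seq.int(pos, pos + ng - 1L)] <-
        mutate_insert(tmpl_chars[[gi]], ng, config$error_rate)
      pos <- pos + ng
    }
    fwd <- concrete_primers(primers$forward, depth)
    rev <- concrete_primers(primers$reverse, depth)
    full <- paste0(fwd, bases, rev)
    lens <- nchar(full)
    quals <- lapply(lens, function(L) rep(35L, L))
    n_tail <- rbinom(1, depth, config$low_qual_tail_fraction)
    if (n_tail > 0) {
      tailed <- sample.int(depth, n_tail)
      tail_len <- sample(25:45, n_tail, replace = TRUE)
      for (u in seq_along(tailed)) {
        i <- tailed[u]
        tl <- min(tail_len[u], lens[i])
        quals[[i]][seq.int(lens[i] - tl + 1L, lens[i])] <- 12L
      }
    }
    ids <- sprintf("%s_r%05d", s, seq_len(depth))
    reads[[s]] <- seq_set(ids, full, quals)
    truth[[s]] <- data.frame(read_id = ids, sample_id = s, genus = src,
                             stringsAsFactors = FALSE)
  }
  list(reads = reads, read_truth = do.call(rbind, c(truth,
                                                    make.row.names = FALSE)))
}

#' Simulate a complete DC/MT dataset on disk
#'
#' Seeds the RNG from `config$seed`, generates reference, compositions and
#' reads, and writes FASTQ files, the reference FASTA, a sample manifest
#' and truth tables under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `manifest`, `reference_path`, `truth`
#'   (compositions, metadata, true core, designed core, read truth) and
#'   `config`.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  ref <- make_reference(config)
  comps <- simulate_compositions(config, ref)
  sim <- simulate_reads(comps, ref, config)

  ref_path <- file.path(outdir, "reference.fasta")
  write_reference(ref$reference, ref_path)
  manifest <- comps$metadata
  manifest$fastq_path <- file.path(outdir,
                                   paste0(manifest$sample_id, ".fastq"))
  for (s in manifest$sample_id)
    write_fastq(sim$reads[[s]],
                manifest$fastq_path[manifest$sample_id == s])
  # FASTQ paths in the on-disk manifest are relative to its own directory
  disk_manifest <- manifest
  disk_manifest$fastq_path <- basename(disk_manifest$fastq_path)
  write_manifest(disk_manifest, file.path(outdir, "manifest.tsv"))
  comp_df <- data.frame(genus = rownames(comps$compositions),
                        comps$compositions, check.names = FALSE)
  write.table(comp_df, file.path(outdir, "true_compositions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$read_truth, file.path(outdir, "read_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(unclass(config)),
             file.path(outdir, "sim_config.yaml"))
  invisible(list(manifest = manifest, reference_path = ref_path,
                 truth = list(compositions = comps$compositions,
                              metadata = comps$metadata,
                              true_core = comps$true_core,
                              designed_core = ref$core_genera,
                              filamentous = ref$filamentous,
                              read_truth = sim$read_truth),
                 config = config))
}
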
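#!/usr/bin/env Rscript
# Community analysis of the genus-level table produced by 02_pipeline.R:
# low-count and low-variance
# filtering, rarefaction to the minimum library, total-sum scaling, core
# microbiome (20% prevalence, 0.2% relative abundance), Chao1 alpha
# diversity with a group test, Bray-Curtis beta diversity with PCoA and
# PERMANOVA, a Ward dendrogram, rarefaction curves, and a permutation
# test for generation-1 vs generations-2/3 differential abundance.

library(subotu)

manifest <- read_manifest("results/sim/manifest.tsv")
meta <- manifest[, c("sample_id", "chamber", "generation")]
genus <- read_feature_table("results/run/genus_table.tsv", metadata = meta)
designed_core <- readLines("results/sim/designed_core.txt")
true_core <- readLines("results/sim/true_core.txt")
dir.create("results/community", showWarnings = FALSE, recursive = TRUE)

## feature filtering (kept permissive at this scale; counts reported)
filt <- filter_low_count(genus, min_count = 4, prevalence = 0.20)
cat(sprintf("Low-count filter removed %d genus-level features\n",
            attr(filt, "n_removed")))
filt <- filter_low_variance(filt, quantile = 0.10)
cat(sprintf("Low-variance (IQR) filter removed %d features\n",
            attr(filt, "n_removed")))

## rarefaction + total-sum scaling
rare <- rarefy(filt, seed = 1L)
tss <- total_sum_scale(rare)
write_feature_table(tss, "results/community/genus_tss.tsv")

## core microbiome (the 'other' pool of unnamed genera is not a taxon and
## is excluded from the call set)
core <- setdiff(core_microbiome(tss, prevalence = 0.20,
                                min_rel_abund = 0.002), "other")
cat("\nCore genera detected:", paste(core, collapse = ", "), "\n")
cat(sprintf("Designed core recovered: %s; calls outside the true core: %d\n",
            all(designed_core %in% core),
            length(setdiff(core, true_core))))
writeLines(core, "results/community/core_genera.txt")

## alpha diversity: Chao1 on the rarefied counts, generation comparison
chao <- apply(rare$counts, 2, chao1)
alpha <- compare_alpha(chao, meta$generation[match(colnames(rare$counts),
                                                   meta$sample_id)])
cat(sprintf("\nChao1 by sample:\n"))
print(round(chao, 2))
cat(sprintf("Alpha diversity across generations: %s statistic %.3f, p = %.3f\n",
            alpha$method, alpha$statistic, alpha$p_value))

## beta diversity: Bray-Curtis, PCoA, PERMANOVA, Ward dendrogram
d <- bray_curtis(tss)
ord <- pcoa(d)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates, check.names = FALSE)
write.table(coords, "results/community/pcoa_coordinates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nPCoA axes 1-2 explain %.1f%% + %.1f%% of (positive) inertia\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))

grp_gen <- meta$generation[match(colnames(d), meta$sample_id)]
pmv <- permanova(d, grp_gen, n_permutations = 999, seed = 2L)
cat(sprintf("PERMANOVA (generation): pseudo-F %.3f, R2 %.4f, p %.4f\n",
            pmv$pseudo_F, pmv$R2, pmv$p_value))

hc <- ward_dendrogram(d)
write_newick(hc, "results/community/ward_dendrogram.nwk")
coph <- as.matrix(stats::cophenetic(hc))
sep <- all(vapply(c("DC", "MT"), function(ch)
  coph[paste0(ch, "_gen2"), paste0(ch, "_gen3")] <
    min(coph[paste0(ch, "_gen1"), paste0(ch, "_gen2")],
        coph[paste0(ch, "_gen1"), paste0(ch, "_gen3")]), logical(1)))
cat(sprintf("Generation 1 separates from generations 2-3 in the dendrogram: %s\n",
            sep))

## rarefaction curves per sample
depths <- round(seq(50, min(library_sizes(filt)), length.out = 8))
curves <- do.call(rbind, lapply(colnames(filt$counts), function(s) {
  cbind(sample_id = s,
        rarefaction_curve(filt$counts[, s], depths, reps = 10, seed = 3L))
}))
write.table(curves, "results/community/rarefaction_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## differential abundance: generation 1 vs generations 2-3
g1 <- meta$sample_id[meta$generation == 1]
g23 <- meta$sample_id[meta$generation > 1]
da <- diff_abundance(filt, g23, g1, seed = 4L)
write.table(da, "results/community/diff_abundance_gen1_vs_rest.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- da$feature_id[da$significant]
cat(sprintf("\n%d genera differentially abundant (BH-adjusted p < 0.05): %s\n",
            length(sig), paste(head(sig, 10), collapse = ", ")))
cat("(with 6 samples split 4 vs 2 the label-permutation space has 15\n",
    " assignments, so the smallest attainable p is 1/15 = 0.067; effect\n",
    " sizes and raw p-values are the informative output at this scale)\n",
    sep = "")
cat("Core-genus log2 fold changes (generations 2-3 over generation 1):\n")
print(da[da$feature_id %in% designed_core,
         c("feature_id", "log2fc", "p_adjusted")], row.names = FALSE)
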
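Package: subotu
Title: Sub-OTU Amplicon Binning and Enrichment-Culture Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Re-implementation, as a tested and reusable workflow, of an
    amplicon analysis pipeline for diffusion-chamber (DC) and microbial-trap
    (MT) enrichment cultures: merged-read cleaning (primer excision, quality
    truncation, ambiguity and length filters), abundance-seeded sub-OTU
    binning of dereplicated sequences at a 98 percent identity threshold,
    named-rank tiered taxonomy assignment against a lineage-annotated
    reference (90/97/99 percent identity gates), and downstream community
    statistics (prevalence and variance filtering, rarefaction, total-sum
    scaling, core-microbiome detection, Chao1, Bray-Curtis, PCoA, PERMANOVA,
    Ward clustering, permutation-based differential abundance).  A
    ground-truthed synthetic DC/MT read simulator provides a fully offline
    test surface for every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
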
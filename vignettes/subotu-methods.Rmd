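---
title: "Methods: sub-OTU binning and enrichment-culture community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-OTU binning and enrichment-culture community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
conventions behind the package, and states what its simulation-based
validation does and does not show.

# The pipeline

Inputs are demultiplexed, already-merged amplicon reads (FASTQ, Phred+33),
a lineage-annotated reference FASTA (seven semicolon-delimited ranks per
header; empty or `unidentified` tokens mark unnamed ranks), and a sample
manifest recording chamber type (diffusion chamber, DC, or microbial
trap, MT) and generation (1–3) per library.

## Read preparation

Stages run in a fixed order — primer excision, quality truncation,
ambiguity rejection, length filter — and every input read lands in
exactly one report bucket, so the report always partitions the input.

* **Primers.** The forward primer is matched at the 5′ start and the
  reverse primer (as its reverse complement) at the 3′ end, IUPAC-aware,
  each tolerating `max_mismatch` mismatches (default 2; common practice,
  as merged reads begin and end in primer). Reads lacking either site
  are discarded; matching is anchored because merged amplicons carry the
  primers at their termini by construction. Primer sequences are supplied
  by configuration; the published 515F/926R (16S) and ITS1F/ITS2R (ITS)
  pairs are the defaults.
* **Quality truncation at p = 0.01.** A read is cut immediately before
  the first base whose Phred error probability $10^{-Q/10}$ exceeds
  0.01 — i.e. the first base with Q < 20, since Q20 corresponds to
  p = 0.01 exactly. We read the threshold as a per-base truncation rule
  rather than a global expected-error filter: it is the simplest rule
  consistent with a single per-read quality threshold, and it is
  configurable (`p_err`). Truncation to length zero is allowed; such
  reads are removed by the downstream filters.
* **Ambiguity.** Any read containing a non-ACGT base after truncation is
  rejected outright. Trimming interior Ns instead would fragment
  amplicons; rejection is conservative and easy to reason about.
* **Length.** Pass iff the *insert* (primers excised) is at least
  `min_len`: 300 bp for 16S, 100 bp for ITS. The filter applies after
  excision because the thresholds describe processed reads.
* **Chimeras.** Chimera detection is out of scope; `prep_reads()` accepts
  an externally produced list of read ids to drop before any other
  stage, as a pluggable hook.

Idempotence holds for the truncation/ambiguity/length stages composed
(running them twice equals once). Primer excision is intrinsically not
idempotent — its output no longer contains primers — so it is excluded
from that property.

## Sub-OTU binning

Cleaned reads from all samples are pooled and dereplicated by exact
string identity (case-insensitive, U→T), keeping per-sample counts.
Unique sequences with total abundance ≥ 10 (across samples — the
dereplication pools samples, so seed designation does too; configurable)
become **seeds**. Every non-seed is compared against all seeds and merged
into the *nearest* seed whose identity reaches 98%, else it remains an
independent feature. Assignment is a single pass and independent per
non-seed: a non-seed never merges into another non-seed, and sub-OTUs are
not re-seeded after merging.

**Identity** is pinned to global (end-to-end) alignment with match +1,
mismatch −1, gap −2 per column, identity = matches / alignment columns.
Because several alignments can share the optimal score, the definition
maximises (score, matches) lexicographically; with $M$ matches and $P$
aligned pairs, score $= 2M + 3P - 2(l_a + l_b)$, so fixing score and $M$
fixes $P$ and the column count — the identity is unique and symmetric.
The kernel is C++ (packed 64-bit DP). Two exact shortcuts keep the
pipeline fast without changing any result:

* a q-gram screen: if identity ≥ t then edit distance
  $e \le (l_a+l_b)(1-t)/(1+t)$, and sequences at edit distance $e$ share
  at least $(L_{\min}-7) - 8e$ 8-mers; pairs sharing fewer are provably
  below threshold and skipped;
* equal-length pairs with ≤ 2 mismatches: any gapped alignment of
  equal-length strings has ≥ 2 gap columns and score ≤ L − 5 < L − 2m,
  so the ungapped identity $(L-m)/L$ is optimal.

Ties on identity go to the higher-abundance seed, then the
lexicographically smaller seed id, making results invariant to input
order. Count conservation (reads in = table total) is asserted inside
`map_to_seeds()`.

## Tiered taxonomy

Hits are all reference entries at ≥ 90% identity to the query, sorted by
identity then reference id (so reference order never matters). Each rank
kingdom→species is assigned from the highest-identity hit that is
*named at that rank* and reaches the rank's gate: the 90% floor for
kingdom–family, 97% for genus, 99% for species. The 90% floor is applied
both when collecting hits and as the kingdom–family gate (the two
readings coincide at the same value). Assignment is best-eligible-hit
rather than a consensus of the top N: the named-rank rule is the
mechanism of interest and best-hit is its minimal deterministic reading.
Unassignable ranks stay unnamed; `collapse_table()` pools features
unnamed at the collapse rank into an `"other"` category, conserving
counts.

## Community statistics

All implemented in the package (with vegan/ape/stats used as independent
cross-checks in the test suite, never as the implementation):

* **Filtering.** Low count: keep features with ≥ `min_count` (4) counts
  in ≥ 20% of samples. Low variance: drop the lowest
  `floor(quantile · n)` features by IQR (10%), ties broken by feature
  id. These mirror a popular web workflow's defaults, which the workflow
  names but does not print; the values here are documented assumptions,
  configurable.
* **Rarefaction** without replacement to the minimum library size
  (seeded); **total-sum scaling** to relative abundances, with a
  `normalised` flag so downstream operations can refuse the wrong form.
* **Core microbiome**: features at ≥ 0.2% relative abundance in ≥ 20% of
  samples, both thresholds inclusive (boundaries must be defined to be
  testable). The source protocol states 20% prevalence in its methods
  and 50% in its results; 20% is the default, either value can be
  passed.
* **Chao1** (bias-corrected): $S_{obs} + F_1(F_1-1)/(2(F_2+1))$.
* **Bray–Curtis**, **PCoA** (Gower double-centering of $-d^2/2$,
  eigendecomposition; negative eigenvalues reported but excluded from
  coordinates and explained proportions), **PERMANOVA** (pseudo-F from
  squared inter-point distances, $p = (1+b)/(1+m)$ under random
  relabelling — never exactly zero), **Ward clustering** (Lance–Williams
  on squared distances, heights on the distance scale, i.e. ward.D2;
  deterministic tie-break by smallest merged-cluster id), newick export.
* **Differential abundance** is a label-permutation test on the log2
  ratio of mean relative abundances (pseudocount 1e-4), BH-adjusted;
  when the label space has ≤ 10,000 combinations the test enumerates it
  exhaustively, making the smallest attainable p-value exact. This is a
  deliberate design choice over count-model tools such as edgeR: the
  contract here is group-difference detection with FDR control,
  verifiable by simulation and exhaustive enumeration, not a
  reimplementation of a published external method.
* **Alpha comparison**: Welch t for two groups, one-way ANOVA for more.

# The simulator

`simulate_dataset()` generates the full study design: 2 chambers × 3
generations, one library each, with designed core genera, per-sample
FASTQ, a lineage-annotated reference, a manifest, and complete ground
truth (compositions, read→genus map, core sets).

Design choices, with rationale:

* **Templates** are random sequences (350–400 bp for 16S, 150–250 bp for
  ITS) forced to ≤ 95% pairwise identity, so the 98% binning threshold
  can never merge across genera. Primers flank the reads, not the
  reference entries: taxonomy queries are primer-stripped inserts, and
  keeping primers in the reference would depress every identity by
  ~10% and make the genus/species gates unreachable.
* **Compositions.** Per-chamber log-normal baselines (σ = 1.5). The core
  genera are rescaled to a designed generation-1 share of 35%
  (`core_baseline_share`): enrichment chambers favour the core taxa from
  the start, and this places generation 1 far enough from the enriched
  states that its separate clustering is a property of the design rather
  than of a lucky draw. Later generations multiply core weights by
  `enrichment_factor` (5) and renormalise; factor 1 therefore leaves all
  generations identical. The MT chamber down-weights non-filamentous
  genera by `mt_depletion` (0.02) in its baseline — the 0.2 µm membrane
  admits filamentous organisms and their hitch-hikers — and since later
  generations are inoculated from generation-1 biomass, the depletion
  persists across the chamber's series.
* **Decidability margin.** Ground-truth core membership must be
  decidable from count data: at 5,000 reads/sample the 0.2% threshold is
  10 expected reads, so a genus with true abundance near the threshold
  is a coin flip for *any* detector. The generator therefore pushes
  non-core abundances out of the (0.1%, 0.4%) band to the band edge on
  their own side of the threshold (qualification status never changes;
  the tiny residual mass moves to the sample's dominant genus). Disable
  with `decidable_margin = FALSE` when exact log-normal algebra is
  needed.
* **Reads.** Source genera are multinomial in the true composition;
  depths are jittered uniformly in [0.8, 1.2] × `depth_per_sample` so
  rarefying to the minimum is non-trivial; errors are iid substitutions
  at 0.5% on the insert (no indels, keeping identity expectations
  analytic — indels are exercised separately in the alignment tests);
  qualities are constant Q35 except a 10% fraction of reads with a Q12
  3′ tail, sized so truncation bites without dropping inserts below the
  length filter; primer IUPAC positions are resolved per read.

**What passing tests show — and don't.** The simulator emulates the
*structure* of enrichment-series data: compositional dynamics, realistic
depths, substitution noise, partially named references. It does not
emulate PCR chimeras, indel or homopolymer errors, abundance-dependent
error profiles, contamination, or the taxonomic richness of a real soil
community (tens of genera, not thousands). Recovery results on synthetic
data therefore validate the algorithms' correctness and their behaviour
under the designed conditions, not performance on real soil amplicon
data.

# Validation design and problem sizes

The test suite checks every operation against an independent oracle
where one exists: a plain-R dynamic program for alignment identity
(tolerance 0), exhaustive pair evaluation for seed assignment,
brute-force IUPAC matching for primers, vegan/ape/stats for Bray–Curtis,
PCoA, PERMANOVA and Ward heights (tolerance 1e−9), closed forms for
Chao1 and PCoA at n = 2–3, hypergeometric expectations for rarefaction,
and exhaustive label enumeration for the permutation test. PERMANOVA
type-I error is calibrated on 1,000 structureless simulations (two
groups of five, 999 permutations). The end-to-end check runs the full
design at 5,000 reads/sample and asserts designed-core sensitivity 1.0
with zero unsupported calls, strictly monotone core enrichment, and
generation-1 separation in the dendrogram. These sizes keep the whole
suite under a minute on one CPU while leaving each statistical check
with comfortable Monte-Carlo margins.

Two statistical facts shape the small-design expectations. With six
samples split 4-vs-2, the permutation space has 15 assignments, so no
permutation p-value can fall below 1/15 ≈ 0.067 — significance claims at
α = 0.05 are unattainable at that split, and effect sizes carry the
information. PERMANOVA power for the generation effect is therefore
demonstrated with three replicate count draws per generation within a
chamber (the physical design pools nine wells per chamber, so replicate
draws are faithful); with the bare six samples, the chamber contrast
dominates within-group scatter.

# Degenerate inputs and numerical conventions

Empty sequences are errors for identity; empty hit lists yield
all-unnamed lineages; empty seed sets leave every non-seed independent;
an all-zero sample cannot be total-sum scaled (error); rarefaction
refuses depths above any library size, naming the offending sample;
permutation p-values use the $(1+b)/(1+m)$ estimator; PCoA drops
eigenvalues below $\lambda_{\max} \times 10^{-12}$ as numerically zero;
all stochastic operations take explicit seeds and the pipeline dumps its
effective configuration (every threshold actually used) beside its
outputs.

# Known limitations

* Single-factor PERMANOVA only (no strata or interactions).
* Best-hit taxonomy (no consensus or bootstrap confidence).
* The chimera stage is a hook, not a detector.
* The permutation differential-abundance test is underpowered below ~10
  samples per comparison — by design it reports exact attainable
  granularity rather than pretending otherwise.
* Substitution-only error model in the simulator's default mode.
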
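rand_table <- function(nf = 6, ns = 6, lambda = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(nf * ns, lambda), nf, ns,
                   dimnames = list(sprintf("f%02d", 1:nf),
                                   sprintf("s%02d", 1:ns)))
  feature_table(counts)
}

test_that("low-count filter keeps features at the inclusive prevalence boundary", {
  counts <- matrix(0L, 3, 10,
                   dimnames = list(c("keep", "weak", "zero"),
                                   paste0("s", 1:10)))
  counts["keep", 1:2] <- 4L    # count 4 in exactly 20% of samples
  counts["weak", 1] <- 100L    # abundant but in only 10% of samples
  ft <- feature_table(counts)
  out <- filter_low_count(ft, min_count = 4, prevalence = 0.20)
  expect_equal(rownames(out$counts), "keep")
  expect_equal(attr(out, "n_removed"), 2L)
  empty <- feature_table(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(filter_low_count(empty)$counts), 0L)
})

test_that("IQR filter drops the lowest-variance tail deterministically", {
  set.seed(61)
  counts <- matrix(rpois(90, 30), 9, 10,
                   dimnames = list(sprintf("f%d", 1:9), paste0("s", 1:10)))
  counts <- rbind(counts, const = rep(5L, 10))
  ft <- feature_table(counts)
  out <- filter_low_variance(ft, quantile = 0.10)  # drops 1 of 10
  expect_false("const" %in% rownames(out$counts))
  expect_equal(attr(out, "n_removed"), 1L)
  # all-identical IQRs: floor(quantile * n) dropped by feature id order
  flat <- feature_table(matrix(3L, 10, 4,
                               dimnames = list(sprintf("g%02d", 1:10),
                                               paste0("s", 1:4))))
  out2 <- filter_low_variance(flat, quantile = 0.25)
  expect_equal(setdiff(rownames(flat$counts), rownames(out2$counts)),
               c("g01", "g02"))
  # quantile 0 leaves the table unchanged
  expect_equal(filter_low_variance(ft, 0)$counts, ft$counts)
})

test_that("rarefaction subsamples every library to the exact depth", {
  ft <- rand_table(8, 5, lambda = 40, seed = 62)
  depth <- min(colSums(ft$counts))
  rf <- rarefy(ft, seed = 1)
  expect_true(all(colSums(rf$counts) == depth))
  expect_true(all(rf$counts <= ft$counts))
  # a sample already at depth is unchanged
  two <- feature_table(matrix(c(3L, 2L, 1L, 4L), 2, 2,
                              dimnames = list(c("a", "b"), c("x", "y"))))
  rf2 <- rarefy(two, depth = 5, seed = 1)
  expect_equal(rf2$counts[, "x"], two$counts[, "x"])
  expect_error(rarefy(two, depth = 6), "x")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- matrix(c(50L, 30L, 20L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s"))
  ft <- feature_table(counts)
  depth <- 40L
  reps <- 200
  draws <- vapply(seq_len(reps), function(r)
    rarefy(ft, depth = depth, seed = r)$counts["a", 1], numeric(1))
  expect_true(all(vapply(seq_len(10), function(r)
    sum(rarefy(ft, depth = depth, seed = r)$counts), numeric(1)) == depth))
  p <- 50 / 100
  expectation <- depth * p
  v <- depth * p * (1 - p) * (100 - depth) / (100 - 1)
  se <- sqrt(v / reps)
  expect_lt(abs(mean(draws) - expectation), 3 * se)
})

test_that("total-sum scaling yields exact relative abundances", {
  counts <- matrix(c(1L, 3L, 2L, 2L), 2, 2,
                   dimnames = list(c("a", "b"), c("x", "y")))
  tss <- total_sum_scale(feature_table(counts))
  expect_equal(tss$counts[, "x"], c(a = 0.25, b = 0.75))
  expect_equal(unname(colSums(tss$counts)), c(1, 1))
  expect_true(tss$normalised)
  zero <- feature_table(matrix(c(1L, 0L), 1, 2,
                               dimnames = list("a", c("x", "y"))))
  expect_error(total_sum_scale(zero), "zero")
})

test_that("core microbiome thresholds are inclusive and monotone", {
  rel <- matrix(0.0001, 3, 10,
                dimnames = list(c("core", "rare", "mid"), paste0("s", 1:10)))
  rel["core", 1:2] <- 0.002      # exactly 0.2% in exactly 20% of samples
  rel["rare", ] <- 0.001         # 0.1% everywhere
  rel["mid", 1:5] <- 0.01
  rel <- sweep(rbind(rel, filler = 1 - colSums(rel)), 2, 1, "/")
  ft <- feature_table(rel, normalised = TRUE)
  core <- core_microbiome(ft)
  expect_true("core" %in% core)
  expect_false("rare" %in% core)
  strict <- core_microbiome(ft, prevalence = 0.5, min_rel_abund = 0.005)
  expect_true(all(strict %in% core))
})

test_that("Chao1 follows the bias-corrected closed form", {
  expect_equal(chao1(c(5L, 1L, 1L, 2L, 2L, 3L)), 6 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(5L, 4L, 3L)), 3)          # F1 = 0 => S_obs
  set.seed(63)
  for (k in 1:10) {
    x <- rpois(30, 2)
    expect_gte(chao1(x), sum(x > 0))
  }
  expect_error(chao1(c(-1L, 2L)), "non-negative")
})

test_that("Bray-Curtis matches hand values and vegan on random tables", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(m)["x", "y"], 1.0)
  m2 <- matrix(c(2, 2, 1, 3), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(m2)["x", "y"], 0.25)
  expect_equal(bray_curtis(cbind(m2[, 1], m2[, 1]))[1, 2], 0)
  for (k in 1:5) {
    ft <- rand_table(6, 6, seed = 70 + k)
    mine <- unclass(bray_curtis(ft))
    ref <- as.matrix(vegan::vegdist(t(ft$counts), method = "bray"))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("PCoA reproduces closed forms and embeds Euclidean data exactly", {
  # two samples at distance 0.5: one positive axis, coordinates +/- 0.25
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(sum(p2$eigenvalues > 1e-12), 1L)
  expect_equal(sort(as.numeric(p2$coordinates)), c(-0.25, 0.25))
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-12]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2])
  # Euclidean-embeddable distances reconstruct exactly
  set.seed(64)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  pc <- pcoa(d)
  rec <- as.matrix(dist(pc$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_equal(sum(pc$proportion_explained), 1)
})

test_that("PCoA agrees with an independent implementation on Bray-Curtis input", {
  for (k in 1:3) {
    ft <- rand_table(8, 6, seed = 80 + k)
    d <- bray_curtis(ft)
    mine <- pcoa(d)
    ref <- ape::pcoa(as.dist(unclass(d)))
    npos <- ncol(mine$coordinates)
    expect_equal(sort(mine$eigenvalues, decreasing = TRUE)[1:npos],
                 ref$values$Eigenvalues[1:npos], tolerance = 1e-9)
    for (ax in 1:2) {
      cors <- abs(cor(mine$coordinates[, ax], ref$vectors[, ax]))
      expect_equal(cors, 1, tolerance = 1e-6)
    }
  }
})

test_that("PERMANOVA pseudo-F and R2 match vegan::adonis2 exactly", {
  for (k in 1:5) {
    ft <- rand_table(7, 8, seed = 90 + k)
    d <- bray_curtis(ft)
    grp <- rep(c("A", "B"), each = 4)
    mine <- permanova(d, grp, n_permutations = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(unclass(d)) ~ g,
                          data = data.frame(g = grp), permutations = 99)
    expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
    expect_equal(mine$R2, ref$R2[1], tolerance = 1e-9)
  }
})

test_that("PERMANOVA on perfectly separated clusters gives R2 = 1 and minimal p", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  class(d) <- c("dist_matrix", "matrix")
  res <- permanova(d, c("a", "a", "b", "b"), n_permutations = 999, seed = 2)
  expect_equal(res$R2, 1)
  # only relabellings preserving the clusters can tie the observed F
  expect_lte(res$p_value, 0.4)
  expect_gt(res$p_value, 0)
})

test_that("PERMANOVA is invariant to sample order", {
  ft <- rand_table(6, 8, seed = 95)
  d <- bray_curtis(ft)
  grp <- rep(c("A", "B"), each = 4)
  f1 <- permanova(d, grp, n_permutations = 9, seed = 1)$pseudo_F
  perm <- sample(8)
  d2 <- unclass(d)[perm, perm]
  class(d2) <- c("dist_matrix", "matrix")
  f2 <- permanova(d2, grp[perm], n_permutations = 9, seed = 1)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("Ward clustering matches hclust ward.D2 heights and topology", {
  for (k in 1:4) {
    ft <- rand_table(6, 7, seed = 100 + k)
    d <- bray_curtis(ft)
    mine <- ward_dendrogram(d)
    ref <- hclust(as.dist(unclass(d)), method = "ward.D2")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
    expect_equal(as.matrix(cophenetic(mine))[colnames(d), colnames(d)],
                 as.matrix(cophenetic(ref))[colnames(d), colnames(d)],
                 tolerance = 1e-9)
  }
})

test_that("Ward clustering joins tight pairs first and writes valid newick", {
  base <- c(10, 0, 0, 10)
  counts <- matrix(as.integer(c(10, 0, 11, 1, 0, 10, 1, 11)), 2, 4,
                   dimnames = list(c("f1", "f2"),
                                   c("a1", "a2", "b1", "b2")))
  d <- bray_curtis(feature_table(counts))
  hc <- ward_dendrogram(d)
  # the first two merges pair (a1,a2) and (b1,b2)
  first_pairs <- lapply(1:2, function(i) sort(-hc$merge[i, ]))
  got <- lapply(first_pairs, function(p) sort(hc$labels[p]))
  expect_setequal(lapply(got, paste, collapse = ","),
                  list("a1,a2", "b1,b2"))
  expect_setequal(hc$labels, colnames(d))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, colnames(d))
  # two samples join at their distance
  d2 <- bray_curtis(feature_table(matrix(c(1L, 0L, 0L, 1L), 2, 2,
                                         dimnames = list(c("x", "y"),
                                                         c("p", "q")))))
  hc2 <- ward_dendrogram(d2)
  expect_equal(hc2$height, d2["p", "q"])
})

test_that("rarefaction curves are monotone and exact at the boundaries", {
  counts <- c(20L, 10L, 5L, 1L, 0L)
  total <- sum(counts)
  rc <- rarefaction_curve(counts, depths = c(1, 5, 10, 20, total),
                          reps = 30, seed = 1)
  expect_equal(rc$mean_richness[1], 1)
  expect_equal(rc$mean_richness[nrow(rc)], sum(counts > 0))
  expect_equal(rc$sd[nrow(rc)], 0)
  expect_true(all(diff(rc$mean_richness) >= 0))
})

test_that("differential abundance matches exhaustive label enumeration", {
  counts <- matrix(as.integer(c(10, 90, 10, 90, 10, 90,
                                0, 100, 0, 100, 0, 100)), 2, 6,
                   dimnames = list(c("hit", "filler"), paste0("s", 1:6)))
  ft <- feature_table(counts)
  res <- diff_abundance(ft, paste0("s", 1:3), paste0("s", 4:6))
  # independent enumeration of all 20 label assignments
  rel <- sweep(counts, 2, colSums(counts), "/")
  stat <- function(cols) {
    abs(log2((mean(rel["hit", cols]) + 1e-4) /
               (mean(rel["hit", -cols]) + 1e-4)))
  }
  all_stats <- apply(combn(6, 3), 2, stat)
  obs <- stat(1:3)
  expected_p <- mean(all_stats >= obs - 1e-12)
  expect_equal(res$p_value[res$feature_id == "hit"], expected_p)
  expect_equal(expected_p, 2 / 20)  # observed and complement labelling only
  # a feature with identical relative abundance everywhere: zero effect, p = 1
  flat <- feature_table(matrix(as.integer(c(30, 70)), 2, 6,
                               dimnames = list(c("same", "rest"),
                                               paste0("s", 1:6))))
  res2 <- diff_abundance(flat, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res2$log2fc[res2$feature_id == "same"], 0, tolerance = 1e-12)
  expect_equal(res2$p_value[res2$feature_id == "same"], 1)
})

test_that("differential-abundance raw p-values are calibrated under the null", {
  set.seed(65)
  rates <- numeric(0)
  for (tbl in 1:5) {
    counts <- matrix(rpois(60 * 10, 50), 60, 10,
                     dimnames = list(sprintf("f%02d", 1:60),
                                     paste0("s", 1:10)))
    ft <- feature_table(counts)
    res <- diff_abundance(ft, paste0("s", 1:5), paste0("s", 6:10),
                          exact = TRUE)
    rates <- c(rates, res$p_value < 0.05)
  }
  # permutation p-values are discrete and slightly conservative; the band
  # is 3 Monte-Carlo standard errors around the nominal 5%
  expect_gte(mean(rates), 0.05 - 3 * sqrt(0.05 * 0.95 / length(rates)))
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / length(rates)))
})

test_that("alpha-diversity comparison picks Welch t or ANOVA by group count", {
  same <- compare_alpha(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$method, "welch_t")
  expect_gt(same$p_value, 0.99)
  shift <- compare_alpha(c(1, 1.01, 0.99, 5, 5.01, 4.99),
                         rep(c("a", "b"), each = 3))
  expect_lt(shift$p_value, 0.01)
  three <- compare_alpha(rnorm(9), rep(c("a", "b", "c"), each = 3))
  expect_equal(three$method, "anova_f")
  expect_error(compare_alpha(1:3, rep("a", 3)), "two groups")
})

test_that("filtering order and totals add up on a shared table", {
  ft <- rand_table(20, 10, seed = 66)
  f1 <- filter_low_count(ft, min_count = 30, prevalence = 0.5)
  f2 <- filter_low_variance(f1, quantile = 0.2)
  expect_equal(nrow(ft$counts),
               nrow(f2$counts) + attr(f1, "n_removed") + attr(f2, "n_removed"))
  expect_lte(nrow(f2$counts), nrow(f1$counts))
})

test_that("PERMANOVA detects the designed generation effect with high power", {
  # three sequencing replicates per generation within one chamber (the
  # study design pools nine wells per chamber, so replicate draws from the
  # same true composition emulate within-treatment replication)
  cfg <- sim_config(n_genera = 24L, n_core = 3L, enrichment_factor = 5,
                    seed = 67L)
  set.seed(cfg$seed)
  hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    ref <- make_reference(cfg)
    comps <- simulate_compositions(cfg, ref)
    cells <- sprintf("DC_gen%d", rep(1:3, each = 3))
    counts <- vapply(cells, function(s)
      rmultinom(1, 2000, comps$compositions[, s])[, 1],
      numeric(nrow(comps$compositions)))
    colnames(counts) <- sprintf("%s_rep%d", cells, rep(1:3, times = 3))
    ft <- total_sum_scale(feature_table(round(counts)))
    d <- bray_curtis(ft)
    res <- permanova(d, rep(1:3, each = 3), n_permutations = 999, seed = r)
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gte(hits / reps, 0.9)
})
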
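test_that("dereplication groups exact duplicates with per-sample counts", {
  bases <- c(rep("ACGT", 5), rep("ACGT", 3), rep("ACGA", 2))
  samples <- c(rep("s1", 5), rep("s2", 3), rep("s1", 2))
  u <- dereplicate(bases, samples)
  expect_equal(length(u), 2L)
  expect_equal(u$bases[1], "ACGT")        # most abundant first
  expect_equal(u$abundance, c(8L, 2L))
  expect_equal(u$counts[1, ], c(s1 = 5L, s2 = 3L))
  # case-insensitive and U -> T at ingest
  u2 <- dereplicate(c("acgu", "ACGT"), c("s1", "s1"))
  expect_equal(length(u2), 1L)
  expect_equal(u2$abundance, 2L)
})

test_that("dereplication conserves read counts on random input", {
  set.seed(3)
  for (k in 1:5) {
    n <- sample(10:40, 1)
    bases <- sample(replicate(5, random_seq(8)), n, replace = TRUE)
    samples <- sample(c("s1", "s2", "s3"), n, replace = TRUE)
    u <- dereplicate(bases, samples)
    expect_equal(sum(u$abundance), n)
    expect_equal(sum(u$counts), n)
    expect_true(all(diff(u$abundance) <= 0))
  }
})

test_that("seed designation uses the inclusive abundance-10 boundary", {
  bases <- c(rep("AAAA", 10), rep("CCCC", 9), rep("GGGG", 12))
  u <- dereplicate(bases, rep("s1", 31))
  parts <- designate_seeds(u)
  expect_setequal(parts$seeds$bases, c("AAAA", "GGGG"))
  expect_equal(parts$non_seeds$bases, "CCCC")
  empty <- dereplicate(character(0), character(0))
  pe <- designate_seeds(empty)
  expect_equal(length(pe$seeds), 0L)
  expect_equal(length(pe$non_seeds), 0L)
})

test_that("alignment identity matches the worked examples and is symmetric", {
  expect_equal(seq_identity("ACGT", "ACGA"), 0.75)
  expect_equal(seq_identity("ACGT", "ACGGT"), 0.8)
  s <- random_seq(100)
  expect_equal(seq_identity(s, s), 1.0)
  a <- random_seq(50); b <- random_seq(47)
  expect_equal(seq_identity(a, b), seq_identity(b, a))
  expect_error(seq_identity("", "ACGT"), "empty")
})

test_that("non-seeds merge into their nearest seed at the 98% threshold", {
  set.seed(21)
  seed_a <- random_seq(200)
  seed_b <- mutate_seq(seed_a, 8)         # ~96% to seed_a
  ns <- mutate_seq(seed_a, 2)             # 99% to A, ~95-97% to B
  bases <- c(rep(seed_a, 20), rep(seed_b, 15), rep(ns, 3))
  u <- dereplicate(bases, rep("s1", 38))
  parts <- designate_seeds(u)
  res <- map_to_seeds(parts$non_seeds, parts$seeds)
  expect_equal(length(res$features), 2L)
  a_id <- u$seq_id[u$bases == seed_a]
  expect_equal(res$mapping$representative[res$mapping$seq_id ==
                                            u$seq_id[u$bases == ns]], a_id)
  expect_equal(res$features$abundance[res$features$seq_id == a_id], 23L)
})

test_that("a non-seed below threshold to every seed stays independent", {
  set.seed(22)
  seed_a <- random_seq(200)
  far <- mutate_seq(seed_a, 10)           # 95% < 98%
  bases <- c(rep(seed_a, 12), rep(far, 2))
  u <- dereplicate(bases, rep("s1", 14))
  parts <- designate_seeds(u)
  res <- map_to_seeds(parts$non_seeds, parts$seeds)
  expect_equal(length(res$features), 2L)
  expect_true("independent" %in% res$mapping$role)
  expect_equal(sum(res$features$abundance), 14L)
})

test_that("with no seeds every non-seed stays independent with counts unchanged", {
  set.seed(23)
  bases <- replicate(3, random_seq(60))
  u <- dereplicate(rep(bases, times = c(2, 3, 1)), rep("s1", 6))
  parts <- designate_seeds(u)   # none reach 10
  expect_equal(length(parts$seeds), 0L)
  res <- map_to_seeds(parts$non_seeds, parts$seeds)
  expect_equal(length(res$features), 3L)
  expect_equal(sum(res$features$abundance), 6L)
  expect_true(all(res$mapping$role == "independent"))
})

test_that("exact identity ties resolve to the higher-abundance, then smaller-id seed", {
  # two seeds equidistant from the non-seed
  tmpl <- paste(rep("ACGT", 20), collapse = "")
  s1 <- sub("^A", "C", tmpl)    # differ at pos 1
  s2 <- sub("T$", "G", tmpl)    # differ at last pos
  bases <- c(rep(s1, 11), rep(s2, 12), rep(tmpl, 3))
  u <- dereplicate(bases, rep("x", 26))
  parts <- designate_seeds(u)
  res <- map_to_seeds(parts$non_seeds, parts$seeds, threshold = 0.98)
  tid <- u$seq_id[u$bases == tmpl]
  winner <- res$mapping$representative[res$mapping$seq_id == tid]
  expect_equal(winner, u$seq_id[u$bases == s2])  # abundance 12 beats 11
  # equal abundance: lexicographically smaller seq_id wins
  bases2 <- c(rep(s1, 11), rep(s2, 11), rep(tmpl, 3))
  ids2 <- c(rep("a_reads", 11), rep("b_reads", 11), rep("t_reads", 3))
  ids2 <- paste0(ids2, ave(seq_along(ids2), ids2, FUN = seq_along))
  u2 <- dereplicate(bases2, rep("x", 25), read_id = ids2)
  p2 <- designate_seeds(u2)
  r2 <- map_to_seeds(p2$non_seeds, p2$seeds, threshold = 0.98)
  tid2 <- u2$seq_id[u2$bases == tmpl]
  expect_equal(r2$mapping$representative[r2$mapping$seq_id == tid2],
               "a_reads1")
})

test_that("greedy binning equals the exhaustive oracle on small random instances", {
  set.seed(101)
  for (k in 1:30) {
    n_templates <- sample(2:4, 1)
    templates <- replicate(n_templates, random_seq(sample(30:60, 1)))
    reads <- character(0)
    for (t in templates) {
      n_exact <- sample(c(3, 12, 15), 1)
      reads <- c(reads, rep(t, n_exact),
                 replicate(sample(0:3, 1), mutate_seq(t, sample(1:3, 1))))
    }
    samples <- sample(c("s1", "s2"), length(reads), replace = TRUE)
    u <- dereplicate(reads, samples)
    parts <- designate_seeds(u)
    res <- map_to_seeds(parts$non_seeds, parts$seeds)
    expected <- oracle_assign(parts$non_seeds, parts$seeds)
    got <- res$mapping$representative[match(parts$non_seeds$seq_id,
                                            res$mapping$seq_id)]
    expect_equal(got, expected)
    expect_equal(sum(res$features$abundance), length(reads))
  }
})

test_that("seeds are fixed points of the seed mapping", {
  set.seed(31)
  bases <- rep(replicate(3, random_seq(50)), times = c(12, 15, 10))
  u <- dereplicate(bases, rep("s1", length(bases)))
  parts <- designate_seeds(u)
  expect_equal(length(parts$non_seeds), 0L)
  res <- map_to_seeds(parts$non_seeds, parts$seeds)
  expect_equal(res$features$bases, parts$seeds$bases)
  expect_equal(res$features$counts, parts$seeds$counts)
})

test_that("raising thresholds is monotone in seeds and independent features", {
  set.seed(32)
  tmpl <- replicate(3, random_seq(80))
  reads <- unlist(lapply(tmpl, function(t)
    c(rep(t, sample(8:14, 1)),
      replicate(4, mutate_seq(t, sample(1:4, 1))))))
  u <- dereplicate(reads, rep("s1", length(reads)))
  n_seeds <- vapply(c(1, 5, 10, 20), function(m)
    length(designate_seeds(u, m)$seeds), numeric(1))
  expect_true(all(diff(n_seeds) <= 0))
  parts <- designate_seeds(u)
  n_indep <- vapply(c(0.90, 0.95, 0.98, 0.995), function(th) {
    r <- map_to_seeds(parts$non_seeds, parts$seeds, threshold = th)
    sum(r$mapping$role == "independent")
  }, numeric(1))
  expect_true(all(diff(n_indep) >= 0))
})

test_that("screened identity equals the unscreened matrix at the threshold", {
  set.seed(33)
  qs <- replicate(6, random_seq(120))
  ts <- c(qs[1], mutate_seq(qs[1], 2), replicate(3, random_seq(120)))
  full <- identity_matrix(qs, ts)
  scr <- identity_matrix(qs, ts, threshold = 0.98)
  idx <- !is.na(scr)
  expect_equal(scr[idx], full[idx])
  # everything screened out is genuinely below the threshold
  expect_true(all(full[is.na(scr)] < 0.98))
})

test_that("templates with enough error-free copies are recovered and reads bin correctly", {
  set.seed(34)
  n_genera <- 5
  templates <- replicate(n_genera, random_seq(350))
  # enforce >= 5% divergence between templates
  idm <- identity_matrix(templates, templates)
  diag(idm) <- 0
  expect_true(all(idm < 0.95))
  reads <- character(0); truth <- integer(0)
  for (g in seq_len(n_genera)) {
    n <- 150
    nerr <- rbinom(n, 350, 0.005)
    reads <- c(reads, vapply(nerr, function(k)
      if (k == 0) templates[g] else mutate_seq(templates[g], k),
      character(1)))
    truth <- c(truth, rep(g, n))
  }
  u <- dereplicate(reads, rep("s1", length(reads)),
                   read_id = paste0("rd", seq_along(reads)))
  parts <- designate_seeds(u)
  res <- map_to_seeds(parts$non_seeds, parts$seeds)
  expect_true(all(templates %in% res$features$bases))
  # fraction of reads whose feature representative is their true template
  rep_of <- res$mapping$representative[match(u$seq_id, res$mapping$seq_id)]
  rep_bases <- res$features$bases[match(rep_of, res$features$seq_id)]
  tmpl_of_unique <- templates[truth[match(u$bases, reads)]]
  correct <- sum(u$abundance[rep_bases == tmpl_of_unique])
  expect_gte(correct / length(reads), 0.95)
})
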
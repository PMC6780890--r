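# Feature-table statistics: filtering, rarefaction, scaling, core
# microbiome, alpha/beta diversity, ordination, PERMANOVA, Ward clustering
# and permutation-based differential abundance.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Low-count (prevalence) filter
#'
#' Keeps features having at least `min_count` counts in at least a
#' `prevalence` fraction of samples (both thresholds inclusive).
#'
#' @param table a count [feature_table()].
#' @param min_count minimum per-sample count (default 4).
#' @param prevalence minimum fraction of samples (default 0.20).
#' @return Filtered table; the number of removed features is recorded in
#'   `attr(, "n_removed")`.
#' @export
filter_low_count <- function(table, min_count = 4, prevalence = 0.20) {
  stopifnot(inherits(table, "feature_table"), !table$normalised)
  if (ncol(table$counts) == 0L || nrow(table$counts) == 0L) {
    out <- table; attr(out, "n_removed") <- 0L; return(out)
  }
  frac <- rowMeans(table$counts >= min_count)
  keep <- frac >= prevalence
  out <- ft_replace_counts(table, table$counts[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Low-variance (IQR) filter
#'
#' Ranks features by inter-quartile range across samples and drops the
#' lowest `floor(quantile * n)` of them; exact IQR ties are broken by
#' feature id so the result is deterministic.
#'
#' @param table a [feature_table()].
#' @param quantile fraction of features to drop (default 0.10).
#' @return Filtered table with `attr(, "n_removed")`.
#' @export
filter_low_variance <- function(table, quantile = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$counts)
  k <- floor(quantile * n)
  if (k <= 0L) { out <- table; attr(out, "n_removed") <- 0L; return(out) }
  iqr <- apply(table$counts, 1, stats::IQR)
  drop <- order(iqr, rownames(table$counts), method = "radix")[seq_len(k)]
  out <- ft_replace_counts(table, table$counts[-drop, , drop = FALSE])
  attr(out, "n_removed") <- k
  out
}

#' Rarefy to a common depth
#'
#' Per-sample subsampling without replacement to exactly `depth` reads
#' (default: the minimum library size).
#'
#' @param table a count [feature_table()].
#' @param depth target depth; must not exceed any library size.
#' @param seed optional RNG seed for reproducibility.
#' @return Rarefied count table.
#' @export
rarefy <- function(table, depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "feature_table"), !table$normalised)
  sizes <- colSums(table$counts)
  if (is.null(depth)) depth <- min(sizes)
  depth <- as.integer(depth)
  small <- which(sizes < depth)
  if (length(small))
    stop(sprintf("sample '%s' has %d reads, fewer than depth %d",
                 colnames(table$counts)[small[1]], sizes[small[1]], depth))
  with_seed(seed, {
    out <- table$counts
    for (j in seq_len(ncol(out))) {
      if (sizes[j] == depth) next
      pool <- rep.int(seq_len(nrow(out)), out[, j])
      keep <- sample(pool, depth, replace = FALSE)
      out[, j] <- tabulate(keep, nbins = nrow(out))
    }
    ft_replace_counts(table, out)
  })
}

#' Total-sum scaling
#'
#' Divides each sample column by its library size, producing relative
#' abundances; the result carries the `normalised` flag.
#'
#' @param table a count [feature_table()].
#' @return Normalised table.
#' @export
total_sum_scale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalised) stop("table is already normalised")
  sizes <- colSums(table$counts)
  if (any(sizes == 0)) stop("cannot scale a sample with zero total count")
  ft_replace_counts(table, sweep(table$counts, 2, sizes, "/"),
                    normalised = TRUE)
}

#' Core-microbiome detection
#'
#' Features whose relative abundance reaches `min_rel_abund` in at least a
#' `prevalence` fraction of samples (both thresholds inclusive).  Count
#' tables are total-sum scaled internally.
#'
#' @param table a [feature_table()] (counts or normalised).
#' @param prevalence minimum sample fraction (default 0.20).
#' @param min_rel_abund minimum relative abundance (default 0.002, i.e.
#'   0.2%).
#' @return Character vector of core feature ids.
#' @export
core_microbiome <- function(table, prevalence = 0.20, min_rel_abund = 0.002) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalised) table <- total_sum_scale(table)
  frac <- rowMeans(table$counts >= min_rel_abund)
  rownames(table$counts)[frac >= prevalence]
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and
#' `F2` are the numbers of singleton and doubleton features.
#'
#' @param counts integer count vector for one sample.
#' @return Chao1 estimate (`>= S_obs` always).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("chao1 needs non-negative integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features.
#'
#' @param table a [feature_table()] (counts or relative abundances), or a
#'   plain features x samples matrix.
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    num <- sum(abs(m[, i] - m[, j]))
    den <- sum(m[, i] + m[, j])
    out[i, j] <- out[j, i] <- if (den > 0) num / den else 0
  }
  class(out) <- c("dist_matrix", "matrix")
  out
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Axes are sorted by eigenvalue; negative eigenvalues are reported but
#' their axes are omitted from the coordinates and from the proportion of
#' variance explained.
#'
#' @param dist a `dist_matrix` (or any symmetric matrix of distances).
#' @return List with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, sorted descending) and `proportion_explained`
#'   (over positive eigenvalues only).
#' @export
pcoa <- function(dist) {
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  a <- -0.5 * d^2
  rmeans <- rowMeans(a); cmeans <- colMeans(a); tmean <- mean(a)
  g <- a - outer(rmeans, rep(1, n)) - outer(rep(1, n), cmeans) + tmean
  eig <- eigen(g, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals) * 1e-12 & vals > 0)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = vals,
       proportion_explained = vals[pos] / sum(vals[pos]))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance.  Total and
#' within-group sums of squares come from squared inter-point distances
#' (`SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2`); `pseudo-F = (SS_between / (g - 1)) /
#' (SS_within / (n - g))` and the p-value is `(1 + #{F_perm >= F_obs}) /
#' (1 + n_permutations)` under random relabelling.
#'
#' @param dist a `dist_matrix`.
#' @param groups factor (or vector) of group labels, one per sample.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional RNG seed.
#' @return A `permanova_result` with `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  g <- nlevels(groups)
  if (g < 2) stop("need at least two groups")
  if (g == n) stop("every group has a single member; no residual df")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  f_stat <- function(lab) {
    ssw <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      if (length(idx) > 1)
        ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ssb <- ss_total - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(groups)
  ssw_obs <- local({
    ssw <- 0
    for (lev in levels(groups)) {
      idx <- which(groups == lev)
      if (length(idx) > 1)
        ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ssw
  })
  r2 <- (ss_total - ssw_obs) / ss_total

  exceed <- with_seed(seed, {
    # vectorised over permutations: for membership indicator Z (perm x n)
    # per group, sum_{i<j in g} d2 = (z' D2 z) / 2
    cnt <- 0L
    block <- 250L
    done <- 0L
    while (done < n_permutations) {
      b <- min(block, n_permutations - done)
      fs <- numeric(b)
      ssw <- numeric(b)
      perm_lab <- replicate(b, sample(as.integer(groups)))
      for (lev in seq_len(g)) {
        z <- (perm_lab == lev) * 1  # n x b
        ng <- colSums(z)
        quad <- colSums(z * (d2 %*% z)) / 2
        ssw <- ssw + ifelse(ng > 1, quad / ng, 0)
      }
      fs <- ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
      cnt <- cnt + sum(fs >= f_obs - 1e-12)
      done <- done + b
    }
    cnt
  })
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, R2 = r2, p_value = p,
                 n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Ward hierarchical clustering
#'
#' Agglomerative Ward linkage via the Lance-Williams update on squared
#' distances (heights are on the original distance scale, matching
#' `hclust(..., "ward.D2")`).  Ties are broken deterministically by the
#' smallest involved cluster id.
#'
#' @param dist a `dist_matrix`.
#' @return An `hclust` object (usable with [write_newick()]).
#' @export
ward_dendrogram <- function(dist) {
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  if (n < 2) stop("need at least two samples to cluster")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  d2 <- d^2
  active <- seq_len(n)
  size <- rep(1L, n)
  # cluster id: negative = singleton (original sample), positive = merge row
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cur <- d2
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      v <- cur[i, j]
      if (v < best[1] - 1e-12) best <- c(v, i, j)
    }
    i <- best[2]; j <- best[3]
    height[step] <- sqrt(best[1])
    a <- id[i]; b <- id[j]
    merge[step, ] <- sort(c(a, b))
    ni <- size[i]; nj <- size[j]
    # Lance-Williams (Ward, on squared distances)
    newrow <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- size[k]
      newrow[k] <- ((ni + nk) * cur[i, k] + (nj + nk) * cur[j, k] -
                      nk * cur[i, j]) / (ni + nj + nk)
    }
    cur[i, ] <- newrow; cur[, i] <- newrow; cur[i, i] <- 0
    size[i] <- ni + nj
    id[i] <- step
    keep <- setdiff(seq_len(m), j)
    cur <- cur[keep, keep, drop = FALSE]
    size <- size[keep]; id <- id[keep]; active <- active[keep]
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge),
             labels = labels, method = "ward.D2",
             call = match.call(), dist.method = "bray-curtis")
  class(hc) <- "hclust"
  hc
}

# leaf ordering compatible with the merge matrix (left-to-right traversal)
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Rarefaction curve for one sample
#'
#' Mean and standard deviation of the observed richness over repeated
#' subsampling without replacement at each depth.
#'
#' @param counts integer count vector for one sample.
#' @param depths depths to evaluate (each `<=` the library size).
#' @param reps subsamples per depth (default 10).
#' @param seed optional RNG seed.
#' @return data.frame with `depth`, `mean_richness`, `sd`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (any(depths > total))
    stop("depth exceeds the library size")
  pool <- rep.int(seq_along(counts), counts)
  with_seed(seed, {
    res <- lapply(depths, function(dp) {
      if (dp == total) {
        rich <- rep(sum(counts > 0), 1L)  # single possible outcome
        return(data.frame(depth = dp, mean_richness = rich, sd = 0))
      }
      rich <- vapply(seq_len(reps), function(r) {
        sub <- sample(pool, dp, replace = FALSE)
        length(unique(sub))
      }, numeric(1))
      data.frame(depth = dp, mean_richness = mean(rich),
                 sd = if (length(rich) > 1) sd(rich) else 0)
    })
    do.call(rbind, res)
  })
}

#' Permutation test for differential abundance between two groups
#'
#' Per feature, the effect is the log2 ratio of mean relative abundances
#' (after total-sum scaling, with a pseudocount); significance comes from
#' permuting sample labels with `|effect|` as the statistic, and p-values
#' are Benjamini-Hochberg adjusted.  When the label-combination space is
#' small the test enumerates it exhaustively, making the minimum
#' attainable p-value exact.
#'
#' @param table a count [feature_table()].
#' @param group_a,group_b sample ids of the two groups.
#' @param n_permutations random permutations when not exhaustive
#'   (default 999).
#' @param seed optional RNG seed.
#' @param pseudocount added to mean relative abundances before the log
#'   ratio (default 1e-4).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates when there are at most 10,000 combinations.
#' @return data.frame with `feature_id`, `log2fc` (A over B), `p_value`,
#'   `p_adjusted` and `significant` (adjusted p < 0.05).
#' @export
diff_abundance <- function(table, group_a, group_b, n_permutations = 999,
                           seed = NULL, pseudocount = 1e-4, exact = NULL) {
  stopifnot(inherits(table, "feature_table"))
  samp <- colnames(table$counts)
  if (!all(c(group_a, group_b) %in% samp))
    stop("unknown sample ids in group definitions")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  tss <- if (table$normalised) table else total_sum_scale(table)
  m <- tss$counts[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a); nb <- length(group_b); n <- na + nb

  eff <- function(cols_a) {
    ma <- rowMeans(m[, cols_a, drop = FALSE])
    mb <- rowMeans(m[, -cols_a, drop = FALSE])
    log2((ma + pseudocount) / (mb + pseudocount))
  }
  obs <- eff(seq_len(na))

  n_comb <- choose(n, na)
  use_exact <- if (is.null(exact)) n_comb <= 10000 else exact
  if (use_exact) {
    combs <- utils::combn(n, na)
    stats <- matrix(0, nrow(m), ncol(combs))
    for (k in seq_len(ncol(combs))) stats[, k] <- abs(eff(combs[, k]))
    # observed labelling is one of the enumerated ones
    p <- rowMeans(stats >= abs(obs) - 1e-12)
    n_used <- ncol(combs)
  } else {
    exceed <- rep(1L, nrow(m))  # include the observed labelling
    with_seed(seed, {
      for (k in seq_len(n_permutations)) {
        perm <- sample(n, na)
        exceed <- exceed + (abs(eff(perm)) >= abs(obs) - 1e-12)
      }
    })
    p <- exceed / (1 + n_permutations)
    n_used <- n_permutations
  }
  padj <- p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(m), log2fc = unname(obs),
             p_value = unname(p), p_adjusted = unname(padj),
             significant = unname(padj < 0.05),
             stringsAsFactors = FALSE)
}

#' Compare alpha diversity between groups
#'
#' Two groups: Welch t-test; more than two: one-way ANOVA.  Values are
#' passed through unchanged.
#'
#' @param values numeric vector (e.g. per-sample [chao1()] estimates).
#' @param groups group labels, one per value.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
compare_alpha <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("one group label per value required")
  if (nlevels(groups) < 2)
    stop("need at least two groups to compare")
  if (nlevels(groups) == 2) {
    tt <- t.test(values ~ groups)
    list(method = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value)
  } else {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    list(method = "anova_f", statistic = s[["F value"]][1],
         p_value = s[["Pr(>F)"]][1])
  }
}
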
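# Independent reference implementations used to check the package's
# computations.  They share no code with the implementation: the identity
# oracle is a plain-R dynamic program, the binning oracle evaluates every
# (non-seed, seed) pair with it, and the IUPAC oracle matches by explicit
# base-set expansion at every position.

# Global-alignment identity: match +1 / mismatch -1 / gap -2, maximising
# (score, matches) lexicographically; identity = matches / columns.
# The pair (score, matches) is packed into one number V = score * 1024 +
# matches: matches is bounded by min(la, lb) < 1024, so maximising V is
# exactly the lexicographic maximisation and the DP becomes additive in V
# (diagonal step adds 1024 + 1 on a match and -1024 on a mismatch, gap
# steps add -2048).
oracle_identity <- function(a, b) {
  A <- utf8ToInt(toupper(a)); B <- utf8ToInt(toupper(b))
  la <- length(A); lb <- length(B)
  stopifnot(la > 0, lb > 0, min(la, lb) < 1024)
  ENC <- 1024
  prev <- -2 * ENC * (0:lb)
  for (i in seq_len(la)) {
    mt <- as.integer(A[i] == B)
    cand <- pmax(prev[1:lb] - ENC + mt * (2 * ENC + 1),
                 prev[2:(lb + 1)] - 2 * ENC)
    cur <- numeric(lb + 1)
    cur[1] <- -2 * ENC * i
    for (j in seq_len(lb)) cur[j + 1] <- max(cand[j], cur[j] - 2 * ENC)
    prev <- cur
  }
  v <- prev[lb + 1]
  m <- v %% ENC
  sc <- (v - m) / ENC
  pairs <- (sc - 2 * m + 2 * (la + lb)) / 3
  m / (la + lb - pairs)
}

# Exhaustive nearest-seed assignment: every pair evaluated with the oracle
# identity; ties by higher seed abundance, then lexicographic seed id.
oracle_assign <- function(non_seeds, seeds, threshold = 0.98) {
  vapply(seq_along(non_seeds$seq_id), function(i) {
    if (length(seeds$seq_id) == 0L) return(non_seeds$seq_id[i])
    ids <- vapply(seeds$bases, function(s)
      oracle_identity(non_seeds$bases[i], s), numeric(1))
    elig <- which(ids >= threshold)
    if (length(elig) == 0L) return(non_seeds$seq_id[i])
    best <- elig[order(-ids[elig], -seeds$abundance[elig],
                       seeds$seq_id[elig], method = "radix")[1]]
    seeds$seq_id[best]
  }, character(1))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Brute-force IUPAC primer matcher: mismatch count of `primer` against the
# window of `read` starting at `pos` (1-based), by base-set membership.
oracle_iupac_mismatches <- function(read, primer, pos) {
  rch <- strsplit(toupper(read), "")[[1]]
  pch <- strsplit(toupper(primer), "")[[1]]
  win <- rch[seq.int(pos, pos + length(pch) - 1L)]
  sum(!mapply(function(r, p) r %in% IUPAC_SETS[[p]], win, pch))
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# introduce exactly k substitutions into a sequence
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a quick seq_set with uniform quality
qseq_set <- function(bases, q = 35L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(bases))
  seq_set(ids, bases, lapply(nchar(bases), function(L) rep(q, L)))
}
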
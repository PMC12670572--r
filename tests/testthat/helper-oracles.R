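# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (enumeration / plain DP written separately from the
# package implementation) and must stay independent of the code paths
# they check.

.oracle_pair_energy <- function(x, y, allow_gu = TRUE) {
  p <- paste0(sort(c(x, y)), collapse = "")
  if (p == "CG") return(-3L)
  if (p == "AU") return(-2L)
  if (allow_gu && p == "GU") return(-1L)
  0L
}

# Exhaustive enumeration over all pseudoknot-free structures of a short
# sequence: returns c(max_pairs, min_energy among maximizers).
brute_fold <- function(seq, min_hairpin = 3L, allow_gu = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  rec <- function(pos) {
    if (length(pos) < min_hairpin + 2L) return(c(0L, 0L))
    p <- pos[1]
    best <- rec(pos[-1])                       # p unpaired
    for (qi in seq_along(pos)) {
      q <- pos[qi]
      if (q - p < min_hairpin + 1L) next
      e <- .oracle_pair_energy(chars[p], chars[q], allow_gu)
      if (e == 0L) next
      inside <- pos[pos > p & pos < q]
      outside <- pos[pos > q]
      a <- rec(inside)
      b <- rec(outside)
      cand <- c(a[1] + b[1] + 1L, a[2] + b[2] + e)
      if (cand[1] > best[1] || (cand[1] == best[1] && cand[2] < best[2]))
        best <- cand
    }
    best
  }
  rec(seq_along(chars))
}

# Plain max-pair recursion with memoization (no energy tie-break): an
# independent check of the pair count for longer sequences.
memo_max_pairs <- function(seq, min_hairpin = 3L, allow_gu = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_hairpin - 1L)) {
      if (.oracle_pair_energy(chars[k], chars[j], allow_gu) == 0L) next
      cand <- 1L + rec(k + 1L, j - 1L) + if (k > i) rec(i, k - 1L) else 0L
      if (cand > best) best <- cand
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Brute-force maximal antiparallel Watson-Crick block over all substring
# pairs: returns c(max_len, max_gc among maximal blocks).
brute_block <- function(rh, lh) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  a <- strsplit(rh, "")[[1]]
  b <- strsplit(lh, "")[[1]]
  best_len <- 0L
  best_gc <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    L <- 0L
    while (i + L <= length(a) && j - L >= 1L &&
           comp[a[i + L]] == b[j - L]) L <- L + 1L
    if (L > 0L) {
      sub <- a[i:(i + L - 1L)]
      gc <- sum(sub %in% c("G", "C"))
      if (L > best_len || (L == best_len && gc > best_gc)) {
        best_len <- L
        best_gc <- gc
      }
    }
  }
  c(best_len, best_gc)
}

# Independent affine-gap Smith-Waterman (Gotoh) in plain R; gap of
# length L costs open + L * extend, matching the package convention.
sw_oracle <- function(q, s, mat, open = 11, extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa)
  n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - extend,
                           E[i + 1, j] - extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open - extend,
                           F[i, j + 1] - extend)
    d <- H[i, j] + mat[qa[i], sa[j]]
    H[i + 1, j + 1] <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Does the directed graph admit a closed walk of exactly length n?
# Explicit enumeration (only used on small graphs / small n).
walk_oracle <- function(adj, n) {
  k <- nrow(adj)
  rec <- function(start, cur, left) {
    if (left == 0L) return(cur == start)
    for (nxt in seq_len(k)) {
      if (adj[cur, nxt] && rec(start, nxt, left - 1L)) return(TRUE)
    }
    FALSE
  }
  any(vapply(seq_len(k), function(v) rec(v, v, n), logical(1)))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_protein_fixed <- function(len, seed) {
  withr::with_seed(seed, random_protein(len))
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})
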
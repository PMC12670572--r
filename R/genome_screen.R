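#' Screen configuration
#'
#' Thresholds for the structure-based genome screen.  The score
#' threshold plays the role of the homology-search significance filter
#' (a deterministic fold-score cutoff, optionally complemented by an
#' empirical shuffle null via [window_score_percentile()]); coverage is
#' matched-window length over template length, mirroring the
#' "coverage > 0.8" selection criterion; internal loops/bulges wider
#' than `max_bulge_span` disqualify a window, mirroring the folding
#' constraint of at most 30 nt interior/bulge loops.
#'
#' @param window_len scan window length in nt (default 120, the scale of
#'   pRNA domain 1).
#' @param step window step in nt (default 10).
#' @param min_coverage minimal matched-window/template fraction
#'   (default 0.8).
#' @param min_block_len minimal LH/RH block length (default 3).
#' @param score_threshold maximal (most positive) admissible fold score
#'   (default -20).
#' @param max_bulge_span maximal internal-loop/bulge span (default 30).
#' @param min_hairpin,allow_gu folding parameters.
#' @param min_loop,max_loop eligible loop length bounds.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(window_len = 120L, step = 10L, min_coverage = 0.8,
                          min_block_len = 3L, score_threshold = -20,
                          max_bulge_span = 30L, min_hairpin = 3L,
                          allow_gu = TRUE, min_loop = 3L, max_loop = 12L) {
  stopifnot(window_len > 0L, step >= 1L,
            min_coverage > 0, min_coverage <= 1)
  structure(list(window_len = as.integer(window_len),
                 step = as.integer(step), min_coverage = min_coverage,
                 min_block_len = as.integer(min_block_len),
                 score_threshold = score_threshold,
                 max_bulge_span = as.integer(max_bulge_span),
                 min_hairpin = as.integer(min_hairpin),
                 allow_gu = allow_gu, min_loop = as.integer(min_loop),
                 max_loop = as.integer(max_loop)),
            class = "screen_config")
}

# Evaluate one window sequence against all structural criteria; NULL if
# any criterion fails, else the candidate ingredients.
.evaluate_window <- function(wseq, cfg) {
  s <- fold_max_pairing(wseq, cfg$min_hairpin, cfg$allow_gu)
  sc <- score_structure(s)
  if (sc$pair_energy_total > cfg$score_threshold) return(NULL)
  rep <- parse_junctions(s)
  if (!rep$has_3wj) return(NULL)
  if (nrow(rep$internal) && any(rep$internal$max_span > cfg$max_bulge_span))
    return(NULL)
  pairs <- eligible_loop_pairs(s, rep, cfg$min_loop, cfg$max_loop)
  best <- NULL
  for (k in seq_len(nrow(pairs))) {
    blk <- max_complementary_block(pairs$rh_seq[k], pairs$lh_seq[k])
    if (blk$length < cfg$min_block_len) next
    if (!predict_activity(blk)$active) next
    if (is.null(best) || blk$length > best$length ||
        (blk$length == best$length && blk$n_gc > best$n_gc)) best <- blk
  }
  if (is.null(best)) return(NULL)
  list(structure = s, score = sc, junctions = rep, block = best)
}

#' Scan a genome for pRNA-like structured windows
#'
#' Slides fixed-length windows over both strands of a genome and keeps
#' windows that satisfy every structural criterion: fold score at or
#' below the threshold, a three-way junction, no oversized internal
#' loop/bulge, and an active complementary LH/RH loop pair.  The screen
#' is structure-driven: no primary-sequence template is consulted.
#'
#' @param genome a [seq_record()] (T is treated as U).
#' @param template_len template length used as the coverage denominator
#'   (defaults to `cfg$window_len`).
#' @param cfg a [screen_config()].
#' @return list of `prna_candidate` objects, each with `genome_id`,
#'   0-based half-open `start`/`end`, `strand`, `structure`, `has_3wj`,
#'   `loop_pair`, `pattern`, `fold_score`, `coverage`.  Genomes shorter
#'   than the window yield an empty list with a warning.
#' @export
scan_genome <- function(genome, template_len = NULL, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  gid <- if (inherits(genome, "seq_record")) genome$id else "genome"
  gseq <- .residues(genome, "rna")
  n <- nchar(gseq)
  w <- cfg$window_len
  if (is.null(template_len)) template_len <- w
  if (n < w) {
    warning("genome shorter than window; no candidates")
    return(list())
  }
  starts0 <- seq.int(0L, n - w, by = cfg$step)
  if (starts0[length(starts0)] != n - w) starts0 <- c(starts0, n - w)
  coverage <- min(1, w / template_len)
  out <- list()
  if (coverage < cfg$min_coverage) return(out)
  grc <- rna_revcomp(gseq)  # revcomp once; minus windows are its slices
  for (st in starts0) {
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") substr(gseq, st + 1L, st + w)
      else substr(grc, n - st - w + 1L, n - st)
      hit <- .evaluate_window(sseq, cfg)
      if (is.null(hit)) next
      out[[length(out) + 1L]] <- structure(list(
        genome_id = gid, start = st, end = st + w, strand = strand,
        structure = hit$structure, has_3wj = TRUE,
        loop_pair = hit$block, pattern = classify_pattern(hit$block),
        fold_score = hit$score$pair_energy_total,
        coverage = coverage), class = "prna_candidate")
    }
  }
  out
}

#' @export
print.prna_candidate <- function(x, ...) {
  cat(sprintf("<prna_candidate> %s:[%d,%d)%s score %d coverage %.2f block %s:%s\n",
              x$genome_id, x$start, x$end, x$strand, x$fold_score,
              x$coverage, x$loop_pair$rh_sub, x$loop_pair$lh_sub))
  invisible(x)
}

#' Merge overlapping candidates
#'
#' Clusters candidates whose intervals overlap with Jaccard index at
#' least `min_overlap` (transitively) and keeps the best-scoring
#' (lowest fold score; ties to the leftmost start) candidate of each
#' cluster, sorted by start.
#'
#' @param cands list of candidates from one genome ([scan_genome()]).
#' @param min_overlap Jaccard threshold (default 0.25).
#' @return filtered, sorted list of candidates.
#' @export
merge_candidates <- function(cands, min_overlap = 0.25) {
  k <- length(cands)
  if (k <= 1L) return(cands)
  if (length(unique(vapply(cands, function(x) x$genome_id,
                           character(1)))) != 1L)
    stop("merge_candidates expects candidates from one genome")
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- cands[[i]]; b <- cands[[j]]
    inter <- max(0L, min(a$end, b$end) - max(a$start, b$start))
    uni <- max(a$end, b$end) - min(a$start, b$start)
    if (uni > 0 && inter / uni >= min_overlap)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  kept <- lapply(split(seq_len(k), roots), function(idx) {
    sub <- cands[idx]
    scores <- vapply(sub, function(x) x$fold_score, numeric(1))
    starts <- vapply(sub, function(x) x$start, numeric(1))
    sub[[order(scores, starts)[1]]]
  })
  kept[order(vapply(kept, function(x) x$start, numeric(1)))]
}

#' Tabulate screen candidates
#'
#' One row per candidate with BED6-compatible leading coordinate columns
#' (`genome_id`, `start`, `end` 0-based half-open, `strand`).
#'
#' @param cands list of candidates.
#' @return data.frame with columns `genome_id,start,end,strand,
#'   fold_score,coverage,block_len,block_rh,block_lh,gg_cc_core,
#'   n_au_additions`.
#' @export
screen_report <- function(cands) {
  if (!length(cands)) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      fold_score = numeric(0), coverage = numeric(0),
                      block_len = integer(0), block_rh = character(0),
                      block_lh = character(0), gg_cc_core = logical(0),
                      n_au_additions = integer(0)))
  }
  do.call(rbind, lapply(cands, function(x) data.frame(
    genome_id = x$genome_id, start = x$start, end = x$end,
    strand = x$strand, fold_score = x$fold_score, coverage = x$coverage,
    block_len = x$loop_pair$length, block_rh = x$loop_pair$rh_sub,
    block_lh = x$loop_pair$lh_sub,
    gg_cc_core = x$pattern$has_gg_cc_core,
    n_au_additions = x$pattern$n_au_additions)))
}

#' Write / read a screen report TSV
#' @param report a [screen_report()] data.frame.
#' @param path TSV path.
#' @return `path` invisibly, or the report data.frame.
#' @export
write_screen_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Naive exact-substring search (primary-sequence baseline)
#'
#' Finds exact occurrences of a query on both strands of a genome -- the
#' primary-sequence counterpart to the structure-driven screen, used to
#' demonstrate that sequence search misses diverged family members that
#' structure recovers.
#'
#' @param genome a [seq_record()] or string.
#' @param query query string.
#' @return data.frame `start,end,strand` (0-based half-open).
#' @export
naive_sequence_search <- function(genome, query) {
  g <- .residues(genome, "rna")
  q <- .residues(query, "rna")
  hits <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") q else rna_revcomp(q)
    m <- gregexpr(subj, g, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      for (p in as.integer(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = p - 1L, end = p - 1L + nchar(q), strand = strand)
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, hits)
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson Eulerian shuffle: returns a random permutation of
#' the sequence preserving its exact dinucleotide counts, the standard
#' null for scoring structured RNA windows.
#'
#' @param seq RNA string or [seq_record()].
#' @param seed integer seed (the shuffle is deterministic given it).
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  s <- strsplit(.residues(seq, "rna"), "")[[1]]
  if (length(s) < 3L) return(paste(s, collapse = ""))
  .with_seed(seed, .dinuc_shuffle_impl(s))
}

.dinuc_shuffle_impl <- function(s) {
  n <- length(s)
  verts <- unique(s)
  edges <- lapply(setNames(verts, verts),
                  function(v) s[which(s[-n] == v) + 1L])
  last <- s[n]
  # pick a last-edge spanning tree oriented toward the last vertex
  ok <- FALSE
  lastedge <- list()
  for (attempt in 1:1000) {
    lastedge <- list()
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      outs <- edges[[v]]
      if (!length(outs)) { ok <- FALSE; break }
      lastedge[[v]] <- outs[sample.int(length(outs), 1L)]
    }
    if (ok) {
      for (v in setdiff(verts, last)) {
        cur <- v
        steps <- 0L
        while (cur != last && steps <= length(verts)) {
          cur <- lastedge[[cur]]
          steps <- steps + 1L
        }
        if (cur != last) { ok <- FALSE; break }
      }
    }
    if (ok) break
    if (!length(setdiff(verts, last))) { ok <- TRUE; break }
  }
  if (!ok) return(paste(s, collapse = ""))  # degenerate composition
  shuffled <- lapply(setNames(verts, verts), function(v) {
    outs <- edges[[v]]
    if (v != last && length(outs)) {
      drop <- match(lastedge[[v]], outs)
      rest <- outs[-drop]
      c(if (length(rest)) sample(rest) else character(0), lastedge[[v]])
    } else if (length(outs) > 1L) sample(outs) else outs
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Empirical fold-score percentile against a shuffle null
#'
#' Folds `n_shuffles` dinucleotide-preserving shuffles of a window and
#' returns the fraction of shuffles scoring at or below (i.e. at least
#' as stable as) the observed window -- an empirical p-value-like
#' complement to the fixed score threshold.
#'
#' @param wseq window sequence.
#' @param cfg a [screen_config()].
#' @param n_shuffles number of shuffles (default 100).
#' @param seed integer seed.
#' @return fraction in `[0, 1]` (small = window more stable than null).
#' @export
window_score_percentile <- function(wseq, cfg = screen_config(),
                                    n_shuffles = 100L, seed = 1L) {
  s <- .residues(wseq, "rna")
  obs <- score_structure(fold_max_pairing(s, cfg$min_hairpin,
                                          cfg$allow_gu))$pair_energy_total
  null_scores <- vapply(seq_len(n_shuffles), function(k) {
    sh <- dinucleotide_shuffle(s, seed = seed + k)
    score_structure(fold_max_pairing(sh, cfg$min_hairpin,
                                     cfg$allow_gu))$pair_energy_total
  }, numeric(1))
  mean(null_scores <= obs)
}
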
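#' pRNA scaffold specification
#'
#' Defines the simplified domain-1 architecture emulated by the
#' generator: a closing helix opening into a three-way-junction
#' multiloop from which two hairpin arms emanate, the first carrying the
#' right-hand (RH) loop and the second the left-hand (LH) loop.  The
#' designed LH/RH complementary block has a GG:CC core plus A/U
#' additions (block length 2-4); a critical G sits in the junction tract
#' between the two arms (the ATP-binding-relevant bulge).
#'
#' @param h0,h1,h2 helix lengths in bp (closing helix, RH arm, LH arm).
#' @param rh_loop,lh_loop hairpin loop lengths in nt.
#' @param gap1,gap2,gap3 junction tract lengths (before arm 1, between
#'   arms, after arm 2).
#' @param block_len designed LH/RH block length (2-4: a GG:CC core plus
#'   `block_len - 2` A/U additions).
#' @return list of class `prna_scaffold` with a segment layout table
#'   (0-based half-open coordinates) and `length`.
#' @export
prna_scaffold <- function(h0 = 9L, h1 = 8L, h2 = 8L, rh_loop = 6L,
                          lh_loop = 6L, gap1 = 2L, gap2 = 3L, gap3 = 2L,
                          block_len = 4L) {
  stopifnot(h0 >= 4L, h1 >= 4L, h2 >= 4L, block_len >= 2L, block_len <= 4L,
            rh_loop >= max(3L, block_len), lh_loop >= max(3L, block_len),
            gap1 >= 1L, gap2 >= 1L, gap3 >= 1L)
  lens <- c(h0_5 = h0, gap1 = gap1, h1_5 = h1, rh_loop = rh_loop,
            h1_3 = h1, gap2 = gap2, h2_5 = h2, lh_loop = lh_loop,
            h2_3 = h2, gap3 = gap3, h0_3 = h0)
  ends <- cumsum(lens)
  segs <- data.frame(segment = names(lens),
                     start0 = as.integer(ends - lens),
                     end0 = as.integer(ends), row.names = NULL)
  structure(list(h0 = h0, h1 = h1, h2 = h2, rh_loop = rh_loop,
                 lh_loop = lh_loop, gap1 = gap1, gap2 = gap2, gap3 = gap3,
                 block_len = as.integer(block_len),
                 segments = segs, length = as.integer(ends[length(ends)])),
            class = "prna_scaffold")
}

.seg <- function(scaffold, name) {
  r <- scaffold$segments[scaffold$segments$segment == name, ]
  c(r$start0, r$end0)  # 0-based half-open
}

# designed pair table (1-based) for a scaffold: the three helices
.designed_pairs <- function(sc) {
  pt <- integer(sc$length)
  link <- function(seg5, seg3) {
    a <- .seg(sc, seg5); b <- .seg(sc, seg3)
    n <- a[2] - a[1]
    for (t in seq_len(n)) pt[a[1] + t] <<- b[2] - t + 1L
    for (t in seq_len(n)) pt[b[2] - t + 1L] <<- a[1] + t
  }
  link("h0_5", "h0_3")
  link("h1_5", "h1_3")
  link("h2_5", "h2_3")
  pt
}

#' Sample a pRNA instance from a scaffold
#'
#' Draws helix strands as exact reverse complements, random loop and
#' junction bases, a designed RH block (GG or CC core at a random
#' position, A/U additions) mirrored into the LH loop as its reverse
#' complement, and a fixed critical G in the central junction tract.
#' Seeded rejection sampling accepts a draw only when
#' [fold_max_pairing()] on the result recovers the three-way junction,
#' both designed loops as hairpins, and the designed block as the
#' active maximal LH/RH block -- so generated instances re-validate
#' against the screen's structural criteria by construction.
#'
#' @param scaffold a [prna_scaffold()].
#' @param seed integer seed (output is deterministic given it).
#' @param gc GC weight for random positions (default 0.5).
#' @param id record id.
#' @param max_tries rejection-sampling bound (default 100).
#' @return list of class `prna_instance`: `record` ([seq_record()]),
#'   `structure` (designed [secondary_structure()]), and `annotation`
#'   (scaffold, designed pair table, 0-based loop and block coordinates,
#'   block pair types, critical-G position, feature column sets).
#' @export
sample_prna <- function(scaffold = prna_scaffold(), seed = 1L, gc = 0.5,
                        id = "prna", max_tries = 100L) {
  stopifnot(inherits(scaffold, "prna_scaffold"))
  .with_seed(seed, {
    inst <- NULL
    for (try in seq_len(max_tries)) {
      cand <- .draw_prna(scaffold, gc, id)
      if (.validates(cand)) {
        inst <- cand
        break
      }
    }
    if (is.null(inst))
      stop("sample_prna: no draw satisfied the structural criteria after ",
           max_tries, " tries (infeasible scaffold?)")
    inst
  })
}

# can positions a and b pair under folding rules (WC + GU)?
.fold_pairable <- function(x, y) {
  p <- paste0(x, y)
  p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# helix strand with G:C-pinned ends, so the designed stack dominates
# count-neutral slippage alternatives under the energy tie-break
.draw_helix <- function(len, gc) {
  v <- .sample_base(len, gc)
  v[c(1L, len)] <- sample(c("G", "C"), 2L, replace = TRUE)
  paste(v, collapse = "")
}

.draw_prna <- function(sc, gc, id) {
  bl <- sc$block_len
  h0 <- .draw_helix(sc$h0, gc)
  h1 <- .draw_helix(sc$h1, gc)
  h2 <- .draw_helix(sc$h2, gc)
  # designed RH block: GG or CC core centered, A/U additions at the
  # edges (an edge addition lost to an accidental pair still leaves an
  # active core-bearing block)
  core <- rep(sample(c("G", "C"), 1L), 2L)
  core_at <- bl %/% 2L  # core occupies positions core_at, core_at + 1
  block <- character(bl)
  block[core_at + 0:1] <- core
  if (bl > 2L) block[-(core_at + 0:1)] <-
      sample(c("A", "U"), bl - 2L, replace = TRUE)
  rh_block <- paste(block, collapse = "")
  lh_block <- rna_revcomp(rh_block)
  rh_off <- (sc$rh_loop - bl) %/% 2L
  lh_off <- (sc$lh_loop - bl) %/% 2L
  # loop free bases are drawn sequentially from the sets that rule out
  # any intra-loop pair (separation > min_hairpin), so max-pairing
  # folding cannot absorb loop bases at divergence 0
  fill_loop <- function(len, blk, off) {
    bchars <- strsplit(blk, "")[[1]]
    bases <- c("A", "C", "G", "U")
    for (t in 1:50) {
      v <- character(len)
      v[(off + 1L):(off + length(bchars))] <- bchars
      ok <- TRUE
      for (i in seq_len(len)) {
        if (nzchar(v[i])) next
        partners <- v[c(seq2(1L, i - 4L), seq2(i + 4L, len))]
        partners <- partners[nzchar(partners)]
        allowed <- bases[vapply(bases, function(b)
          !any(vapply(partners, .fold_pairable, logical(1), y = b)),
          logical(1))]
        if (!length(allowed)) { ok <- FALSE; break }
        v[i] <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
      }
      if (ok) return(paste(v, collapse = ""))
    }
    paste(.sample_base(len, gc), collapse = "")  # validation will reject
  }
  rh <- fill_loop(sc$rh_loop, rh_block, rh_off)
  lh <- fill_loop(sc$lh_loop, lh_block, lh_off)
  gap1 <- paste(.sample_base(sc$gap1, gc), collapse = "")
  gap3 <- paste(.sample_base(sc$gap3, gc), collapse = "")
  g2 <- .sample_base(sc$gap2, gc)
  gpos <- (sc$gap2 + 1L) %/% 2L
  g2[gpos] <- "G"
  gap2 <- paste(g2, collapse = "")
  seq <- paste0(h0, gap1, h1, rh, rna_revcomp(h1), gap2,
                h2, lh, rna_revcomp(h2), gap3, rna_revcomp(h0))
  pt <- .designed_pairs(sc)
  rh_span <- .seg(sc, "rh_loop")
  lh_span <- .seg(sc, "lh_loop")
  gap2_span <- .seg(sc, "gap2")
  features <- list(
    Bulge1 = seq2(rh_span[1], rh_span[2] - 1L),
    Bulge2 = seq2(gap2_span[1], gap2_span[2] - 1L),
    Bulge3 = seq2(lh_span[1], lh_span[2] - 1L),
    critical_G = gap2_span[1] + gpos - 1L,
    `3WJ` = c(seq2(.seg(sc, "gap1")[1], .seg(sc, "gap1")[2] - 1L),
              seq2(gap2_span[1], gap2_span[2] - 1L),
              seq2(.seg(sc, "gap3")[1], .seg(sc, "gap3")[2] - 1L)))
  block_chars <- strsplit(rh_block, "")[[1]]
  structure(list(
    record = seq_record(id, seq, "rna"),
    structure = secondary_structure(seq, pt),
    annotation = list(
      scaffold = sc, pairs = pt,
      rh_loop0 = rh_span, lh_loop0 = lh_span,
      rh_block0 = c(rh_span[1] + rh_off, rh_span[1] + rh_off + bl),
      lh_block0 = c(lh_span[1] + lh_off, lh_span[1] + lh_off + bl),
      rh_block = rh_block, lh_block = lh_block,
      block_types = ifelse(block_chars %in% c("G", "C"), "GC", "AU"),
      critical_g0 = gap2_span[1] + gpos - 1L,
      features = features)
  ), class = "prna_instance")
}

# closed-loop validation: fold the draw and require the designed
# architecture to be recovered
.validates <- function(inst) {
  ann <- inst$annotation
  folded <- fold_max_pairing(inst$record)
  rep <- parse_junctions(folded)
  if (!rep$has_3wj) return(FALSE)
  hp <- rep$hairpins
  rh_ok <- any(hp$start0 == ann$rh_loop0[1] & hp$end0 == ann$rh_loop0[2])
  lh_ok <- any(hp$start0 == ann$lh_loop0[1] & hp$end0 == ann$lh_loop0[2])
  if (!rh_ok || !lh_ok) return(FALSE)
  rh <- substr(inst$record$residues, ann$rh_loop0[1] + 1L, ann$rh_loop0[2])
  lh <- substr(inst$record$residues, ann$lh_loop0[1] + 1L, ann$lh_loop0[2])
  blk <- max_complementary_block(rh, lh)
  blk$length == nchar(ann$rh_block) && blk$rh_sub == ann$rh_block &&
    predict_activity(blk)$active
}

#' @export
print.prna_instance <- function(x, ...) {
  cat("<prna_instance> ", x$record$id, ", ", nchar(x$record$residues),
      " nt, designed block ", x$annotation$rh_block, ":",
      x$annotation$lh_block, "\n", sep = "")
  invisible(x)
}

#' Diverge a pRNA instance
#'
#' Applies per-site substitutions at probability `rate`.  With
#' `compensatory = TRUE` the designed structure and block are preserved:
#' a substitution at a helix position applies the Watson-Crick
#' complementary substitution to its partner; a substitution at a
#' designed-block position swaps within its pair type (G:C positions
#' exchange G and C, A:U positions exchange A and U) with the partner
#' kept complementary, so the block's length, GG:CC core, and activity
#' call are invariant.  With `compensatory = FALSE` every position
#' mutates independently, degrading structure and pairing -- the
#' one-sided mutations that inactivate hand-in-hand assembly.
#'
#' Structure preservation means preservation of the folded architecture,
#' not merely of designed-pair complementarity: a compensatory draw whose
#' mutated free positions would refold the molecule away from the
#' three-way junction is redrawn (selection purges fold-breaking
#' mutations), using the same closed-loop validation as [sample_prna()].
#'
#' @param prna a [sample_prna()] instance.
#' @param rate per-site substitution probability in `[0, 1]`.
#' @param compensatory preserve designed pairing (default TRUE).
#' @param seed integer seed.
#' @param id id of the diverged record (default: parent id + suffix).
#' @param max_tries redraw bound for the structure-preservation
#'   constraint under `compensatory = TRUE`.
#' @return a `prna_instance` with mutated sequence, same coordinates.
#' @export
diverge <- function(prna, rate, compensatory = TRUE, seed = 1L, id = NULL,
                    max_tries = 100L) {
  stopifnot(inherits(prna, "prna_instance"), rate >= 0, rate <= 1)
  ann <- prna$annotation
  chars <- strsplit(prna$record$residues, "")[[1]]
  n <- length(chars)
  if (is.null(id)) id <- paste0(prna$record$id, "_d", seed)
  if (compensatory) {
    out <- .with_seed(seed, {
      res <- NULL
      for (t in seq_len(max_tries)) {
        cand <- .apply_compensatory(prna, chars, rate, id)
        if (rate == 0 || .validates(cand)) {
          res <- cand
          break
        }
      }
      if (is.null(res)) {
        warning("diverge: no structure-preserving mutation pattern found",
                " in ", max_tries, " tries; returning last draw")
        res <- cand
      }
      res
    })
    return(out)
  }
  new_chars <- .with_seed(seed, {
    hit <- runif(n) < rate
    for (i in which(hit)) chars[i] <- .sample_base(1L, exclude = chars[i])
    chars
  })
  .finish_instance(prna, new_chars, id)
}

# overwrite the designed block with the pair-type-preserving swap
# variant `mask` of the base block (bit t set = swap position t+1),
# mirror it into the LH loop, and re-validate; NULL when the resulting
# molecule no longer folds to the designed architecture
.set_block_variant <- function(d, base, mask, seed = 1L, max_tries = 30L,
                               validate = TRUE, resample_free = FALSE) {
  ann <- d$annotation
  bchars <- strsplit(base$annotation$rh_block, "")[[1]]
  swap <- c(G = "C", C = "G", A = "U", U = "A")
  for (t in seq_along(bchars)) {
    if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) != 0L)
      bchars[t] <- swap[bchars[t]]
  }
  rh_block <- paste(bchars, collapse = "")
  lh_block <- rna_revcomp(rh_block)
  chars <- strsplit(d$record$residues, "")[[1]]
  chars[(ann$rh_block0[1] + 1L):ann$rh_block0[2]] <-
    strsplit(rh_block, "")[[1]]
  chars[(ann$lh_block0[1] + 1L):ann$lh_block0[2]] <-
    strsplit(lh_block, "")[[1]]
  # free (non-block) loop positions may be incompatible with the new
  # block (accidental pairs or block extensions); resample them until
  # the designed architecture re-validates
  free_pos <- setdiff(c(seq2(ann$rh_loop0[1] + 1L, ann$rh_loop0[2]),
                        seq2(ann$lh_loop0[1] + 1L, ann$lh_loop0[2])),
                      c(seq2(ann$rh_block0[1] + 1L, ann$rh_block0[2]),
                        seq2(ann$lh_block0[1] + 1L, ann$lh_block0[2])))
  if (!validate) {
    if (resample_free) {
      chars[free_pos] <- .with_seed(seed, .sample_base(length(free_pos)))
    }
    return(.finish_instance(d, chars, d$record$id))
  }
  .with_seed(seed, {
    res <- NULL
    for (t in seq_len(max_tries)) {
      out <- .finish_instance(d, chars, d$record$id)
      if (.validates(out)) {
        res <- out
        break
      }
      chars[free_pos] <- .sample_base(length(free_pos))
    }
    res
  })
}

# one compensatory mutation draw (advances the RNG): helix positions get
# a free base with complementary partner, designed-block positions swap
# within pair type, unpaired positions are free
.apply_compensatory <- function(prna, chars, rate, id) {
  ann <- prna$annotation
  n <- length(chars)
  pv <- ann$pairs
  bl <- length(ann$block_types)
  rh_pos <- ann$rh_block0[1] + seq_len(bl)       # 1-based
  lh_pos <- ann$lh_block0[1] + seq_len(bl)
  for (t in seq_len(bl)) {
    pv[rh_pos[t]] <- lh_pos[bl - t + 1L]
    pv[lh_pos[bl - t + 1L]] <- rh_pos[t]
  }
  in_block <- logical(n)
  in_block[c(rh_pos, lh_pos)] <- TRUE
  done <- logical(n)
  for (i in seq_len(n)) {
    if (done[i]) next
    j <- pv[i]
    if (j > 0L) done[j] <- TRUE
    done[i] <- TRUE
    if (runif(1) >= rate) next
    if (j == 0L) {
      chars[i] <- .sample_base(1L, exclude = chars[i])
    } else if (in_block[i]) {
      swap <- c(G = "C", C = "G", A = "U", U = "A")
      chars[i] <- swap[chars[i]]
      chars[j] <- .wc_complement(chars[i])
    } else {
      chars[i] <- .sample_base(1L, exclude = chars[i])
      chars[j] <- .wc_complement(chars[i])
    }
  }
  .finish_instance(prna, chars, id)
}

.finish_instance <- function(prna, new_chars, id) {
  ann <- prna$annotation
  seq <- paste(new_chars, collapse = "")
  out <- prna
  out$record <- seq_record(id, seq, "rna")
  out$structure <- secondary_structure(seq, ann$pairs)
  out$annotation$rh_block <- substr(seq, ann$rh_block0[1] + 1L,
                                    ann$rh_block0[2])
  out$annotation$lh_block <- substr(seq, ann$lh_block0[1] + 1L,
                                    ann$lh_block0[2])
  out
}

#' Plant pRNA instances in a random background genome
#'
#' Generates an i.i.d. background genome with the requested GC fraction
#' and inserts each pRNA at a uniform-random non-overlapping position
#' (reverse-complemented for minus-strand placements), recording ground
#' truth.
#'
#' @param prnas list of `prna_instance`s (or [seq_record()]s).
#' @param genome_len genome length in nt.
#' @param gc background GC fraction (default 0.5).
#' @param strand `"plus"`, `"minus"`, or `"random"`.
#' @param seed integer seed.
#' @param id genome record id.
#' @param max_tries placement retries before giving up.
#' @return list of class `planted_genome`: `genome` ([seq_record()]) and
#'   `truth` (data.frame `start,end,strand,family_id`, 0-based
#'   half-open).
#' @export
plant_in_genome <- function(prnas, genome_len = 10000L, gc = 0.5,
                            strand = c("plus", "minus", "random"),
                            seed = 1L, id = "synthetic_genome",
                            max_tries = 1000L) {
  strand <- match.arg(strand)
  recs <- lapply(prnas, function(p) {
    if (inherits(p, "prna_instance")) p$record else p
  })
  total <- sum(vapply(recs, function(r) nchar(r$residues), integer(1)))
  if (total >= genome_len)
    stop("total planted length ", total, " >= genome length ", genome_len)
  .with_seed(seed, {
    bg <- .sample_base(genome_len, gc)
    placed <- data.frame(start = integer(0), end = integer(0),
                         strand = character(0), family_id = character(0))
    for (r in recs) {
      len <- nchar(r$residues)
      st <- NA_integer_
      for (try in seq_len(max_tries)) {
        cand <- sample.int(genome_len - len + 1L, 1L) - 1L
        if (!nrow(placed) ||
            all(cand + len <= placed$start | cand >= placed$end)) {
          st <- cand
          break
        }
      }
      if (is.na(st)) stop("could not place '", r$id,
                          "' without overlap after ", max_tries, " tries")
      sd <- switch(strand, plus = "+", minus = "-",
                   random = sample(c("+", "-"), 1L))
      ins <- if (sd == "+") r$residues else rna_revcomp(r$residues)
      bg[(st + 1L):(st + len)] <- strsplit(ins, "")[[1]]
      placed <- rbind(placed, data.frame(start = st, end = st + len,
                                         strand = sd, family_id = r$id))
    }
    placed <- placed[order(placed$start), ]
    rownames(placed) <- NULL
    list_out <- list(genome = seq_record(id, paste(bg, collapse = ""),
                                         "rna"),
                     truth = placed)
    structure(list_out, class = "planted_genome")
  })
}

#' Build an annotated alignment of a diverged pRNA family
#'
#' Diverges one sampled scaffold instance `n` times under compensatory
#' covariation; because every row shares the scaffold coordinates the
#' rows are aligned by construction and the designed regions become the
#' feature map (`Bulge1` = RH loop, `Bulge2` = central junction tract,
#' `Bulge3` = LH loop, `critical_G`, `3WJ` = junction tracts).  Options
#' force pairwise-distinct bulge strings, conserve or vary the critical
#' G, and gap out feature regions in a subset of rows (k-of-n
#' occupancy).
#'
#' @param n number of rows.
#' @param scaffold a [prna_scaffold()].
#' @param divergence compensatory per-site substitution rate.
#' @param seed integer seed.
#' @param distinct_features features whose region strings must be
#'   pairwise distinct across rows (default `Bulge1`/`Bulge3`; ignored
#'   when `divergence == 0`).
#' @param occupancy named list `feature = k`: only `k` of `n` rows keep
#'   the feature, the rest are gapped there.
#' @param critical_g_variants number of rows whose critical-G column is
#'   mutated to a non-G base (default 0: fully conserved).
#' @param max_tries per-row redraw bound for the distinctness constraint.
#' @return a [feature_alignment()].
#' @export
make_alignment <- function(n, scaffold = prna_scaffold(),
                           divergence = 0.3, seed = 1L,
                           distinct_features = c("Bulge1", "Bulge3"),
                           occupancy = NULL, critical_g_variants = 0L,
                           max_tries = 200L) {
  stopifnot(n >= 1L)
  base <- sample_prna(scaffold, seed = seed)
  feats <- base$annotation$features
  if (divergence == 0) distinct_features <- character(0)
  region <- function(s, f) {
    paste(strsplit(s, "")[[1]][feats[[f]] + 1L], collapse = "")
  }
  rows <- character(n)
  names(rows) <- sprintf("fam_%03d", seq_len(n))
  seen <- lapply(distinct_features, function(f) character(0))
  names(seen) <- distinct_features
  bl <- length(base$annotation$block_types)
  for (i in seq_len(n)) {
    ok <- FALSE
    # rows cycle through the designed block's pair-type-preserving swap
    # variants, which makes bulge regions distinct across variants by
    # construction; rows sharing a variant differ in their free loop
    # bases (enforced by redrawing)
    mask <- if (length(distinct_features)) (i - 1L) %% bitwShiftL(1L, bl)
    else 0L
    for (t in seq_len(max_tries)) {
      sub_seed <- (seed + 7919L * i + 104729L * (t - 1L)) %%
        .Machine$integer.max
      d <- diverge(base, divergence, compensatory = TRUE, seed = sub_seed)
      if (length(distinct_features)) {
        # alignment rows are aligned by construction and never folded;
        # block variants need no structural re-validation, and retries
        # redraw the free loop bases outright to widen the region space
        d <- .set_block_variant(d, base, mask, seed = sub_seed + 1L,
                                validate = FALSE, resample_free = t > 1L)
      }
      s <- d$record$residues
      clash <- FALSE
      for (f in distinct_features) {
        if (region(s, f) %in% seen[[f]]) { clash <- TRUE; break }
      }
      if (!clash) {
        rows[i] <- s
        for (f in distinct_features)
          seen[[f]] <- c(seen[[f]], region(s, f))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("make_alignment: could not draw ", n,
                  " rows with distinct ",
                  paste(distinct_features, collapse = "/"), " regions")
  }
  gcol <- feats$critical_G + 1L
  chars <- strsplit(rows, "")
  for (i in seq_len(n)) chars[[i]][gcol] <- "G"
  extra <- .with_seed(seed + 31L, {
    list(gvar = if (critical_g_variants > 0L)
      sample.int(n, critical_g_variants) else integer(0),
      gaps = if (!is.null(occupancy)) lapply(occupancy, function(k) {
        stopifnot(k >= 0L, k <= n)
        if (k < n) sample.int(n, n - k) else integer(0)
      }) else list())
  })
  for (i in extra$gvar) chars[[i]][gcol] <- sample(c("A", "C", "U"), 1L)
  for (f in names(extra$gaps)) {
    cols1 <- feats[[f]] + 1L
    for (i in extra$gaps[[f]]) chars[[i]][cols1] <- "-"
  }
  rows <- vapply(chars, paste, character(1), collapse = "")
  names(rows) <- sprintf("fam_%03d", seq_len(n))
  feature_alignment(rows, feats)
}

#' Generate a loop-variant panel with expected activity labels
#'
#' Realizes the classic complementation-experiment configurations as
#' loop species with ground-truth labels:
#' `self_complementary` (one species whose RH pairs its own LH),
#' `cross_pair` (two species, individually inactive, jointly closing a
#' 2-cycle), `cross_triplet` (three species closing a 3-cycle),
#' `unpaired` (one species with non-complementary loops), `gc_only`
#' (a lone GG:CC 2-bp pairing -- active) and `au_only` (a lone AA:UU
#' 2-bp pairing -- inactive).  Generated loops are verified against the
#' [predict_activity()] rules (for the cross tags: exactly the cycle
#' edges active); an unrealizable draw is retried and eventually errors.
#'
#' @param tags character vector of pattern tags (repeats allowed).
#' @param seed integer seed.
#' @param loop_len loop length for searched tags (default 4).
#' @param max_tries search bound per tag.
#' @return list of class `loop_panel`: `species` (data.frame
#'   `name,rh,lh,group,tag`) and `expected` (data.frame per group:
#'   `individual_active`, `mixture_active`, `minimal_cycle`).
#' @export
make_loop_panel <- function(tags, seed = 1L, loop_len = 4L,
                            max_tries = 2000L) {
  valid <- c("self_complementary", "cross_pair", "cross_triplet",
             "unpaired", "gc_only", "au_only")
  stopifnot(all(tags %in% valid))
  species <- list()
  expected <- list()
  .with_seed(seed, {
    for (g in seq_along(tags)) {
      tag <- tags[g]
      grp <- sprintf("g%d_%s", g, tag)
      sp <- switch(tag,
        gc_only = data.frame(name = "G/g", rh = "GG", lh = "CC"),
        au_only = data.frame(name = "A/u", rh = "AA", lh = "UU"),
        self_complementary = .search_self(loop_len, max_tries),
        unpaired = .search_unpaired(loop_len, max_tries),
        cross_pair = .search_cycle(2L, loop_len, max_tries),
        cross_triplet = .search_cycle(3L, loop_len, max_tries))
      sp$name <- paste0(sp$name, if (sum(tags == tag) > 1L)
        paste0("#", g) else "")
      sp$group <- grp
      sp$tag <- tag
      species[[g]] <- sp
      indiv <- vapply(seq_len(nrow(sp)), function(k) {
        hexamer_verdict(sp[k, c("name", "rh", "lh")])$hexamer_active
      }, logical(1))
      verdict <- hexamer_verdict(sp[, c("name", "rh", "lh")])
      expected[[g]] <- data.frame(
        group = grp, tag = tag,
        individual_active = all(indiv),
        mixture_active = verdict$hexamer_active,
        minimal_cycle = verdict$minimal_cycle)
    }
  })
  out <- list(species = do.call(rbind, species),
              expected = do.call(rbind, expected))
  # ground-truth labels the tags promise; generation must have realized
  # them or the search would have errored -- assert once more
  want_mix <- c(self_complementary = TRUE, cross_pair = TRUE,
                cross_triplet = TRUE, unpaired = FALSE, gc_only = TRUE,
                au_only = FALSE)
  if (!all(out$expected$mixture_active == want_mix[out$expected$tag]))
    stop("make_loop_panel: generated panel violates its tag semantics")
  structure(out, class = "loop_panel")
}

.rand_loop <- function(len, with_core = TRUE) {
  v <- .sample_base(len)
  if (with_core) {
    core <- sample(c("G", "C"), 1L)
    at <- sample.int(len - 1L, 1L)
    v[at + 0:1] <- core
  }
  paste(v, collapse = "")
}

.search_self <- function(len, max_tries) {
  for (t in seq_len(max_tries)) {
    rh <- .rand_loop(len)
    lh <- rna_revcomp(rh)
    if (predict_activity(max_complementary_block(rh, lh))$active)
      return(data.frame(name = "S/s", rh = rh, lh = lh))
  }
  stop("unrealizable tag: self_complementary")
}

.search_unpaired <- function(len, max_tries) {
  for (t in seq_len(max_tries)) {
    rh <- .rand_loop(len, with_core = FALSE)
    lh <- .rand_loop(len, with_core = FALSE)
    if (!predict_activity(max_complementary_block(rh, lh))$active)
      return(data.frame(name = "U/x", rh = rh, lh = lh))
  }
  stop("unrealizable tag: unpaired")
}

# k-cycle: rh_i pairs lh_{i+1} (lh_{i+1} = revcomp(rh_i)); all other
# ordered pairs, including self-pairs, must be inactive.  Because
# block(rh_u, lh_v) reduces to the common substrings of rh_u and
# rh_{v-1}, drawing each rh from a different "flavor" -- {A,G} strings
# with a GG core, {U,C} strings with a CC core, and alternating G/C --
# guarantees the cycle edges are the only active pairings: strings of
# different flavors share no pairable 2-mer.
.search_cycle <- function(k, len, max_tries) {
  nms <- if (k == 2L) c("A/i", "I/a") else c("A/i", "I/j", "J/a")
  flavor <- function(f) {
    if (f == 1L) {
      for (t in seq_len(max_tries)) {
        v <- sample(c("A", "G"), len, replace = TRUE)
        s <- paste(v, collapse = "")
        if (grepl("GG", s, fixed = TRUE)) return(s)
      }
    } else if (f == 2L) {
      for (t in seq_len(max_tries)) {
        v <- sample(c("U", "C"), len, replace = TRUE)
        s <- paste(v, collapse = "")
        if (grepl("CC", s, fixed = TRUE)) return(s)
      }
    } else {
      start <- sample(c("G", "C"), 1L)
      other <- if (start == "G") "C" else "G"
      return(paste(rep(c(start, other), length.out = len), collapse = ""))
    }
    stop("unrealizable tag: ", if (k == 2L) "cross_pair" else
      "cross_triplet")
  }
  rh <- vapply(seq_len(k), flavor, character(1))
  # lh_i = revcomp(rh_{i-1}) so that rh_i pairs lh_{i+1} around the cycle
  lh <- vapply(rh[c(k, seq_len(k - 1L))], rna_revcomp, character(1),
               USE.NAMES = FALSE)
  for (u in seq_len(k)) for (v in seq_len(k)) {
    act <- predict_activity(max_complementary_block(rh[u], lh[v]))$active
    if (act != (v == (u %% k) + 1L))
      stop("unrealizable tag: ", if (k == 2L) "cross_pair" else
        "cross_triplet")
  }
  data.frame(name = nms, rh = rh, lh = lh)
}
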
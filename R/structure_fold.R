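#' Pseudoknot-free secondary structure
#'
#' A sequence plus an involutive pair table.  Validated on construction:
#' pairing is involutive (`pairs[i] == j` iff `pairs[j] == i`), contains
#' no pseudoknots, and every hairpin loop spans at least `min_hairpin`
#' unpaired bases.
#'
#' @param seq RNA string or [seq_record()].
#' @param pairs integer vector, 1-based partner per position (0 =
#'   unpaired), or a dot-bracket string of the same length.
#' @param min_hairpin minimal hairpin loop length (default 3).
#' @return object of class `secondary_structure`: list with `seq`,
#'   `pairs` (1-based partner vector) and `dotbracket`.
#' @examples
#' secondary_structure("GGGAAACCC", "(((...)))")
#' @export
secondary_structure <- function(seq, pairs, min_hairpin = 3L) {
  seq <- .residues(seq, "rna")
  n <- nchar(seq)
  if (is.character(pairs)) {
    if (nchar(pairs) != n) stop("dot-bracket length != sequence length")
    pairs <- parse_dotbracket(pairs)
  }
  pairs <- as.integer(pairs)
  if (length(pairs) != n) stop("pair table length != sequence length")
  idx <- which(pairs > 0L)
  if (any(pairs[idx] == idx)) stop("self-pairing is not allowed")
  if (!all(pairs[pairs[idx]] == idx)) stop("pair table is not involutive")
  # pseudoknot + hairpin checks via a stack scan
  stack <- integer(0)
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j == 0L) next
    if (j > i) {
      stack <- c(stack, i)
    } else {
      if (!length(stack) || stack[length(stack)] != j)
        stop("pseudoknotted pair table at position ", i)
      stack <- stack[-length(stack)]
    }
  }
  opens <- idx[pairs[idx] > idx]
  for (i in opens) {
    j <- pairs[i]
    if (all(pairs[seq2(i + 1L, j - 1L)] == 0L) && (j - i - 1L) < min_hairpin)
      stop("hairpin loop shorter than min_hairpin = ", min_hairpin,
           " closed by pair (", i, ",", j, ")")
  }
  structure(list(seq = seq, pairs = pairs,
                 dotbracket = pairs_to_dotbracket(pairs)),
            class = "secondary_structure")
}

# seq() that yields integer(0) when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Convert a dot-bracket string to a 1-based pair table
#' @param db dot-bracket string over `.()`
#' @return integer vector of partners (0 = unpaired).
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c(".", "(", ")")))
    stop("dot-bracket may contain only '.', '(' and ')'")
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1])
  pt
}

pairs_to_dotbracket <- function(pairs) {
  out <- rep(".", length(pairs))
  out[pairs > seq_along(pairs)] <- "("
  out[pairs > 0L & pairs < seq_along(pairs)] <- ")"
  paste(out, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> ", nchar(x$seq), " nt, ",
      sum(x$pairs > 0) / 2, " pairs\n", sep = "")
  cat(" ", x$seq, "\n ", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Fold by base-pair maximization
#'
#' Predicts the pseudoknot-free structure maximizing the number of base
#' pairs (Watson-Crick, plus G:U wobble when `allow_gu = TRUE`); among
#' maximizers the structure with the lowest additive pair energy
#' (G:C = -3, A:U = -2, G:U = -1) is chosen, with a deterministic
#' traceback that pairs each 3' base with its smallest admissible 5'
#' partner.  Hairpin loops span at least `min_hairpin` unpaired bases.
#' A pre-computed structure (e.g. from an external thermodynamic folder)
#' can be supplied anywhere a `secondary_structure` is consumed.
#'
#' @param seq RNA string or [seq_record()].
#' @param min_hairpin minimal hairpin loop (default 3).
#' @param allow_gu permit G:U wobble pairs (default TRUE).
#' @return a [secondary_structure()].  Sequences shorter than
#'   `min_hairpin + 2` fold to the empty structure with a warning.
#' @examples
#' fold_max_pairing("GGGAAACCC")$dotbracket
#' @export
fold_max_pairing <- function(seq, min_hairpin = 3L, allow_gu = TRUE) {
  s <- .residues(seq, "rna")
  n <- nchar(s)
  if (grepl("[^ACGU]", s)) stop("fold_max_pairing: sequence must be AUCG")
  if (n < min_hairpin + 2L) {
    warning("sequence shorter than min_hairpin + 2; returning empty structure")
    return(secondary_structure(s, integer(n), min_hairpin))
  }
  pt <- nussinov_fold(s, as.integer(min_hairpin), isTRUE(allow_gu))
  secondary_structure(s, pt, min_hairpin)
}

#' Score a structure with the additive per-pair energy stand-in
#'
#' G:C pairs contribute -3, A:U -2, G:U -1; the total is a dimensionless
#' stand-in for folding free energy (more negative = more stable).
#'
#' @param s a [secondary_structure()].
#' @return list of class `fold_score` with `pair_energy_total` and
#'   `n_pairs`.
#' @export
score_structure <- function(s) {
  stopifnot(inherits(s, "secondary_structure"))
  chars <- strsplit(s$seq, "")[[1]]
  opens <- which(s$pairs > seq_along(s$pairs))
  e <- 0L
  for (i in opens) {
    pair <- paste0(sort(c(chars[i], chars[s$pairs[i]])), collapse = "")
    e <- e + switch(pair, "CG" = -3L, "AU" = -2L, "GU" = -1L, 0L)
  }
  structure(list(pair_energy_total = e, n_pairs = length(opens)),
            class = "fold_score")
}

#' Loop decomposition and three-way-junction detection
#'
#' Decomposes a structure into its loops: hairpin loops, internal loops /
#' bulges, multiloops, and the exterior loop.  Every unpaired position
#' belongs to exactly one loop.  A multiloop's degree counts the helices
#' incident to it, including the closing helix; `has_3wj` is `TRUE` iff
#' some multiloop has degree exactly 3.  All coordinates are 0-based
#' half-open.
#'
#' @param s a [secondary_structure()].
#' @return object of class `junction_report`: list with `hairpins`
#'   (data.frame `start0,end0,seq,close_i0,close_j0`), `internal`
#'   (data.frame of 5'/3' spans), `multiloops` (list of
#'   `degree`/`closing`/`children`), `exterior0`, `position_class`
#'   and `has_3wj`.
#' @export
parse_junctions <- function(s) {
  stopifnot(inherits(s, "secondary_structure"))
  pt <- s$pairs
  n <- length(pt)
  chars <- strsplit(s$seq, "")[[1]]
  cls <- rep(NA_character_, n)
  cls[pt > 0L] <- "paired"

  hp_start <- hp_end <- hp_ci <- hp_cj <- integer(0)
  hp_seq <- character(0)
  il_s5 <- il_e5 <- il_s3 <- il_e3 <- il_max <- integer(0)
  il_q5 <- il_q3 <- character(0)
  multiloops <- list()

  # exterior loop
  k <- 1L
  ext <- integer(0)
  while (k <= n) {
    if (pt[k] == 0L) {
      ext <- c(ext, k)
      k <- k + 1L
    } else k <- pt[k] + 1L
  }
  cls[ext] <- "exterior"

  opens <- which(pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    children <- list()
    unp <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (pt[k] == 0L) {
        unp <- c(unp, k)
        k <- k + 1L
      } else {
        children[[length(children) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      }
    }
    nc <- length(children)
    if (nc == 0L) {
      cls[unp] <- "hairpin"
      hp_start <- c(hp_start, i)
      hp_end <- c(hp_end, j - 1L)
      hp_seq <- c(hp_seq, paste(chars[unp], collapse = ""))
      hp_ci <- c(hp_ci, i - 1L)
      hp_cj <- c(hp_cj, j - 1L)
    } else if (nc == 1L) {
      if (length(unp)) {
        cls[unp] <- "internal"
        a <- children[[1]][1]; b <- children[[1]][2]
        il_s5 <- c(il_s5, i); il_e5 <- c(il_e5, a - 1L)
        il_s3 <- c(il_s3, b); il_e3 <- c(il_e3, j - 1L)
        il_q5 <- c(il_q5, paste(chars[seq2(i + 1L, a - 1L)], collapse = ""))
        il_q3 <- c(il_q3, paste(chars[seq2(b + 1L, j - 1L)], collapse = ""))
        il_max <- c(il_max, max(a - i - 1L, j - b - 1L))
      } # no unpaired: helix stacking, not a loop
    } else {
      cls[unp] <- "multiloop"
      multiloops[[length(multiloops) + 1L]] <- list(
        degree = nc + 1L,
        closing = c(i - 1L, j - 1L),
        children = lapply(children, function(p) p - 1L),
        unpaired0 = unp - 1L)
    }
  }

  degs <- vapply(multiloops, function(m) m$degree, integer(1))
  structure(list(
    hairpins = data.frame(start0 = hp_start, end0 = hp_end, seq = hp_seq,
                          close_i0 = hp_ci, close_j0 = hp_cj),
    internal = data.frame(span5_start0 = il_s5, span5_end0 = il_e5,
                          span3_start0 = il_s3, span3_end0 = il_e3,
                          seq5 = il_q5, seq3 = il_q3, max_span = il_max),
    multiloops = multiloops,
    exterior0 = ext - 1L,
    position_class = cls,
    has_3wj = any(degs == 3L)
  ), class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("<junction_report> ", nrow(x$hairpins), " hairpin(s), ",
      nrow(x$internal), " internal loop(s)/bulge(s), ",
      length(x$multiloops), " multiloop(s); has_3wj = ", x$has_3wj,
      "\n", sep = "")
  invisible(x)
}

#' Enumerate candidate RH/LH loop pairs
#'
#' Lists ordered pairs of distinct loops (hairpin loops and, optionally,
#' the unpaired tracts of internal loops/bulges) whose lengths fall in
#' `[min_loop, max_loop]`.  The first loop of each pair is the right-hand
#' candidate, the second the left-hand candidate; whether they actually
#' pair is decided downstream by [max_complementary_block()].
#'
#' @param s a [secondary_structure()].
#' @param report the [parse_junctions()] report for `s`.
#' @param min_loop,max_loop loop length bounds (defaults 3 and 12).
#' @param include_internal also consider internal-loop/bulge tracts.
#' @return data.frame with columns `rh_seq,rh_start0,rh_end0,rh_kind,
#'   lh_seq,lh_start0,lh_end0,lh_kind` (0-based half-open loop spans).
#' @export
eligible_loop_pairs <- function(s, report, min_loop = 3L, max_loop = 12L,
                                include_internal = TRUE) {
  stopifnot(inherits(report, "junction_report"))
  loops <- list()
  hp <- report$hairpins
  for (k in seq_len(nrow(hp))) {
    loops[[length(loops) + 1L]] <- list(seq = hp$seq[k], start0 = hp$start0[k],
                                        end0 = hp$end0[k], kind = "hairpin")
  }
  if (include_internal) {
    il <- report$internal
    for (k in seq_len(nrow(il))) {
      if (nzchar(il$seq5[k]))
        loops[[length(loops) + 1L]] <- list(seq = il$seq5[k],
                                            start0 = il$span5_start0[k],
                                            end0 = il$span5_end0[k],
                                            kind = "internal5")
      if (nzchar(il$seq3[k]))
        loops[[length(loops) + 1L]] <- list(seq = il$seq3[k],
                                            start0 = il$span3_start0[k],
                                            end0 = il$span3_end0[k],
                                            kind = "internal3")
    }
  }
  len_ok <- vapply(loops, function(l) {
    w <- nchar(l$seq)
    w >= min_loop && w <= max_loop
  }, logical(1))
  loops <- loops[len_ok]
  k <- length(loops)
  if (k < 2L) {
    return(data.frame(rh_seq = character(0), rh_start0 = integer(0),
                      rh_end0 = integer(0), rh_kind = character(0),
                      lh_seq = character(0), lh_start0 = integer(0),
                      lh_end0 = integer(0), lh_kind = character(0)))
  }
  grid <- expand.grid(a = seq_len(k), b = seq_len(k))
  grid <- grid[grid$a != grid$b, ]
  seqs <- vapply(loops, `[[`, character(1), "seq")
  st <- vapply(loops, `[[`, numeric(1), "start0")
  en <- vapply(loops, `[[`, numeric(1), "end0")
  kind <- vapply(loops, `[[`, character(1), "kind")
  data.frame(rh_seq = seqs[grid$a], rh_start0 = as.integer(st[grid$a]),
             rh_end0 = as.integer(en[grid$a]), rh_kind = kind[grid$a],
             lh_seq = seqs[grid$b], lh_start0 = as.integer(st[grid$b]),
             lh_end0 = as.integer(en[grid$b]), lh_kind = kind[grid$b],
             row.names = NULL)
}
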
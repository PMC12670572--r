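#' Maximal antiparallel complementary block between two loops
#'
#' String search for the longest contiguous block in which a substring of
#' the right-hand loop pairs antiparallel with a substring of the
#' left-hand loop under Watson-Crick rules (A:U, G:C; G:U optionally).
#' Ties are broken by more G:C pairs, then the smallest RH offset, then
#' the smallest LH offset.  A zero-length block is returned when no
#' complementarity exists.
#'
#' @param rh right-hand loop sequence (RNA string or [seq_record()]).
#' @param lh left-hand loop sequence.
#' @param allow_gu also accept G:U wobble pairs in the block (default
#'   FALSE: the loop-loop pairing and covariation logic is framed in
#'   Watson-Crick complementarity).
#' @return object of class `pair_block`: list with `rh_sub`, `lh_sub`,
#'   `length`, `n_gc`, `n_au`, `n_gu`, `rh_offset`, `lh_offset`
#'   (0-based starts within each loop).  `lh_sub` is the reverse
#'   complement of `rh_sub` when `allow_gu = FALSE`.
#' @examples
#' max_complementary_block("GGAA", "UUCC")
#' @export
max_complementary_block <- function(rh, lh, allow_gu = FALSE) {
  rh <- .residues(rh, "rna")
  lh <- .residues(lh, "rna")
  if (!nzchar(rh) || !nzchar(lh)) stop("empty loop sequence")
  a <- strsplit(rh, "")[[1]]
  b <- strsplit(lh, "")[[1]]
  m <- length(a)
  n <- length(b)
  pairable <- function(x, y) {
    (x == "A" && y == "U") || (x == "U" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G") ||
    (allow_gu && ((x == "G" && y == "U") || (x == "U" && y == "G")))
  }
  # D[i, j]: block length ending at rh position i, starting at lh
  # position j (rh[i - L + 1 .. i] pairs antiparallel lh[j .. j + L - 1])
  D <- matrix(0L, m, n)
  best <- list(len = 0L, gc = -1L, rh_off = 0L, lh_off = 0L)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (pairable(a[i], b[j])) {
      prev <- if (i > 1L && j < n) D[i - 1L, j + 1L] else 0L
      D[i, j] <- prev + 1L
      L <- D[i, j]
      rh_off <- i - L           # 0-based
      lh_off <- j - 1L
      sub <- a[(i - L + 1L):i]
      gc <- sum(sub %in% c("G", "C") &
                  rev(b[j:(j + L - 1L)]) %in% c("G", "C"))
      if (L > best$len ||
          (L == best$len && (gc > best$gc ||
            (gc == best$gc && (rh_off < best$rh_off ||
              (rh_off == best$rh_off && lh_off < best$lh_off)))))) {
        best <- list(len = L, gc = gc, rh_off = rh_off, lh_off = lh_off)
      }
    }
  }
  if (best$len == 0L) {
    return(structure(list(rh_sub = "", lh_sub = "", length = 0L,
                          n_gc = 0L, n_au = 0L, n_gu = 0L,
                          rh_offset = NA_integer_, lh_offset = NA_integer_),
                     class = "pair_block"))
  }
  L <- best$len
  rh_sub <- substr(rh, best$rh_off + 1L, best$rh_off + L)
  lh_sub <- substr(lh, best$lh_off + 1L, best$lh_off + L)
  ra <- strsplit(rh_sub, "")[[1]]
  la <- rev(strsplit(lh_sub, "")[[1]])  # antiparallel partner per position
  gc <- sum(ra %in% c("G", "C") & la %in% c("G", "C"))
  au <- sum(ra %in% c("A", "U") & la %in% c("A", "U"))
  structure(list(rh_sub = rh_sub, lh_sub = lh_sub, length = L,
                 n_gc = gc, n_au = au, n_gu = L - gc - au,
                 rh_offset = best$rh_off, lh_offset = best$lh_off),
            class = "pair_block")
}

#' @export
print.pair_block <- function(x, ...) {
  if (x$length == 0L) {
    cat("<pair_block> empty (no complementarity)\n")
  } else {
    cat(sprintf("<pair_block> %s : %s  (length %d, %d G:C, %d A:U)\n",
                x$rh_sub, x$lh_sub, x$length, x$n_gc, x$n_au))
  }
  invisible(x)
}

#' Classify the pairing pattern of a block
#'
#' Detects the recurrent GG:CC motif: `has_gg_cc_core` is `TRUE` when
#' the block contains two adjacent G:C pairs; `n_au_additions` counts
#' the A:U pairs flanking/extending the core.
#'
#' @param block a [max_complementary_block()] result.
#' @return list of class `pattern_class` with `has_gg_cc_core` and
#'   `n_au_additions`.
#' @export
classify_pattern <- function(block) {
  stopifnot(inherits(block, "pair_block"))
  core <- FALSE
  if (block$length >= 2L) {
    ra <- strsplit(block$rh_sub, "")[[1]]
    la <- rev(strsplit(block$lh_sub, "")[[1]])
    is_gc <- ra %in% c("G", "C") & la %in% c("G", "C")
    core <- any(is_gc[-length(is_gc)] & is_gc[-1])
  }
  structure(list(has_gg_cc_core = core, n_au_additions = block$n_au),
            class = "pattern_class")
}

#' Activity call for a loop-loop block
#'
#' Encodes the experimentally derived rules for hand-in-hand activity:
#' a 2-bp block is sufficient only when both pairs are G:C (a single
#' GG:CC pairing suffices); longer blocks (>= 3 bp) are called active
#' when they carry a GG:CC core, matching the universally observed
#' "GG/CC plus zero to two A/U additions" pattern.  Whether a >= 3 bp
#' all-A/U block would be active is not settled experimentally; the
#' GG:CC-core requirement for long blocks is an explicit assumption and
#' is surfaced in the `rule_fired` field.
#'
#' @param block a [max_complementary_block()] result.
#' @return list of class `activity_call` with `active` (logical) and
#'   `rule_fired` (`"block_ge3"`, `"gc_pair_only"` or `"none"`).
#' @examples
#' predict_activity(max_complementary_block("GG", "CC"))$active   # TRUE
#' predict_activity(max_complementary_block("AA", "UU"))$active   # FALSE
#' @export
predict_activity <- function(block) {
  stopifnot(inherits(block, "pair_block"))
  pat <- classify_pattern(block)
  rule <- if (block$length >= 3L && pat$has_gg_cc_core) "block_ge3"
  else if (block$length == 2L && block$n_gc == 2L) "gc_pair_only"
  else "none"
  structure(list(active = rule != "none", rule_fired = rule),
            class = "activity_call")
}
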
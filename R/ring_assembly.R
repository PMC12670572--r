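#' Loop species
#'
#' A named pRNA loop variant: the identity of its right-hand loop and of
#' its left-hand loop (the field's `A/i` notation: uppercase = RH,
#' lowercase = LH).
#'
#' @param name unique species name.
#' @param rh right-hand loop sequence.
#' @param lh left-hand loop sequence.
#' @return list of class `loop_species`.
#' @export
loop_species <- function(name, rh, lh) {
  structure(list(name = name, rh = .residues(rh, "rna"),
                 lh = .residues(lh, "rna")),
            class = "loop_species")
}

.as_panel <- function(panel) {
  if (is.data.frame(panel)) {
    stopifnot(all(c("name", "rh", "lh") %in% names(panel)))
    panel <- Map(loop_species, panel$name, panel$rh, panel$lh)
  }
  stopifnot(length(panel) >= 1L)
  nms <- vapply(panel, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate species names in panel")
  panel
}

#' Build the directed hand-in-hand pairing graph
#'
#' Node `u` has an edge to node `v` iff `u`'s RH loop forms an active
#' block with `v`'s LH loop under the [predict_activity()] rules.
#' Self-edges model self-complementary species.
#'
#' @param panel list of [loop_species()] or a data.frame with columns
#'   `name`, `rh`, `lh`.
#' @param allow_gu passed to [max_complementary_block()].
#' @return object of class `pairing_graph`: list with `species` and the
#'   boolean `adjacency` matrix (rows = RH donor, cols = LH acceptor).
#' @export
build_pairing_graph <- function(panel, allow_gu = FALSE) {
  panel <- .as_panel(panel)
  nms <- vapply(panel, function(s) s$name, character(1))
  k <- length(panel)
  adj <- matrix(FALSE, k, k, dimnames = list(nms, nms))
  for (u in seq_len(k)) for (v in seq_len(k)) {
    blk <- max_complementary_block(panel[[u]]$rh, panel[[v]]$lh,
                                   allow_gu = allow_gu)
    adj[u, v] <- predict_activity(blk)$active
  }
  structure(list(species = panel, adjacency = adj),
            class = "pairing_graph")
}

#' @export
print.pairing_graph <- function(x, ...) {
  cat("<pairing_graph> ", nrow(x$adjacency), " species, ",
      sum(x$adjacency), " active pairing(s)\n", sep = "")
  print(x$adjacency)
  invisible(x)
}

#' Feasible ring sizes of a pairing graph
#'
#' A ring of `n` subunits is feasible iff a closed directed walk of
#' length `n` exists (species are reusable: an experimental mixture
#' supplies unlimited copies, so one species may occupy alternating
#' positions).  Computed by boolean powers of the adjacency matrix.
#'
#' @param g a [build_pairing_graph()] result.
#' @param max_n largest ring size considered (default 12: the hexamer
#'   plus one harmonic).
#' @return integer vector of feasible sizes.
#' @export
feasible_ring_sizes <- function(g, max_n = 12L) {
  stopifnot(inherits(g, "pairing_graph"), max_n >= 1L)
  A <- g$adjacency * 1L
  P <- A
  sizes <- integer(0)
  for (n in seq_len(max_n)) {
    if (n > 1L) P <- (P %*% A) > 0
    if (any(diag(P * 1) > 0)) sizes <- c(sizes, n)
    P <- P * 1
  }
  sizes
}

#' Ring verdict for a panel of loop species
#'
#' Summarizes the ring-closure combinatorics of a mixture: the feasible
#' ring sizes, the minimal period (shortest directed cycle), and whether
#' a hexamer can close (`6` feasible).
#'
#' @param panel list of [loop_species()] or `name/rh/lh` data.frame.
#' @param max_n largest ring size considered (>= 6 for a meaningful
#'   hexamer verdict; default 12).
#' @param allow_gu passed to the pairing rules.
#' @return object of class `ring_verdict`: list with `feasible_sizes`,
#'   `minimal_cycle` (NA when the graph is acyclic) and `hexamer_active`.
#' @examples
#' panel <- data.frame(name = c("A/i", "I/a"),
#'                     rh = c("AGGA", "UCCU"),
#'                     lh = c("AGGA", "UCCU"))
#' hexamer_verdict(panel)
#' @export
hexamer_verdict <- function(panel, max_n = 12L, allow_gu = FALSE) {
  g <- build_pairing_graph(panel, allow_gu = allow_gu)
  sizes <- feasible_ring_sizes(g, max_n = max_n)
  structure(list(
    feasible_sizes = sizes,
    minimal_cycle = if (length(sizes)) min(sizes) else NA_integer_,
    hexamer_active = 6L %in% sizes,
    graph = g
  ), class = "ring_verdict")
}

#' @export
print.ring_verdict <- function(x, ...) {
  cat("<ring_verdict> feasible sizes: ",
      if (length(x$feasible_sizes)) paste(x$feasible_sizes, collapse = ",")
      else "none",
      "; minimal cycle: ", x$minimal_cycle,
      "; hexamer_active: ", x$hexamer_active, "\n", sep = "")
  invisible(x)
}

#' Smallest ring size feasible for every panel
#'
#' For complementation mixtures with minimal periods 2 and 3 this
#' returns 6, the stoichiometry compatible with both -- the combinatorial
#' support for the hexameric ring.
#'
#' @param panels list of panels (each a list of [loop_species()] or a
#'   `name/rh/lh` data.frame).
#' @param max_n largest ring size considered.
#' @return smallest `n <= max_n` feasible in every panel.
#' @export
smallest_common_ring <- function(panels, max_n = 12L) {
  stopifnot(length(panels) >= 1L)
  common <- seq_len(max_n)
  for (p in panels) {
    sizes <- feasible_ring_sizes(build_pairing_graph(p), max_n = max_n)
    if (!length(sizes)) stop("a panel has no feasible ring size")
    common <- intersect(common, sizes)
  }
  if (!length(common))
    stop("no common ring size <= ", max_n, " across panels")
  min(common)
}
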
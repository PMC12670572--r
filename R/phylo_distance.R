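#' Pairwise distance matrix from an alignment
#'
#' Pairwise-deletion distances in substitutions/site: `"p"` is the raw
#' mismatch proportion over mutually non-gap columns; `"jc69"` is the
#' Jukes-Cantor correction `-(3/4) * log(1 - 4p/3)`, finite only while
#' `p < 3/4` (larger `p` yields `Inf`, or an error in strict mode).
#'
#' @param aln a [feature_alignment()], a named character vector of
#'   aligned sequences, or a list of gap-allowing [seq_record()]s.
#' @param model `"p"` or `"jc69"`.
#' @param deletion `"pairwise"` (default) or `"complete"` (drop every
#'   column containing any gap before comparing).
#' @param strict error on non-finite jc69 entries.
#' @return symmetric numeric matrix with zero diagonal, labelled by row
#'   ids, with attribute `model`.
#' @export
distance_matrix <- function(aln, model = c("p", "jc69"),
                            deletion = c("pairwise", "complete"),
                            strict = FALSE) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  rows <- .aln_rows(aln)
  if (length(rows) < 2L) stop("need at least 2 aligned rows")
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(rows)
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  k <- nrow(mat)
  d <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    nc <- sum(ok)
    if (nc == 0L) stop("rows '", rownames(mat)[i], "' and '",
                       rownames(mat)[j], "' share no compared columns")
    p <- sum(mat[i, ok] != mat[j, ok]) / nc
    v <- if (model == "p") p else {
      if (p >= 0.75) {
        if (strict) stop("jc69 undefined: p-distance ", signif(p, 3),
                         " >= 3/4 for rows '", rownames(mat)[i], "' and '",
                         rownames(mat)[j], "'")
        Inf
      } else -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- v
  }
  attr(d, "model") <- model
  d
}

.aln_rows <- function(aln) {
  if (inherits(aln, "feature_alignment")) {
    setNames(vapply(aln$rows, function(r) r$residues, character(1)),
             vapply(aln$rows, function(r) r$id, character(1)))
  } else if (is.character(aln)) {
    stopifnot(!is.null(names(aln)))
    gsub("T", "U", toupper(aln))
  } else if (is.list(aln)) {
    setNames(vapply(aln, function(r) r$residues, character(1)),
             vapply(aln, function(r) r$id, character(1)))
  } else stop("unsupported alignment input")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining via [ape::nj()].  On an additive matrix the
#' realized patristic distances equal the input exactly.  Negative
#' branch lengths (a known NJ artifact on noisy matrices) are clamped to
#' 0 with a message.
#'
#' @param d symmetric distance matrix (>= 3 taxa) as returned by
#'   [distance_matrix()].
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3L) stop("need >= 3 taxa for NJ")
  if (any(!is.finite(d))) stop("non-finite distances; cannot run NJ")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("nj_tree: clamped ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Patristic distances to a reference leaf
#'
#' Sums branch lengths along the unique tree path from the reference
#' leaf to every other leaf (substitutions/site), the per-node distance
#' report used to compare each pRNA against the phi29 reference.
#'
#' @param tree an [ape::phylo] tree with branch lengths (e.g. from
#'   [nj_tree()] or [read_newick()]).
#' @param reference_leaf leaf name to measure from.
#' @return data.frame with columns `leaf` and `distance`, reference row
#'   first (distance 0), remaining leaves sorted by distance.
#' @export
patristic_report <- function(tree, reference_leaf) {
  stopifnot(inherits(tree, "phylo"))
  if (!reference_leaf %in% tree$tip.label)
    stop("unknown leaf '", reference_leaf, "'")
  dm <- ape::cophenetic.phylo(tree)
  dist <- dm[reference_leaf, ]
  others <- sort(dist[setdiff(names(dist), reference_leaf)])
  data.frame(leaf = c(reference_leaf, names(others)),
             distance = as.numeric(c(0, others)),
             row.names = NULL)
}
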
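#' Annotated feature alignment
#'
#' An alignment (equal-length rows, `-` gaps) together with a
#' [feature_map()] naming column sets such as `Bulge1`, `Bulge3`,
#' `critical_G` or `3WJ`, the substrate of the conservation statistics.
#'
#' @param rows list of gap-allowing [seq_record()]s, or a named character
#'   vector of aligned sequences.
#' @param features a [feature_map()] or plain named list of 0-based
#'   column vectors.
#' @return object of class `feature_alignment`.
#' @export
feature_alignment <- function(rows, features = list()) {
  if (is.character(rows)) {
    stopifnot(!is.null(names(rows)))
    rows <- Map(function(id, s) seq_record(id, s, "rna", allow_gaps = TRUE),
                names(rows), rows)
  }
  stopifnot(length(rows) >= 1L)
  widths <- vapply(rows, function(r) nchar(r$residues), integer(1))
  if (length(unique(widths)) != 1L) stop("ragged alignment rows")
  if (!inherits(features, "feature_map"))
    features <- feature_map(features, alignment_length = widths[1])
  else feature_map(unclass(features), alignment_length = widths[1])
  structure(list(rows = rows, features = features, width = widths[1]),
            class = "feature_alignment")
}

#' @export
print.feature_alignment <- function(x, ...) {
  cat("<feature_alignment> ", length(x$rows), " rows x ", x$width,
      " columns; features: ",
      if (length(x$features)) paste(names(x$features), collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

.feature_cols <- function(a, feature) {
  stopifnot(inherits(a, "feature_alignment"))
  if (!feature %in% names(a$features))
    stop("unknown feature '", feature, "'")
  cols <- a$features[[feature]]
  if (!length(cols)) stop("feature '", feature, "' has an empty column set")
  cols + 1L  # to 1-based
}

.region_strings <- function(a, cols1) {
  vapply(a$rows, function(r) {
    paste(strsplit(r$residues, "")[[1]][cols1], collapse = "")
  }, character(1))
}

#' Existence rate of a feature region
#'
#' Percentage of alignment rows whose feature columns are all occupied
#' (non-gap): the fraction of species in which the structural element
#' exists at all.
#'
#' @param a a [feature_alignment()].
#' @param feature feature name.
#' @return percent in `[0, 100]`.
#' @export
existence_rate <- function(a, feature) {
  cols1 <- .feature_cols(a, feature)
  regs <- .region_strings(a, cols1)
  occupied <- !grepl("-", regs, fixed = TRUE)
  100 * sum(occupied) / length(regs)
}

#' Sequence-similarity rate of a feature region
#'
#' Percentage of occupied rows whose feature-region string equals the
#' region's majority (modal) string, computed over occupied rows only
#' (comparison is case-insensitive with T treated as U; modal ties are
#' broken lexicographically).  When every occupied row is pairwise
#' distinct the rate is 0; a single occupied row scores 100 by
#' convention.
#'
#' @inheritParams existence_rate
#' @return percent in `[0, 100]`.
#' @export
similarity_rate <- function(a, feature) {
  cols1 <- .feature_cols(a, feature)
  regs <- .region_strings(a, cols1)
  regs <- gsub("T", "U", toupper(regs))
  occ <- regs[!grepl("-", regs, fixed = TRUE)]
  if (!length(occ)) return(0)
  if (length(occ) == 1L) return(100)
  tab <- table(occ)
  modal_count <- max(tab)
  if (modal_count == 1L) return(0)  # no two rows share the region string
  100 * modal_count / length(occ)
}

#' Per-feature conservation report
#'
#' One row per annotated feature with its existence and
#' sequence-similarity rates, in the layout of a
#' function-vs-sequence conservation comparison table.
#'
#' @param a a [feature_alignment()] with a non-empty feature map.
#' @return data.frame of class `conservation_report` with columns
#'   `feature`, `existence_rate`, `similarity_rate`, `n_rows`.
#' @export
table1_report <- function(a) {
  stopifnot(inherits(a, "feature_alignment"))
  if (!length(a$features)) stop("feature map is empty")
  out <- data.frame(
    feature = names(a$features),
    existence_rate = vapply(names(a$features),
                            function(f) existence_rate(a, f), numeric(1)),
    similarity_rate = vapply(names(a$features),
                             function(f) similarity_rate(a, f), numeric(1)),
    n_rows = length(a$rows),
    row.names = NULL)
  class(out) <- c("conservation_report", "data.frame")
  out
}

#' Write a conservation report as TSV
#' @param report a [table1_report()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
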
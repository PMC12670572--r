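#' Exact local protein alignment
#'
#' Optimal Smith-Waterman local alignment with affine gaps, computed by
#' [Biostrings::pairwiseAlignment()].  Defaults reproduce the standard
#' protein-search parameterization: BLOSUM62 with gap existence 11 and
#' extension 1.  A best local score <= 0 yields the empty alignment
#' (score 0).
#'
#' @param query,subject protein [seq_record()]s or plain strings.
#' @param matrix substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `local_alignment`: list with `query_id`,
#'   `subject_id`, `score`, 0-based half-open spans `qs,qe,ss,se`, and
#'   gapped `aligned_query` / `aligned_subject` strings.
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  qid <- if (inherits(query, "seq_record")) query$id else "query"
  sid <- if (inherits(subject, "seq_record")) subject$id else "subject"
  q <- .residues(query, "protein")
  s <- .residues(subject, "protein")
  for (x in c(q, s)) {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", x))
      stop("non-protein character in sequence")
  }
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(s),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query_id = qid, subject_id = sid, score = 0,
                          qs = 0L, qe = 0L, ss = 0L, se = 0L,
                          aligned_query = "", aligned_subject = ""),
                     class = "local_alignment"))
  }
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  structure(list(
    query_id = qid, subject_id = sid, score = sc,
    qs = Biostrings::start(pat) - 1L, qe = Biostrings::end(pat),
    ss = Biostrings::start(sub) - 1L, se = Biostrings::end(sub),
    aligned_query = as.character(pat),
    aligned_subject = as.character(sub)
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> %s vs %s, score %.1f\n", x$query_id,
              x$subject_id, x$score))
  if (nzchar(x$aligned_query)) {
    cat(sprintf("  query   [%d,%d): %s\n", x$qs, x$qe, x$aligned_query))
    cat(sprintf("  subject [%d,%d): %s\n", x$ss, x$se, x$aligned_subject))
  } else cat("  (empty alignment)\n")
  invisible(x)
}

#' Query coverage of a local alignment
#'
#' Percentage of the query included in the aligned span.
#'
#' @param a a [local_align()] result.
#' @param query_len full query length.
#' @return percent in `[0, 100]`.
#' @export
query_coverage <- function(a, query_len) {
  stopifnot(inherits(a, "local_alignment"), a$qe <= query_len)
  100 * (a$qe - a$qs) / query_len
}

#' Percent identity of a local alignment
#'
#' Identical aligned columns over all alignment columns; gap columns
#' count in the denominator.  With `denominator = "reference"` the
#' divisor is `reference_len` instead (the alternative reading of
#' "divided by the total number of amino acids").
#'
#' @param a a [local_align()] result.
#' @param denominator `"alignment"` (default) or `"reference"`.
#' @param reference_len required when `denominator = "reference"`.
#' @return percent in `[0, 100]`; the empty alignment returns 0 with a
#'   warning.
#' @export
percent_identity <- function(a, denominator = c("alignment", "reference"),
                             reference_len = NULL) {
  stopifnot(inherits(a, "local_alignment"))
  denominator <- match.arg(denominator)
  if (!nzchar(a$aligned_query)) {
    warning("empty alignment; percent identity is 0")
    return(0)
  }
  qa <- strsplit(a$aligned_query, "")[[1]]
  sa <- strsplit(a$aligned_subject, "")[[1]]
  ident <- sum(qa == sa & qa != "-")
  den <- if (denominator == "alignment") length(qa) else {
    stopifnot(!is.null(reference_len))
    reference_len
  }
  100 * ident / den
}

#' Motor-component co-occurrence check
#'
#' Confirms that a genome's protein set contains homologs of the two
#' other packaging-motor components -- the connector/channel protein
#' (gp10) and the packaging ATPase (gp16) -- by exact local alignment of
#' each reference against every supplied CDS translation.  A genome
#' passes when the best hit for every reference meets both the coverage
#' and the identity thresholds.
#'
#' @param genome_cds list of protein [seq_record()]s (CDS translations).
#' @param references list of protein [seq_record()]s (e.g. gp10, gp16).
#' @param min_coverage,min_identity pass thresholds in percent
#'   (defaults 50 and 25).
#' @param identity_denominator `"alignment"` or `"reference"`.
#' @param ... passed to [local_align()].
#' @return object of class `motor_check_report`: list with `hits` (one
#'   row per reference: best subject, score, query_coverage,
#'   percent_identity, pass) and overall `pass`.
#' @export
motor_component_check <- function(genome_cds, references,
                                  min_coverage = 50, min_identity = 25,
                                  identity_denominator = c("alignment",
                                                           "reference"),
                                  ...) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(length(references) >= 1L)
  rows <- list()
  for (ref in references) {
    best <- NULL
    for (cds in genome_cds) {
      al <- local_align(ref, cds, ...)
      if (is.null(best) || al$score > best$score) best <- al
    }
    if (is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref$id, subject = NA_character_, score = 0,
        query_coverage = 0, percent_identity = 0, pass = FALSE)
      next
    }
    cov <- query_coverage(best, nchar(ref$residues))
    idn <- if (best$score > 0) {
      percent_identity(best, identity_denominator,
                       reference_len = nchar(ref$residues))
    } else 0
    rows[[length(rows) + 1L]] <- data.frame(
      reference = ref$id, subject = best$subject_id, score = best$score,
      query_coverage = cov, percent_identity = idn,
      pass = cov >= min_coverage && idn >= min_identity)
  }
  hits <- do.call(rbind, rows)
  structure(list(hits = hits, pass = all(hits$pass)),
            class = "motor_check_report")
}

#' @export
print.motor_check_report <- function(x, ...) {
  cat("<motor_check_report> pass =", x$pass, "\n")
  print(x$hits)
  invisible(x)
}
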
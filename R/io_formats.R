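#' Sequence record
#'
#' A minimal container for one sequence: an identifier, the residues, and
#' the molecule type.  RNA residues are canonicalized to uppercase AUCG
#' (T is converted to U on read and the conversion reported via a
#' message); protein residues use the 20 standard amino-acid letters.
#'
#' @param id single character identifier.
#' @param residues character scalar of residues (no gaps unless
#'   `allow_gaps = TRUE`).
#' @param moltype `"rna"` or `"protein"`.
#' @param allow_gaps permit `"-"` gap characters (aligned rows).
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `residues`, `moltype`.
#' @export
seq_record <- function(id, residues, moltype = c("rna", "protein"),
                       allow_gaps = FALSE) {
  moltype <- match.arg(moltype)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (moltype == "rna" && grepl("T", residues, fixed = TRUE)) {
    residues <- gsub("T", "U", residues, fixed = TRUE)
    message("seq_record: converted T -> U in '", id, "'")
  }
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  alpha <- if (moltype == "rna") "ACGU" else "ACDEFGHIKLMNPQRSTVWY"
  if (allow_gaps) alpha <- paste0(alpha, "-")
  bad <- regmatches(residues, regexpr(sprintf("[^%s]", alpha), residues))
  if (length(bad) && nzchar(bad)) {
    stop("illegal character '", bad, "' in record '", id, "' (", moltype,
         " alphabet", if (allow_gaps) " + gaps", ")")
  }
  structure(list(id = id, residues = residues, moltype = moltype),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<seq_record %s> %s (%d %s residues)\n", x$moltype, x$id,
              nchar(x$residues), x$moltype))
  cat(" ", res, "\n")
  invisible(x)
}

# Accept a seq_record or a plain string; return the residue string.
# RNA use sites canonicalize T -> U; protein use sites only upper-case.
.residues <- function(x, moltype = c("rna", "protein")) {
  moltype <- match.arg(moltype)
  s <- if (inherits(x, "seq_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a seq_record or a single character string")
  if (moltype == "rna") s <- gsub("T", "U", s)
  s
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A<->U, G<->C) read 3' to 5'.
#' @param x RNA string or `seq_record`.
#' @return character scalar.
#' @export
rna_revcomp <- function(x) {
  s <- .residues(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
}

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Read a FASTA file
#'
#' Parses FASTA via [Biostrings::readBStringSet()] and validates every
#' record against the declared alphabet.  For RNA, T is converted to U
#' (reported via a message).  Gaps are rejected unless
#' `allow_gaps = TRUE` (aligned input).  Errors name the offending line.
#'
#' @param path FASTA file.
#' @param moltype `"rna"` or `"protein"`.
#' @param allow_gaps permit `"-"` in sequences.
#' @return list of [seq_record()] objects, input order preserved.
#' @export
read_fasta <- function(path, moltype = c("rna", "protein"),
                       allow_gaps = FALSE) {
  moltype <- match.arg(moltype)
  lines <- .read_lines_checked(path)
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at)) stop("not a FASTA file (no '>' header): ", path)
  if (hdr_at[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr_at[1] - 1)]))))
    stop("malformed FASTA: sequence before first header at line 1 in ", path)
  ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr_at])
  if (any(!nzchar(ids))) {
    stop("malformed header at line ", hdr_at[which(!nzchar(ids))[1]],
         " in ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate FASTA id '", dup, "' at line ",
         hdr_at[which(ids == dup)[2]], " in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  recs <- vector("list", length(set))
  for (k in seq_along(set)) {
    res <- as.character(set[[k]])
    rec <- tryCatch(
      seq_record(ids[k], res, moltype, allow_gaps = allow_gaps),
      error = function(e) {
        stop("record starting at line ", hdr_at[k], " in ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
    recs[[k]] <- rec
  }
  recs
}

#' Write sequence records to FASTA
#' @param records list of [seq_record()] (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    records <- Map(function(id, s) list(id = id, residues = s),
                   names(records), records)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Feature map: named alignment column sets
#'
#' Associates feature names (e.g. `Bulge1`, `critical_G`, `3WJ`) with
#' sets of 0-based alignment column indices.
#'
#' @param features named list of integer vectors (0-based columns).
#' @param alignment_length if given, columns are checked against it.
#' @return object of class `feature_map` (the validated named list).
#' @export
feature_map <- function(features, alignment_length = NULL) {
  stopifnot(is.list(features))
  if (length(features)) {
    stopifnot(!is.null(names(features)), all(nzchar(names(features))))
    if (anyDuplicated(names(features))) stop("duplicate feature names")
    features <- lapply(features, function(v) sort(unique(as.integer(v))))
    for (nm in names(features)) {
      v <- features[[nm]]
      if (length(v) && any(v < 0L)) stop("negative column in feature ", nm)
      if (!is.null(alignment_length) && length(v) &&
          any(v >= alignment_length)) {
        stop("feature '", nm, "' has column >= alignment length ",
             alignment_length)
      }
    }
  }
  structure(features, class = "feature_map")
}

# Sidecar TSV: two columns, feature name and comma-separated 0-based
# column indices.
read_feature_map <- function(path, alignment_length = NULL) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  feats <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("feature map line not 2 TSV fields: ", ln)
    cols <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    if (anyNA(cols)) stop("non-integer column in feature map line: ", ln)
    feats[[parts[1]]] <- cols
  }
  feature_map(feats, alignment_length)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or (read-only) plain Stockholm.  All rows must
#' be equal length; `-` is the gap character (`.` in Stockholm is mapped
#' to `-`).  An optional sidecar TSV maps feature names to comma-separated
#' 0-based column indices.
#'
#' @param path alignment file (aligned FASTA, or Stockholm starting with
#'   `# STOCKHOLM`).
#' @param feature_path optional feature-map TSV.
#' @param moltype `"rna"` or `"protein"`.
#' @return list with `rows` (list of gap-allowing [seq_record()]) and
#'   `features` (a [feature_map()], empty when no sidecar is given).
#' @export
read_alignment <- function(path, feature_path = NULL,
                           moltype = c("rna", "protein")) {
  moltype <- match.arg(moltype)
  lines <- .read_lines_checked(path)
  if (length(lines) && grepl("^# STOCKHOLM", lines[1])) {
    rows <- .read_stockholm(lines, moltype)
  } else {
    rows <- read_fasta(path, moltype, allow_gaps = TRUE)
  }
  if (!length(rows)) stop("alignment has no rows: ", path)
  widths <- vapply(rows, function(r) nchar(r$residues), integer(1))
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(widths),
                                                 collapse = ", "))
  }
  feats <- if (is.null(feature_path)) feature_map(list()) else
    read_feature_map(feature_path, alignment_length = widths[1])
  list(rows = rows, features = feats)
}

# Minimal Stockholm reader: sequence lines "name seq", '#' annotations
# and '//' ignored; interleaved blocks concatenated.
.read_stockholm <- function(lines, moltype) {
  seqs <- list()
  for (ln in lines[-1]) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
    nm <- parts[1]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]],
                         gsub(".", "-", parts[2], fixed = TRUE))
  }
  if (!length(seqs)) stop("Stockholm input has no sequence lines")
  unname(Map(function(id, s) seq_record(id, s, moltype, allow_gaps = TRUE),
             names(seqs), seqs))
}

#' Read Vienna dot-bracket records
#'
#' Three-line records: `>header`, sequence, structure over `.()`
#' characters.  The structure must match the sequence length and have
#' balanced parentheses; the first violating position is reported.
#'
#' @param path Vienna-format file.
#' @return list of `list(record = seq_record, dotbracket = string)`.
#' @export
read_dotbracket <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("Vienna file must be triples of header/sequence/structure: ", path)
  out <- list()
  for (k in seq(1L, length(lines), by = 3L)) {
    if (!startsWith(lines[k], ">"))
      stop("expected '>' header at record ", (k + 2) %/% 3, " in ", path)
    id <- sub("^>\\s*(\\S*).*$", "\\1", lines[k])
    seq <- toupper(trimws(lines[k + 1]))
    db <- trimws(lines[k + 2])
    if (nchar(db) != nchar(seq)) {
      stop("structure length ", nchar(db), " != sequence length ",
           nchar(seq), " for record '", id, "'")
    }
    if (grepl("[^.()]", db))
      stop("illegal structure character for record '", id, "'")
    .check_balanced(db, id)
    rec <- seq_record(id, seq, "rna")
    out[[length(out) + 1L]] <- list(record = rec, dotbracket = db)
  }
  out
}

.check_balanced <- function(db, id) {
  depth <- 0L
  chars <- strsplit(db, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, " in structure of '", id, "'")
    }
  }
  if (depth > 0L) {
    opens <- which(chars == "(")
    stop("unbalanced '(' at position ", opens[length(opens) - depth + 1L],
         " in structure of '", id, "'")
  }
  invisible(TRUE)
}

#' Write Vienna dot-bracket records
#' @param structures list of `secondary_structure` objects, or list of
#'   `list(record=, dotbracket=)` as returned by [read_dotbracket()].
#' @param path output file.
#' @param ids optional ids when `structures` are `secondary_structure`s.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path, ids = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(structures)) {
    x <- structures[[k]]
    if (inherits(x, "secondary_structure")) {
      id <- if (!is.null(ids)) ids[k] else paste0("structure_", k)
      writeLines(c(paste0(">", id), x$seq, x$dotbracket), con)
    } else {
      writeLines(c(paste0(">", x$record$id), x$record$residues,
                   x$dotbracket), con)
    }
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()].  Missing branch lengths default
#' to 0 with a warning; malformed input raises an error.
#'
#' @param path Newick file (or a literal Newick string ending in `;`).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch({
    if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
    else ape::read.tree(path)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick input: ", path)
  if (is.null(tr$edge.length)) {
    warning("Newick tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("Newick tree has unnamed leaves")
  tr
}
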
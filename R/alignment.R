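# Protein multiple sequence alignments: import (aligned FASTA, Stockholm) and
# reference-coordinate slicing used to split the superfold alignment into the
# three domain alignments.

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gap character `-`; `.` is normalized to `-`).
#' @return Object of class `aa_alignment` (named character vector).
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stopf("alignment rows must be named")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  if (length(unique(nchar(seqs))) != 1)
    stopf("alignment rows differ in length")
  if (anyDuplicated(names(seqs)))
    stopf("duplicate row ids in alignment")
  structure(seqs, class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("protein alignment: %d rows x %d columns\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

#' Read a protein multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm (sequence lines only; `#=` annotation
#' lines are ignored).
#'
#' @param path Input file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(as_alignment(seqs))
  }
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stopf("not a Stockholm file: %s", path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  ids <- sub("\\s.*$", "", lines)
  seq <- sub("^\\S+\\s+", "", lines)
  agg <- vapply(split(seq, factor(ids, levels = unique(ids))),
                paste0, character(1), collapse = "")
  as_alignment(agg)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(unclass(aln), path)
}

#' Slice alignment columns by reference residue coordinates
#'
#' Returns the columns spanning the reference sequence's ungapped residues
#' `start_res..end_res` (1-based inclusive, the paper-style residue numbering
#' of the named reference row). Columns where the reference carries a gap
#' between those residues are included; row order is preserved.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Row id of the reference sequence.
#' @param start_res,end_res 1-based inclusive residue positions on the
#'   ungapped reference.
#' @return An `aa_alignment` over the selected columns.
#' @export
slice_alignment_by_reference <- function(aln, reference_id, start_res, end_res) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!reference_id %in% names(aln))
    stopf("reference '%s' not found in alignment", reference_id)
  if (start_res > end_res) stopf("start_res must be <= end_res")
  ref <- strsplit(aln[[reference_id]], "")[[1]]
  is_res <- ref != "-"
  res_index <- cumsum(is_res)
  n_res <- res_index[length(res_index)]
  if (end_res > n_res)
    stopf("reference has only %d residues (requested %d)", n_res, end_res)
  col_start <- which(is_res & res_index == start_res)
  col_end <- which(is_res & res_index == end_res)
  out <- substring(unclass(aln), col_start, col_end)
  names(out) <- names(aln)
  as_alignment(out)
}
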
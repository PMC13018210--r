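# Sequence input/output, six-frame conceptual translation with stop-splitting,
# and exact peptide <-> genome coordinate maps.
#
# Conventions: all internal coordinates are 0-based half-open; user-facing
# tables and GFF3 emitted elsewhere are 1-based inclusive. Reverse-strand
# intervals are always reported on the forward strand with strand = "-".

#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA via Biostrings and validates records.
#' Lowercase is uppercased; for nucleotide input `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` (alphabet `A,C,G,T,N` after normalization) or `"AA"`.
#' @return Named character vector of sequences (names are record ids, order as
#'   in the file).
#' @details Duplicate ids, empty sequences, and characters outside the stated
#'   alphabet are errors; the error names the offending record.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stopf("empty sequence for record '%s'", ids[which(!nzchar(seqs))[1]])
  if (type == "DNA") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- grepl("[^ACGTN]", seqs)
  } else {
    bad <- grepl("[^ABCDEFGHIKLMNPQRSTUVWXYZ*\\-\\.]", seqs)
  }
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr(
      if (type == "DNA") "[^ACGTN]" else "[^ABCDEFGHIKLMNPQRSTUVWXYZ*\\-\\.]",
      seqs[i]))
    stopf("illegal character '%s' in record '%s'", ch, ids[i])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wb")  # binary mode: byte-stable newlines
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a genome metadata table
#'
#' Tab-separated table with columns `genome_id`, `species`, `taxon_group`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_genome_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "taxon_group")
  if (!all(need %in% names(md)))
    stopf("metadata must contain columns: %s", paste(need, collapse = ", "))
  md
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Character scalar over `A,C,G,T,N`.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

resolve_genetic_code <- function(table) {
  table <- as.character(table)
  if (table %in% c("standard", "Standard", "1"))
    return(Biostrings::GENETIC_CODE)
  if (table %in% c("bacterial", "Bacterial", "11"))
    return(Biostrings::getGeneticCode("11"))
  stopf("unsupported genetic code table '%s' (use 'standard' or '11')", table)
}

translate_frame <- function(dna, offset, code) {
  L <- length(dna)
  usable <- L - offset
  n_codon <- usable %/% 3
  if (n_codon < 1) return("")
  sub <- Biostrings::subseq(dna, start = offset + 1,
                            width = n_codon * 3)
  as.character(Biostrings::translate(sub, genetic.code = code,
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

split_stops <- function(pep, min_segment_len) {
  if (!nzchar(pep)) {
    return(data.frame(peptide = character(), pep_offset = integer()))
  }
  parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  # offset of each part within the full-frame translation (stops occupy 1 aa)
  offs <- cumsum(c(0L, utils::head(lens, -1) + 1L))
  keep <- lens >= min_segment_len
  data.frame(peptide = parts[keep], pep_offset = offs[keep],
             stringsAsFactors = FALSE)
}

#' Six-frame conceptual translation with stop-splitting
#'
#' Translates a genome record in all six frames: `+1,+2,+3` read the forward
#' strand at offsets 0,1,2 and `-1,-2,-3` read the reverse complement at
#' offsets 0,1,2. Trailing partial codons are dropped; codons containing `N`
#' translate to `X`. Each full-frame translation is split at stop codons into
#' peptide segments, discarding segments shorter than `min_segment_len`.
#'
#' @param genome Character scalar, nucleotide sequence over `A,C,G,T,N`.
#' @param id Genome/record id carried through to downstream hit tables.
#' @param table Genetic code: `"standard"` (default, the transeq default) or
#'   `"11"` (bacterial).
#' @param min_segment_len Minimum retained segment length in amino acids
#'   (default 30).
#' @return An object of class `six_frame`: list with `genome_id`, `length`,
#'   `min_segment_len`, and `frames`, a named list over
#'   `"+1","+2","+3","-1","-2","-3"` each holding a data.frame with columns
#'   `peptide` and `pep_offset` (0-based offset of the segment within the
#'   full-frame translation).
#' @export
six_frame_translate <- function(genome, id = "genome", table = "standard",
                                min_segment_len = 30) {
  code <- resolve_genetic_code(table)
  genome <- toupper(genome)
  if (nchar(genome) < 1) stopf("empty genome sequence for '%s'", id)
  fwd <- Biostrings::DNAString(genome)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- list()
  for (off in 0:2) {
    frames[[sprintf("+%d", off + 1)]] <-
      split_stops(translate_frame(fwd, off, code), min_segment_len)
    frames[[sprintf("-%d", off + 1)]] <-
      split_stops(translate_frame(rev, off, code), min_segment_len)
  }
  frames <- frames[c("+1", "+2", "+3", "-1", "-2", "-3")]
  structure(list(genome_id = id, length = nchar(genome),
                 table = table, min_segment_len = min_segment_len,
                 frames = frames),
            class = "six_frame")
}

#' @export
print.six_frame <- function(x, ...) {
  nseg <- vapply(x$frames, nrow, integer(1))
  cat(sprintf("six-frame translation of '%s' (%d nt, code %s)\n",
              x$genome_id, x$length, x$table))
  cat(sprintf("  segments >= %d aa per frame: %s\n", x$min_segment_len,
              paste(sprintf("%s:%d", names(nseg), nseg), collapse = " ")))
  invisible(x)
}

#' Map a peptide slice back to genomic coordinates
#'
#' Given a frame and a slice of one of its stop-free peptide segments, returns
#' the exact genomic interval encoding that slice. Reverse-frame slices are
#' reported on the forward strand with `strand = "-"`. Re-translating the
#' returned interval in the stated frame reproduces the peptide slice.
#'
#' @param sf A `six_frame` object.
#' @param frame Frame label, one of `"+1".."+3"`, `"-1".."-3"` (or the
#'   integers 1:3, -1:-3).
#' @param segment Segment index within that frame (1-based row of the frame's
#'   segment table).
#' @param pep_start,pep_end 0-based half-open slice of the segment's peptide.
#' @return List with `start`, `end` (0-based half-open genomic interval on the
#'   forward strand) and `strand` (`"+"` or `"-"`).
#' @export
map_to_genome <- function(sf, frame, segment, pep_start, pep_end) {
  stopifnot(inherits(sf, "six_frame"))
  frame <- frame_label(frame)
  seg <- sf$frames[[frame]]
  if (is.null(seg) || segment < 1 || segment > nrow(seg))
    stopf("no segment %s in frame %s", segment, frame)
  plen <- nchar(seg$peptide[segment])
  pep_start <- as.integer(pep_start); pep_end <- as.integer(pep_end)
  if (pep_start < 0 || pep_end <= pep_start || pep_end > plen)
    stopf("peptide slice [%d,%d) out of range for segment of length %d",
          pep_start, pep_end, plen)
  off <- as.integer(substr(frame, 2, 2)) - 1L   # frame offset 0..2
  p0 <- as.integer(seg$pep_offset[segment])
  s_strand <- p0 + pep_start
  e_strand <- p0 + pep_end
  g_start <- off + 3L * s_strand
  g_end <- off + 3L * e_strand
  if (startsWith(frame, "+")) {
    list(start = g_start, end = g_end, strand = "+")
  } else {
    L <- sf$length
    list(start = L - g_end, end = L - g_start, strand = "-")
  }
}

frame_label <- function(frame) {
  if (is.numeric(frame)) {
    frame <- ifelse(frame > 0, sprintf("+%d", frame), sprintf("%d", frame))
  }
  frame <- as.character(frame)
  if (!frame %in% c("+1", "+2", "+3", "-1", "-2", "-3"))
    stopf("invalid frame '%s'", frame)
  frame
}
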
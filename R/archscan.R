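# Domain-hit calling on translated frames, the three-domain architecture
# filter (same reading frame, correct order, bounded gaps), downstream ORF
# detection, and prevalence/copy-number summaries.

#' Scan translated frames with an HMM library
#'
#' Scores every stop-free peptide segment of every frame against every model
#' in the library and retains hits with `E <= E_max` and model coverage
#' `>= min_model_cov` (fraction of the model's match states spanned by the
#' optimal alignment, the model-side reading of a minimum domain overlap).
#' E-values use each model's Gumbel calibration with
#' `n_targets =` total number of segments scanned in this call.
#'
#' A conservative ungapped prefilter (default 25 bits) skips full Viterbi
#' alignment of segments that cannot approach significance; set
#' `filter_bits = -Inf` to score every segment exhaustively.
#'
#' @param lib An [hmm_library()] whose models are all calibrated.
#' @param frames A `six_frame` object or a list of them (one per genome
#'   record).
#' @param E_max E-value threshold (default `1e-10`).
#' @param min_model_cov Minimum model-coverage fraction (default 0.30).
#' @param filter_bits Ungapped prefilter threshold in bits.
#' @return A data.frame of domain hits with 1-based inclusive user-facing
#'   coordinates: `genome_id, model, frame, segment, pep_start, pep_end,
#'   gstart, gend, strand, score, evalue, model_cov, k_start, k_end`,
#'   ordered by genome, genomic start, model. The total segment count used
#'   for the E-value correction is attached as attribute `n_targets`.
#' @export
scan_frames <- function(lib, frames, E_max = 1e-10, min_model_cov = 0.30,
                        filter_bits = 25) {
  stopifnot(inherits(lib, "hmm_library"))
  for (m in lib$models) {
    if (is.null(m$calibration))
      stopf("model '%s' is not calibrated; run calibrate_hmm() first", m$name)
  }
  if (inherits(frames, "six_frame")) frames <- list(frames)
  # flatten all segments across genomes and frames
  idx <- do.call(rbind, lapply(seq_along(frames), function(gi) {
    sf <- frames[[gi]]
    do.call(rbind, lapply(names(sf$frames), function(fr) {
      n <- nrow(sf$frames[[fr]])
      if (n == 0) return(NULL)
      data.frame(gi = gi, frame = fr, segment = seq_len(n),
                 stringsAsFactors = FALSE)
    }))
  }))
  empty <- data.frame(genome_id = character(), model = character(),
                      frame = character(), segment = integer(),
                      pep_start = integer(), pep_end = integer(),
                      gstart = integer(), gend = integer(),
                      strand = character(), score = numeric(),
                      evalue = numeric(), model_cov = numeric(),
                      k_start = integer(), k_end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(idx) || nrow(idx) == 0) {
    attr(empty, "n_targets") <- 0L
    return(empty)
  }
  peptides <- mapply(function(gi, fr, sg) frames[[gi]]$frames[[fr]]$peptide[sg],
                     idx$gi, idx$frame, idx$segment)
  n_targets <- length(peptides)
  model_forms <- lapply(lib$models, hmm_scan_form)
  raw <- cpp_scan(peptides, unname(model_forms), filter_bits)
  if (nrow(raw) == 0) {
    attr(empty, "n_targets") <- n_targets
    return(empty)
  }
  model_names <- names(lib$models)
  rows <- lapply(seq_len(nrow(raw)), function(r) {
    seg_row <- idx[raw$seg[r], ]
    hmm <- lib$models[[raw$model[r]]]
    E <- evalue(hmm, raw$score[r], n_targets)
    cov <- (raw$k_end[r] - raw$k_start[r] + 1) / hmm$M
    if (E > E_max || cov < min_model_cov) return(NULL)
    sf <- frames[[seg_row$gi]]
    g <- map_to_genome(sf, seg_row$frame, seg_row$segment,
                       raw$env_start[r], raw$env_end[r])
    data.frame(genome_id = sf$genome_id,
               model = model_names[raw$model[r]],
               frame = seg_row$frame, segment = seg_row$segment,
               pep_start = raw$env_start[r] + 1L, pep_end = raw$env_end[r],
               gstart = g$start + 1L, gend = g$end,
               strand = g$strand, score = raw$score[r], evalue = E,
               model_cov = cov, k_start = raw$k_start[r],
               k_end = raw$k_end[r], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    attr(empty, "n_targets") <- n_targets
    return(empty)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$genome_id, hits$gstart, hits$model), ]
  rownames(hits) <- NULL
  attr(hits, "n_targets") <- n_targets
  hits
}

#' Assemble domain hits into TLP loci with the architecture filter
#'
#' Within each (genome, frame, stop-free segment), scans hits N-to-C for
#' triples matching the expected architecture order with inter-envelope gaps
#' at most `max_gap` amino acids and pairwise envelope overlap at most
#' `max_env_overlap` of the shorter envelope. Overlapping candidate triples
#' are resolved greedily by highest combined bit score (ties: leftmost
#' genomic start); accepted loci never share a domain hit or genomic span.
#' Loci are numbered per genome by genomic start (`copy_index`).
#'
#' @param hits Hit table from [scan_frames()].
#' @param order Expected N-to-C model order (default FN-plug, NHL, YD-shell).
#' @param max_gap Maximum inter-envelope gap in amino acids (default 300).
#' @param max_env_overlap Maximum allowed pairwise envelope overlap fraction
#'   (default 0.5).
#' @return Data.frame of loci: `genome_id, copy_index, strand, frame, segment,
#'   gstart, gend, combined_score` plus per-domain genomic intervals in
#'   columns `d1_gstart, d1_gend, d2_gstart, d2_gend, d3_gstart, d3_gend`
#'   (domains in architecture order). Empty input gives an empty table.
#' @export
call_architecture <- function(hits, order = c("FN-plug", "NHL", "YD-shell"),
                              max_gap = 300, max_env_overlap = 0.5) {
  out_cols <- c("genome_id", "copy_index", "strand", "frame", "segment",
                "gstart", "gend", "combined_score",
                "d1_gstart", "d1_gend", "d2_gstart", "d2_gend",
                "d3_gstart", "d3_gend")
  empty <- as.data.frame(setNames(
    list(character(), integer(), character(), character(), integer(),
         integer(), integer(), numeric(), integer(), integer(), integer(),
         integer(), integer(), integer()), out_cols),
    stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  stopifnot(length(order) == 3)
  cands <- list()
  groups <- split(hits, list(hits$genome_id, hits$frame, hits$segment),
                  drop = TRUE)
  for (g in groups) {
    g <- g[order(g$pep_start, g$pep_end), ]
    i1 <- which(g$model == order[1])
    i2 <- which(g$model == order[2])
    i3 <- which(g$model == order[3])
    for (a in i1) for (b in i2) for (cc in i3) {
      trio <- g[c(a, b, cc), ]
      ok <- TRUE
      for (p in 1:2) {
        gap <- trio$pep_start[p + 1] - 1L - trio$pep_end[p]
        if (trio$pep_start[p + 1] <= trio$pep_start[p]) { ok <- FALSE; break }
        if (gap > max_gap) { ok <- FALSE; break }
        ov <- min(trio$pep_end[p], trio$pep_end[p + 1]) -
          max(trio$pep_start[p], trio$pep_start[p + 1]) + 1L
        shorter <- min(trio$pep_end[p] - trio$pep_start[p] + 1L,
                       trio$pep_end[p + 1] - trio$pep_start[p + 1] + 1L)
        if (ov > max_env_overlap * shorter) { ok <- FALSE; break }
      }
      if (!ok) next
      cands[[length(cands) + 1]] <- data.frame(
        genome_id = trio$genome_id[1], strand = trio$strand[1],
        frame = trio$frame[1], segment = trio$segment[1],
        gstart = min(trio$gstart), gend = max(trio$gend),
        combined_score = sum(trio$score),
        d1_gstart = trio$gstart[1], d1_gend = trio$gend[1],
        d2_gstart = trio$gstart[2], d2_gend = trio$gend[2],
        d3_gstart = trio$gstart[3], d3_gend = trio$gend[3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$combined_score, cand$genome_id, cand$gstart), ]
  accepted <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    clash <- accepted$genome_id == row$genome_id &
      accepted$gstart <= row$gend & row$gstart <= accepted$gend
    if (!any(clash)) accepted <- rbind(accepted, row)
  }
  accepted <- accepted[order(accepted$genome_id, accepted$gstart), ]
  accepted$copy_index <- stats::ave(seq_len(nrow(accepted)),
                                    accepted$genome_id, FUN = seq_along)
  rownames(accepted) <- NULL
  accepted[, out_cols]
}

#' Find candidate downstream open reading frames
#'
#' Naive ORF detection (`ATG ... stop`, same strand as the locus, 5'->3'
#' downstream of the locus 3' end, start within `window` nucleotides), the
#' signature of a candidate immunity gene encoded immediately downstream of a
#' toxin locus. ORFs are reported sorted by proximity to the locus.
#'
#' @param locus One row of the [call_architecture()] table (or any list with
#'   `gstart`, `gend` 1-based inclusive and `strand`).
#' @param genome Nucleotide sequence of the locus's genome record.
#' @param window Search window downstream of the locus 3' end (default 5000).
#' @param min_orf Minimum ORF length in nucleotides, ATG through stop
#'   inclusive (default 150).
#' @param table Genetic code for stop definitions (default `"standard"`).
#' @return Data.frame `start, end, strand, length` (1-based inclusive forward
#'   -strand coordinates), ordered by distance from the locus.
#' @export
find_downstream_orf <- function(locus, genome, window = 5000, min_orf = 150,
                                table = "standard") {
  L <- nchar(genome)
  if (locus$gstart < 1 || locus$gend > L) stopf("locus out of genome bounds")
  code <- resolve_genetic_code(table)
  stops <- names(code)[code == "*"]
  if (locus$strand == "+") {
    from <- locus$gend + 1L
    sub <- substr(genome, from, min(L, locus$gend + window + 3L * 2000L))
  } else {
    to <- locus$gstart - 1L
    sub <- substr(genome, max(1L, locus$gstart - window - 3L * 2000L), to)
    sub <- reverse_complement(sub)
    from <- 1L  # coordinates mapped back below
  }
  orfs <- scan_orfs(sub, stops, min_orf, window)
  if (nrow(orfs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer()))
  }
  if (locus$strand == "+") {
    out <- data.frame(start = as.integer(locus$gend + orfs$start),
                      end = as.integer(locus$gend + orfs$end),
                      strand = "+", length = as.integer(orfs$len))
  } else {
    # orfs$start is 1-based on the reverse-complemented downstream window
    base <- locus$gstart  # first nt downstream (reverse strand) is gstart-1
    out <- data.frame(start = as.integer(base - orfs$end),
                      end = as.integer(base - orfs$start),
                      strand = "-", length = as.integer(orfs$len))
  }
  out[order(orfs$start), , drop = FALSE]
}

# ORFs on the forward strand of `sub`, ATG..stop in-frame, ATG within
# `window` of position 1. Returns 1-based start/end inclusive of the stop.
scan_orfs <- function(sub, stops, min_orf, window) {
  n <- nchar(sub)
  out <- data.frame(start = integer(), end = integer(), len = integer())
  if (n < 6) return(out)
  atg <- gregexpr("ATG", sub, fixed = TRUE)[[1]]
  if (atg[1] == -1) return(out)
  atg <- atg[atg <= window]
  used_frame_pos <- character(0)
  for (s in atg) {
    # skip ATGs nested in-frame inside an already-reported ORF
    codon_starts <- seq(s, n - 2, by = 3)
    codons <- substring(sub, codon_starts, codon_starts + 2)
    stop_i <- which(codons %in% stops)[1]
    if (is.na(stop_i)) next
    e <- codon_starts[stop_i] + 2L
    len <- e - s + 1L
    if (len < min_orf) next
    key <- paste(e, s %% 3)
    if (key %in% used_frame_pos) next  # same stop, downstream ATG: keep first
    used_frame_pos <- c(used_frame_pos, key)
    out <- rbind(out, data.frame(start = s, end = e, len = len))
  }
  out
}

#' Summarize TLP prevalence and copy number by taxon group
#'
#' @param loci Locus table from [call_architecture()] (may be empty).
#' @param metadata Data.frame with columns `genome_id`, `species`,
#'   `taxon_group` covering all screened genomes.
#' @return List of class `prevalence_summary`: `by_taxon` (genomes screened,
#'   genomes with >= 1 locus, percentage per taxon group), `copy_number`
#'   (histogram over positive genomes), `per_genome` (locus count per
#'   genome), and `multi_copy` (ids of genomes with > 1 locus).
#' @export
summarize_prevalence <- function(loci, metadata) {
  stopifnot(all(c("genome_id", "taxon_group") %in% names(metadata)))
  counts <- table(factor(loci$genome_id, levels = metadata$genome_id))
  per_genome <- data.frame(genome_id = metadata$genome_id,
                           taxon_group = metadata$taxon_group,
                           n_loci = as.integer(counts),
                           stringsAsFactors = FALSE)
  by_taxon <- do.call(rbind, lapply(split(per_genome, per_genome$taxon_group),
    function(g) data.frame(taxon_group = g$taxon_group[1],
                           genomes_screened = nrow(g),
                           genomes_positive = sum(g$n_loci > 0),
                           pct_positive = 100 * sum(g$n_loci > 0) / nrow(g),
                           stringsAsFactors = FALSE)))
  by_taxon <- by_taxon[order(by_taxon$taxon_group), ]
  rownames(by_taxon) <- NULL
  pos <- per_genome$n_loci[per_genome$n_loci > 0]
  copy_number <- as.data.frame(table(copies = pos), stringsAsFactors = FALSE)
  if (nrow(copy_number)) copy_number$copies <- as.integer(copy_number$copies)
  structure(list(by_taxon = by_taxon, copy_number = copy_number,
                 per_genome = per_genome,
                 multi_copy = per_genome$genome_id[per_genome$n_loci > 1]),
            class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat("TLP prevalence by taxon group:\n")
  print(x$by_taxon, row.names = FALSE)
  if (nrow(x$copy_number)) {
    cat("copy-number histogram (positive genomes):\n")
    print(x$copy_number, row.names = FALSE)
  }
  if (length(x$multi_copy))
    cat("multi-copy genomes:", paste(x$multi_copy, collapse = ", "), "\n")
  invisible(x)
}

#' Write a prevalence summary as JSON
#'
#' @param summary A `prevalence_summary`.
#' @param path Output path.
#' @export
write_prevalence_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a hit table as TSV
#'
#' @param hits Data.frame from [scan_frames()] (or any data.frame).
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Export loci as GFF3
#'
#' One `protein_match` feature per locus (1-based inclusive coordinates per
#' the GFF3 standard), with the per-domain intervals as child
#' `match_part` features.
#'
#' @param loci Locus table from [call_architecture()].
#' @param path Output `.gff3` path.
#' @param order Domain names for the three `match_part` children.
#' @export
loci_to_gff3 <- function(loci, path, order = c("FN-plug", "NHL", "YD-shell")) {
  if (nrow(loci) == 0) {
    gr <- GenomicRanges::GRanges()
    rtracklayer::export(gr, path, format = "gff3")
    return(invisible(path))
  }
  parent_ids <- sprintf("TLP_%s_%d", loci$genome_id, loci$copy_index)
  parents <- GenomicRanges::GRanges(
    seqnames = loci$genome_id,
    ranges = IRanges::IRanges(start = loci$gstart, end = loci$gend),
    strand = loci$strand,
    type = "protein_match", source = "tlpscan",
    score = loci$combined_score, ID = parent_ids)
  kids <- do.call(c, lapply(1:3, function(d) {
    GenomicRanges::GRanges(
      seqnames = loci$genome_id,
      ranges = IRanges::IRanges(start = loci[[sprintf("d%d_gstart", d)]],
                                end = loci[[sprintf("d%d_gend", d)]]),
      strand = loci$strand,
      type = "match_part", source = "tlpscan",
      score = NA_real_,
      ID = sprintf("%s.%s", parent_ids, order[d]))
  }))
  kids$Parent <- sub("\\.[^.]+$", "", kids$ID)
  all <- c(parents, kids)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all), all$type)]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
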
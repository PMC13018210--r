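# Synthetic data with planted ground truth: superfold-like alignments,
# domain-sampled peptides, reverse translation, and benchmark genomes
# carrying three-domain cassettes, decoys and downstream immunity-like ORFs.

#' Generate a synthetic superfold-like protein alignment
#'
#' Builds a multiple alignment that emulates a superfold family MSA: a
#' full-length reference protein (default 2237 residues so that the
#' paper-style residue numbering applies: domain boundaries at 673-928 /
#' 929-1255 / 1256-2139, RHS bipartite motif with catalytic aspartates at
#' 2118 and 2140, and a hydrophobic C-terminal stretch at 2165-2185), plus
#' mutated homologs with substitutions, deletion gaps, and insertion columns
#' (gapped in the reference).
#'
#' @param n_seqs Number of homolog rows in addition to the reference
#'   (default 9).
#' @param ref_len Ungapped reference length (default 2237).
#' @param sub_rate Per-residue substitution probability in homologs
#'   (default 0.3, i.e. ~70 percent identity to the reference).
#' @param n_deletions,deletion_len Deletion events per homolog row and their
#'   length range.
#' @param n_insertions,insertion_len Insertion-column events and their length
#'   range (each event places residues in a random subset of homolog rows).
#' @param reference_id Row id given to the reference.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return An [as_alignment()] object; the reference row carries no gaps
#'   except at insertion columns.
#' @export
simulate_superfold_alignment <- function(n_seqs = 9, ref_len = 2237,
                                         sub_rate = 0.3,
                                         n_deletions = 3,
                                         deletion_len = c(1, 8),
                                         n_insertions = 4,
                                         insertion_len = c(1, 4),
                                         reference_id = "REF_superfold",
                                         seed = 101) {
  stopifnot(ref_len >= 2200)
  with_seed(seed, {
    ref <- sample(AA_ALPHABET, ref_len, replace = TRUE)
    # plant the RHS bipartite cleavage motif (first tetrad with the L
    # variant) and a hydrophobic TM-like stretch in the CTD region
    ref[2118:2121] <- c("D", "P", "Y", "L")
    ref[2140:2143] <- c("D", "P", "N", "G")
    ref[2165:2185] <- sample(c("L", "I", "V", "F", "A"), 21, replace = TRUE)
    rows <- list()
    rows[[reference_id]] <- ref
    for (s in seq_len(n_seqs)) {
      row <- ref
      mut <- which(stats::runif(ref_len) < sub_rate)
      row[mut] <- sample(AA_ALPHABET, length(mut), replace = TRUE)
      for (d in seq_len(n_deletions)) {
        len <- sample(deletion_len[1]:deletion_len[2], 1)
        at <- sample(ref_len - len, 1)
        row[at:(at + len - 1)] <- "-"
      }
      rows[[sprintf("homolog_%02d", s)]] <- row
    }
    # insertion columns: residues in a random subset of homolog rows,
    # gaps in the reference (and remaining rows)
    n_col <- ref_len
    for (ins in seq_len(n_insertions)) {
      len <- sample(insertion_len[1]:insertion_len[2], 1)
      at <- sample(2:n_col, 1)  # insert before column `at`
      block <- matrix("-", nrow = length(rows), ncol = len)
      carriers <- sample(2:length(rows), max(1, length(rows) %/% 3))
      for (r in carriers)
        block[r, ] <- sample(AA_ALPHABET, len, replace = TRUE)
      rows <- lapply(seq_along(rows), function(r) {
        append(rows[[r]], block[r, ], after = at - 1)
      })
      names(rows) <- c(reference_id,
                       sprintf("homolog_%02d", seq_len(n_seqs)))
      n_col <- n_col + len
    }
    as_alignment(vapply(rows, paste, character(1), collapse = ""))
  })
}

#' Build the three-domain superfold HMM library from an alignment
#'
#' Splits the alignment at the reference residue boundaries into FN-plug
#' (673-928), NHL (929-1255) and YD-shell (1256-2139) sub-alignments, builds
#' one profile HMM per domain, calibrates each, and combines them into a
#' library in architecture order.
#'
#' @param aln Superfold alignment ([as_alignment()]).
#' @param reference_id Reference row id.
#' @param boundaries Named list of 1-based inclusive reference residue ranges.
#' @param calibration_seed Master seed for per-model calibration.
#' @param n_cal,len_cal Calibration parameters (see [calibrate_hmm()]).
#' @return An [hmm_library()] of three calibrated models.
#' @export
build_superfold_library <- function(aln, reference_id = "REF_superfold",
                                    boundaries = list(
                                      "FN-plug" = c(673, 928),
                                      "NHL" = c(929, 1255),
                                      "YD-shell" = c(1256, 2139)),
                                    calibration_seed = 7,
                                    n_cal = 200, len_cal = 400) {
  models <- lapply(seq_along(boundaries), function(i) {
    b <- boundaries[[i]]
    sub <- slice_alignment_by_reference(aln, reference_id, b[1], b[2])
    hmm <- build_hmm(sub, name = names(boundaries)[i])
    calibrate_hmm(hmm, n_cal = n_cal, len_cal = len_cal,
                  seed = derive_seed(calibration_seed, i))
  })
  hmm_library(models, order = names(boundaries))
}

#' Sample a peptide from a profile HMM
#'
#' Samples a match-state path from state 1 to state M with
#' transition-governed inserts and deletes, emitting match residues from the
#' match emissions and insert residues from the insert (background)
#' emissions.
#'
#' @param hmm A `profile_hmm`.
#' @param seed Optional integer seed (deterministic output when given).
#' @return Character scalar peptide.
#' @export
emit_from_hmm <- function(hmm, seed = NULL) {
  do_emit <- function() {
    out <- character(0)
    k <- 1L; state <- "M"
    repeat {
      if (state == "M") {
        out <- c(out, sample(AA_ALPHABET, 1, prob = hmm$match_emissions[k, ]))
        if (k == hmm$M) break
        nxt <- sample(c("M", "I", "D"), 1,
                      prob = hmm$transitions[k, c("mm", "mi", "md")])
      } else if (state == "I") {
        out <- c(out, sample(AA_ALPHABET, 1, prob = hmm$insert_emissions))
        nxt <- sample(c("M", "I"), 1, prob = hmm$transitions[k, c("im", "ii")])
      } else {
        if (k == hmm$M) break
        nxt <- sample(c("M", "D"), 1, prob = hmm$transitions[k, c("dm", "dd")])
      }
      if (state == "I") {
        if (nxt == "M") { k <- k + 1L; state <- "M" } else state <- "I"
      } else {
        if (nxt == "I") state <- "I"
        else { k <- k + 1L; state <- nxt }
      }
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) do_emit() else with_seed(seed, do_emit())
}

#' Reverse-translate a peptide into DNA
#'
#' Each residue is mapped to a synonymous codon (uniform over synonyms, or
#' biased toward G/C-rich codons). Stop codons are never emitted, so the
#' result translates back to the peptide in frame +1 with no internal stops.
#'
#' @param peptide Amino-acid string over the 20-letter alphabet.
#' @param table Genetic code (default `"standard"`).
#' @param codon_mode `"uniform"` or `"gc_rich"`.
#' @param seed Optional integer seed.
#' @return DNA string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide, table = "standard",
                              codon_mode = c("uniform", "gc_rich"),
                              seed = NULL) {
  codon_mode <- match.arg(codon_mode)
  code <- resolve_genetic_code(table)
  code <- code[code != "*"]
  by_aa <- split(names(code), code)
  chars <- strsplit(toupper(peptide), "")[[1]]
  if (any(!chars %in% names(by_aa)))
    stopf("cannot reverse-translate residue '%s'",
          chars[which(!chars %in% names(by_aa))[1]])
  do_rt <- function() {
    codons <- vapply(chars, function(a) {
      syn <- by_aa[[a]]
      if (length(syn) == 1) return(syn)
      w <- if (codon_mode == "uniform") rep(1, length(syn)) else
        2^vapply(strsplit(syn, ""), function(cc) sum(cc %in% c("G", "C")),
                 numeric(1))
      sample(syn, 1, prob = w)
    }, character(1))
    paste(codons, collapse = "")
  }
  if (is.null(seed)) do_rt() else with_seed(seed, do_rt())
}

#' Generator configuration for the synthetic benchmark
#'
#' Defaults define the fixed benchmark used throughout validation: 20
#' genomes of 200 kb at GC 0.5, 30 planted cassettes, 10 decoys of each of
#' the three kinds the architecture filter must reject (wrong domain order;
#' domains split across strands; single partial domain), short 2-20 aa
#' linkers, a downstream immunity-like ORF for every cassette, at least 2 kb
#' between planted elements, and seed 1337.
#'
#' @param n_genomes,genome_length,gc_content Genome count, length (nt), GC.
#' @param n_cassettes Number of true cassettes planted across genomes (at
#'   most 4 per genome, mirroring observed maximal copy numbers).
#' @param n_decoy_order,n_decoy_strand_split,n_decoy_partial Decoy counts.
#' @param linker_len Uniform bounds (aa) for inter-domain linkers.
#' @param partial_frac Range of the retained fraction for partial decoys.
#' @param codon_mode Passed to [reverse_translate()].
#' @param plant_immunity_orf Plant an ATG..stop ORF downstream of each
#'   cassette on the same strand.
#' @param immunity_distance,immunity_len Ranges (nt) for the ORF's distance
#'   downstream and its length (rounded to full codons).
#' @param taxon_groups Group labels cycled over genomes.
#' @param positive_rate Optional named per-group probability that a genome
#'   carries one cassette; overrides `n_cassettes` when given.
#' @param min_spacing Minimum distance (nt) between planted elements.
#' @param seed Master seed.
#' @return List of class `generator_config`.
#' @export
benchmark_config <- function(n_genomes = 20, genome_length = 200000,
                             gc_content = 0.5, n_cassettes = 30,
                             n_decoy_order = 10, n_decoy_strand_split = 10,
                             n_decoy_partial = 10, linker_len = c(2, 20),
                             partial_frac = c(0.35, 0.6),
                             codon_mode = "uniform",
                             plant_immunity_orf = TRUE,
                             immunity_distance = c(50, 500),
                             immunity_len = c(150, 600),
                             taxon_groups = c("phylum_A", "phylum_B",
                                              "phylum_C", "phylum_D"),
                             positive_rate = NULL, min_spacing = 2000,
                             seed = 1337) {
  cfg <- as.list(environment())
  stopifnot(n_genomes >= 1, genome_length >= 1000,
            gc_content > 0, gc_content < 1,
            n_cassettes >= 0, n_decoy_order >= 0,
            n_decoy_strand_split >= 0, n_decoy_partial >= 0)
  structure(cfg, class = "generator_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_linker <- function(len_range) {
  n <- sample(len_range[1]:len_range[2], 1)
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# sample domain peptides for a cassette-like element; returns peptides and
# the DNA of [dom1]+linker+[dom2]+linker+[dom3] with per-domain nt offsets
build_cassette_dna <- function(lib, order, cfg) {
  peps <- lapply(order, function(nm) emit_from_hmm(lib$models[[nm]]))
  names(peps) <- order
  parts <- character(0); offsets <- integer(0); at <- 0L
  for (i in seq_along(order)) {
    if (i > 1) {
      link <- random_linker(cfg$linker_len)
      parts <- c(parts, link); at <- at + 3L * nchar(link)
    }
    offsets <- c(offsets, at)
    parts <- c(parts, peps[[i]]); at <- at + 3L * nchar(peps[[i]])
  }
  dna <- reverse_translate(paste(parts, collapse = ""),
                           codon_mode = cfg$codon_mode)
  list(dna = dna, peptides = peps,
       dom_offsets = offsets,  # 0-based nt offset of each domain in dna
       dom_lens = vapply(peps, function(p) 3L * nchar(p), integer(1)))
}

immunity_orf_dna <- function(cfg) {
  len <- sample(cfg$immunity_len[1]:cfg$immunity_len[2], 1)
  n_codon <- max(2L, as.integer(len) %/% 3L)
  body <- paste(vapply(seq_len(n_codon - 2L), function(i) {
    reverse_translate(sample(AA_ALPHABET, 1))
  }, character(1)), collapse = "")
  paste0("ATG", body, "TAA")
}

#' Generate the synthetic benchmark: genomes, metadata and truth
#'
#' Plants reverse-translated three-domain cassettes (sampled from the HMM
#' library, joined by short linkers) on random strands and positions in
#' i.i.d. background DNA, together with the configured decoys and optional
#' downstream immunity-like ORFs, and emits a truth table alongside.
#'
#' Decoy kinds: `decoy_order` (all three domains, shuffled non-architecture
#' order), `decoy_strand_split` (first two domains on one strand, third on
#' the other), `decoy_partial` (a random fraction of a single domain).
#'
#' @param cfg A [benchmark_config()].
#' @param lib The [hmm_library()] providing the three domain models.
#' @return List with `genomes` (named character vector), `metadata`
#'   (data.frame `genome_id, species, taxon_group`) and `truth` (data.frame:
#'   one row per planted part with `element_id, genome_id, kind, part,
#'   model, start, end, strand`, 1-based inclusive forward-strand
#'   coordinates). Deterministic given `cfg$seed`.
#' @export
generate_benchmark <- function(cfg, lib) {
  stopifnot(inherits(cfg, "generator_config"), inherits(lib, "hmm_library"))
  order <- lib$order
  with_seed(cfg$seed, {
    ids <- sprintf("genome_%02d", seq_len(cfg$n_genomes))
    metadata <- data.frame(
      genome_id = ids,
      species = sprintf("Synthetibacter sp. %02d", seq_len(cfg$n_genomes)),
      taxon_group = rep(cfg$taxon_groups, length.out = cfg$n_genomes),
      stringsAsFactors = FALSE)
    genomes <- vapply(ids, function(i)
      random_dna(cfg$genome_length, cfg$gc_content), character(1))

    # decide cassette counts per genome
    if (!is.null(cfg$positive_rate)) {
      pr <- cfg$positive_rate[metadata$taxon_group]
      pr[is.na(pr)] <- 0
      n_cass_per_genome <- as.integer(stats::runif(cfg$n_genomes) < pr)
    } else {
      n_cass_per_genome <- integer(cfg$n_genomes)
      remaining <- cfg$n_cassettes
      while (remaining > 0) {
        open <- which(n_cass_per_genome < 4L)
        g <- open[sample.int(length(open), 1)]
        n_cass_per_genome[g] <- n_cass_per_genome[g] + 1L
        remaining <- remaining - 1L
      }
    }
    decoy_kinds <- rep(c("decoy_order", "decoy_strand_split", "decoy_partial"),
                       c(cfg$n_decoy_order, cfg$n_decoy_strand_split,
                         cfg$n_decoy_partial))
    decoy_genome <- if (length(decoy_kinds))
      sample(cfg$n_genomes, length(decoy_kinds), replace = TRUE) else integer(0)

    truth_rows <- list()
    elem_counter <- 0L
    occupied <- lapply(seq_len(cfg$n_genomes), function(i) {
      data.frame(start = integer(), end = integer())
    })

    place_element <- function(gi, dna_len) {
      occ <- occupied[[gi]]
      for (try in seq_len(200)) {
        pos <- sample(cfg$genome_length - dna_len - 1L, 1)  # 0-based insert
        lo <- pos - cfg$min_spacing; hi <- pos + dna_len + cfg$min_spacing
        if (!nrow(occ) || all(occ$end < lo | occ$start > hi)) {
          occupied[[gi]] <<- rbind(occ, data.frame(start = pos,
                                                   end = pos + dna_len))
          return(pos)
        }
      }
      stopf("could not place element of %d nt in genome %d (too crowded)",
            dna_len, gi)
    }

    splice <- function(gi, pos, dna) {
      g <- genomes[[gi]]
      genomes[[gi]] <<- paste0(substr(g, 1, pos), dna,
                               substr(g, pos + nchar(dna) + 1L, nchar(g)))
    }

    add_truth <- function(eid, gi, kind, part, model, start0, end0, strand) {
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        element_id = eid, genome_id = ids[gi], kind = kind, part = part,
        model = model, start = start0 + 1L, end = end0, strand = strand,
        stringsAsFactors = FALSE)
    }

    plant_cassette <- function(gi) {
      elem_counter <<- elem_counter + 1L
      eid <- sprintf("elem_%03d", elem_counter)
      cass <- build_cassette_dna(lib, order, cfg)
      dna_len <- nchar(cass$dna)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") cass$dna else reverse_complement(cass$dna)
      pos <- place_element(gi, dna_len)
      splice(gi, pos, ins)
      add_truth(eid, gi, "cassette", "element", NA_character_,
                pos, pos + dna_len, strand)
      for (i in seq_along(order)) {
        o <- cass$dom_offsets[i]; l <- cass$dom_lens[i]
        if (strand == "+") {
          add_truth(eid, gi, "cassette", sprintf("domain_%d", i), order[i],
                    pos + o, pos + o + l, "+")
        } else {
          add_truth(eid, gi, "cassette", sprintf("domain_%d", i), order[i],
                    pos + dna_len - o - l, pos + dna_len - o, "-")
        }
      }
      if (isTRUE(cfg$plant_immunity_orf)) {
        orf <- immunity_orf_dna(cfg)
        dist <- sample(cfg$immunity_distance[1]:cfg$immunity_distance[2], 1)
        # place the ORF downstream of the cassette 3' end on the same strand
        if (strand == "+") {
          opos <- pos + dna_len + dist
          if (opos + nchar(orf) <= cfg$genome_length) {
            splice(gi, opos, orf)
            occupied[[gi]] <<- rbind(occupied[[gi]],
              data.frame(start = opos, end = opos + nchar(orf)))
            add_truth(eid, gi, "immunity_orf", "element", NA_character_,
                      opos, opos + nchar(orf), "+")
          }
        } else {
          opos <- pos - dist - nchar(orf)
          if (opos > 0) {
            splice(gi, opos, reverse_complement(orf))
            occupied[[gi]] <<- rbind(occupied[[gi]],
              data.frame(start = opos, end = opos + nchar(orf)))
            add_truth(eid, gi, "immunity_orf", "element", NA_character_,
                      opos, opos + nchar(orf), "-")
          }
        }
      }
    }

    plant_decoy <- function(gi, kind) {
      elem_counter <<- elem_counter + 1L
      eid <- sprintf("elem_%03d", elem_counter)
      if (kind == "decoy_order") {
        wrong <- order
        while (identical(wrong, order)) wrong <- sample(order)
        cass <- build_cassette_dna(lib, wrong, cfg)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") cass$dna else reverse_complement(cass$dna)
        pos <- place_element(gi, nchar(cass$dna))
        splice(gi, pos, ins)
        add_truth(eid, gi, kind, "element",
                  paste(wrong, collapse = ","), pos, pos + nchar(ins), strand)
      } else if (kind == "decoy_strand_split") {
        duo <- build_cassette_dna(lib, order[1:2], cfg)
        third <- reverse_translate(emit_from_hmm(lib$models[[order[3]]]),
                                   codon_mode = cfg$codon_mode)
        link <- reverse_translate(random_linker(cfg$linker_len),
                                  codon_mode = cfg$codon_mode)
        dna <- paste0(duo$dna, link, reverse_complement(third))
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") dna else reverse_complement(dna)
        pos <- place_element(gi, nchar(dna))
        splice(gi, pos, ins)
        add_truth(eid, gi, kind, "element",
                  paste(c(order[1:2], paste0("rc:", order[3])), collapse = ","),
                  pos, pos + nchar(dna), strand)
      } else {  # decoy_partial
        model <- sample(order, 1)
        pep <- emit_from_hmm(lib$models[[model]])
        frac <- stats::runif(1, cfg$partial_frac[1], cfg$partial_frac[2])
        keep <- max(10L, as.integer(frac * nchar(pep)))
        at <- sample(nchar(pep) - keep + 1L, 1)
        dna <- reverse_translate(substr(pep, at, at + keep - 1L),
                                 codon_mode = cfg$codon_mode)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") dna else reverse_complement(dna)
        pos <- place_element(gi, nchar(dna))
        splice(gi, pos, ins)
        add_truth(eid, gi, kind, "element", model, pos, pos + nchar(dna),
                  strand)
      }
    }

    # plant in fixed order: cassettes genome by genome, then decoys
    for (gi in seq_len(cfg$n_genomes)) {
      for (r in seq_len(n_cass_per_genome[gi])) plant_cassette(gi)
    }
    for (d in seq_along(decoy_kinds)) plant_decoy(decoy_genome[d],
                                                  decoy_kinds[d])

    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(element_id = character(), genome_id = character(),
                 kind = character(), part = character(), model = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    list(genomes = genomes, metadata = metadata, truth = truth)
  })
}

#' Write benchmark outputs to a directory
#'
#' Genomes as FASTA, metadata and truth as TSV.
#'
#' @param bench Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$genomes, file.path(dir, "genomes.fasta"))
  utils::write.table(bench$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(bench$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(dir)
}
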
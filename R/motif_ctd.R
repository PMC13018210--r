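# RHS core cleavage-motif detection, C-terminal domain (CTD) extraction, and
# CTD sequence statistics: Kyte-Doolittle hydropathy with transmembrane
# segment calling, and molecular mass.

#' Kyte-Doolittle hydropathy scale
#' @format Named numeric vector over the 20 canonical residues.
#' @export
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# average (isotope-averaged) free amino-acid masses in Da (standard residue
# masses plus one water); peptide mass is the residue sum minus (n-1) waters
WATER_MASS <- 18.01528
AA_MASS_AVG <- WATER_MASS +
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
    C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
    H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
    M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
    T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

all_matches <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan for the simple RHS core cleavage motif PxxxxDPxG
#'
#' Finds all (including overlapping) matches of `P-x(4)-D-P-x-G`
#' (`x` = any amino acid), the motif characteristic of the conserved RHS core
#' domain cleavage site.
#'
#' @param seq Protein sequence (character scalar).
#' @return Data.frame with one row per match: `pattern_id` (`"simple_PxxxxDPxG"`),
#'   `start` (1-based position of the leading proline), `d_pos` (position of
#'   the aspartate), `match` (the 9-residue instance).
#' @export
scan_simple_motif <- function(seq) {
  seq <- toupper(seq)
  pos <- all_matches(seq, "P....DP.G")
  if (!length(pos)) {
    return(data.frame(pattern_id = character(), start = integer(),
                      d_pos = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(pattern_id = rep("simple_PxxxxDPxG", length(pos)),
             start = pos, d_pos = pos + 5L,
             match = substring(seq, pos, pos + 8L),
             stringsAsFactors = FALSE)
}

#' Scan for the bipartite RHS motif DPx[G/L/R]-Xn-DPxG
#'
#' Finds the bipartite aspartyl-protease motif `D-P-x-[GLR] - x(spacer) -
#' D-P-x-G` in which the two aspartates are the catalytic residues. The
#' terminal residue of the first tetrad is canonically glycine but may be
#' substituted by leucine or arginine in some species; the observed variant
#' is recorded.
#'
#' @param seq Protein sequence.
#' @param spacer Number of intervening residues between the two tetrads
#'   (default 18, the DPxG-X18-DPxG pattern; the aspartate-to-aspartate
#'   distance is then `4 + spacer = 22`).
#' @param first_terminal_variants Allowed terminal residues of the first
#'   tetrad (default `G`, `L`, `R`).
#' @return Data.frame with one row per match: `pattern_id` (`"bipartite"`),
#'   `d1_pos`, `d2_pos` (1-based positions of the catalytic aspartates),
#'   `first_motif_variant` (observed terminal residue of the first tetrad),
#'   `match`.
#' @export
scan_bipartite_motif <- function(seq, spacer = 18,
                                 first_terminal_variants = c("G", "L", "R")) {
  seq <- toupper(seq)
  cls <- paste0("[", paste(first_terminal_variants, collapse = ""), "]")
  regex <- sprintf("DP.%s.{%d}DP.G", cls, spacer)
  pos <- all_matches(seq, regex)
  width <- 4L + spacer + 4L
  if (!length(pos)) {
    return(data.frame(pattern_id = character(), d1_pos = integer(),
                      d2_pos = integer(), first_motif_variant = character(),
                      match = character(), stringsAsFactors = FALSE))
  }
  data.frame(pattern_id = rep("bipartite", length(pos)),
             d1_pos = pos, d2_pos = pos + 4L + as.integer(spacer),
             first_motif_variant = substring(seq, pos + 3L, pos + 3L),
             match = substring(seq, pos, pos + width - 1L),
             stringsAsFactors = FALSE)
}

#' Extract the C-terminal domain downstream of the RHS cleavage site
#'
#' The CTD starts at `d2_pos + 5`: cleavage falls between the glycine of the
#' second DPxG tetrad (`d2_pos + 4`, the last residue ordered in the shell)
#' and the following residue. With the second catalytic aspartate at
#' reference position 2140 this gives a CTD starting at residue 2145.
#'
#' @param seq Parent protein sequence.
#' @param hit One row of [scan_bipartite_motif()] output (or a list with
#'   `d1_pos`, `d2_pos`).
#' @param parent_id Identifier recorded on the record.
#' @param hydropathy_window,tm_threshold Passed to [hydropathy_tm()].
#' @return List of class `ctd_record`: `parent_id`, `ctd_start` (1-based),
#'   `sequence`, `mass_kDa`, `hydropathy`, `tm_segments`, `d1_pos`, `d2_pos`.
#' @export
extract_ctd <- function(seq, hit, parent_id = "protein",
                        hydropathy_window = 19, tm_threshold = 1.6) {
  seq <- toupper(seq)
  d2 <- as.integer(hit$d2_pos)
  if (substr(seq, d2, d2) != "D")
    stopf("no aspartate at reported d2_pos = %d", d2)
  ctd_start <- d2 + 5L
  if (ctd_start > nchar(seq))
    stopf("CTD would be empty: motif at sequence end (d2_pos = %d)", d2)
  ctd <- substr(seq, ctd_start, nchar(seq))
  hp <- hydropathy_tm(ctd, window = hydropathy_window,
                      threshold = tm_threshold)
  structure(list(parent_id = parent_id, ctd_start = ctd_start,
                 sequence = ctd, mass_kDa = molecular_mass(ctd),
                 hydropathy = hp$profile, tm_segments = hp$tm_segments,
                 d1_pos = as.integer(hit$d1_pos), d2_pos = d2),
            class = "ctd_record")
}

#' @export
print.ctd_record <- function(x, ...) {
  cat(sprintf("CTD of '%s': residues %d..%d of parent (%d aa, %.2f kDa)\n",
              x$parent_id, x$ctd_start,
              x$ctd_start + nchar(x$sequence) - 1L,
              nchar(x$sequence), x$mass_kDa))
  if (nrow(x$tm_segments)) {
    cat("hydropathy-predicted TM segments (parent coordinates):\n")
    seg <- x$tm_segments
    seg$start <- seg$start + x$ctd_start - 1L
    seg$end <- seg$end + x$ctd_start - 1L
    print(seg, row.names = FALSE)
  } else cat("no hydropathy-predicted TM segment\n")
  invisible(x)
}

#' Windowed Kyte-Doolittle hydropathy and TM segment calling
#'
#' Centered moving-average hydropathy (window must be odd; positions whose
#' window does not fit are `NA`). Maximal runs of window centres strictly
#' above `threshold` are merged when separated by at most `merge_gap`
#' positions and reported as transmembrane segments when at least
#' `min_run` long. Outputs are hydropathy-predicted segments, not a claim of
#' residue-exact structural TM boundaries.
#'
#' @param seq Protein sequence.
#' @param scale Named per-residue hydropathy scale (default Kyte-Doolittle).
#' @param window Sliding-window width in residues (odd; default 19).
#' @param threshold Segment-calling cutoff on the windowed mean (default 1.6).
#' @param merge_gap Merge runs separated by at most this many centres
#'   (default 3).
#' @param min_run Minimum merged run length in residues (default 15).
#' @return List with `profile` (per-residue numeric, `NA` at the edges) and
#'   `tm_segments` (data.frame `start`, `end`, 1-based inclusive).
#' @export
hydropathy_tm <- function(seq, scale = KYTE_DOOLITTLE, window = 19,
                          threshold = 1.6, merge_gap = 3, min_run = 15) {
  stopifnot(window %% 2 == 1)
  seq <- toupper(seq)
  vals <- scale[strsplit(seq, "")[[1]]]
  vals[is.na(vals)] <- 0  # unknown residues are hydropathy-neutral
  n <- length(vals)
  prof <- rep(NA_real_, n)
  h <- (window - 1) / 2
  if (n >= window) {
    cs <- cumsum(c(0, vals))
    centers <- (h + 1):(n - h)
    prof[centers] <- (cs[centers + h + 1] - cs[centers - h]) / window
  }
  above <- which(!is.na(prof) & prof > threshold)
  segs <- data.frame(start = integer(), end = integer())
  if (length(above)) {
    breaks <- which(diff(above) > merge_gap + 1)
    run_start <- above[c(1, breaks + 1)]
    run_end <- above[c(breaks, length(above))]
    keep <- (run_end - run_start + 1) >= min_run
    segs <- data.frame(start = run_start[keep], end = run_end[keep])
  }
  list(profile = prof, tm_segments = segs)
}

#' Molecular mass of a peptide in kDa
#'
#' Sum of average residue (free amino-acid) masses minus `(n-1)` waters.
#' Unknown residues (e.g. `X`) take the mean residue mass.
#'
#' @param seq Protein sequence.
#' @return Mass in kDa.
#' @export
molecular_mass <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- AA_MASS_AVG[chars]
  m[is.na(m)] <- mean(AA_MASS_AVG)
  (sum(m) - (length(chars) - 1) * WATER_MASS) / 1000
}

#' Annotate a set of proteins with RHS motifs and CTDs
#'
#' Convenience driver over [scan_simple_motif()], [scan_bipartite_motif()]
#' and [extract_ctd()]: for each protein, all bipartite hits are recorded and
#' a CTD is derived from the last bipartite hit (the cleavage site proximal
#' to the C-terminus, as in RHS-family proteins).
#'
#' @param prots Named character vector of protein sequences.
#' @param spacer Passed to [scan_bipartite_motif()].
#' @return List with `motifs` (data.frame over all proteins) and `ctds`
#'   (named list of `ctd_record`, proteins without a usable bipartite hit
#'   omitted).
#' @export
annotate_rhs_ctd <- function(prots, spacer = 18) {
  motif_rows <- list(); ctds <- list()
  for (id in names(prots)) {
    seq <- prots[[id]]
    simple <- scan_simple_motif(seq)
    bip <- scan_bipartite_motif(seq, spacer = spacer)
    if (nrow(simple)) {
      motif_rows[[length(motif_rows) + 1]] <-
        cbind(protein_id = id, simple[, c("pattern_id", "start", "d_pos")],
              detail = simple$match)
    }
    if (nrow(bip)) {
      motif_rows[[length(motif_rows) + 1]] <-
        data.frame(protein_id = id, pattern_id = bip$pattern_id,
                   start = bip$d1_pos, d_pos = bip$d2_pos,
                   detail = paste0(bip$match, " (first-motif variant ",
                                   bip$first_motif_variant, ")"))
      last <- bip[nrow(bip), ]
      if (last$d2_pos + 5L <= nchar(seq))
        ctds[[id]] <- extract_ctd(seq, last, parent_id = id)
    }
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(protein_id = character(), pattern_id = character(),
               start = integer(), d_pos = integer(), detail = character())
  rownames(motifs) <- NULL
  list(motifs = motifs, ctds = ctds)
}
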
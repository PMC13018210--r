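# Independent oracles used across tests. Each is written against the model
# definitions directly (enumeration, codon lookup, cumulative sums), not
# against the package's DP/scan code paths.

# --- exhaustive path enumeration for local profile-HMM scores --------------
# Enumerates every local path (entry at any match state with weight 1/M,
# free exit from any match state, flanks ignored) and returns the log2 sum
# (forward) and log2 max (Viterbi) of path weights. Feasible for M <= 3 and
# short peptides.
oracle_scores <- function(hmm, pep) {
  codes <- match(strsplit(pep, "")[[1]], AA_ALPHABET)
  L <- length(codes); M <- hmm$M
  eodds <- function(k, i) {
    ci <- codes[i]
    if (is.na(ci)) 1 else hmm$match_emissions[k, ci] / hmm$background[ci]
  }
  tr <- hmm$transitions
  weights <- c()
  recurse <- function(state, k, i, w) {
    if (state == "M") {
      weights <<- c(weights, w)  # exit here
      if (k < M) {
        if (i < L) recurse("M", k + 1, i + 1, w * tr[k, "mm"] * eodds(k + 1, i + 1))
        if (i < L) recurse("I", k, i + 1, w * tr[k, "mi"])
        recurse("D", k + 1, i, w * tr[k, "md"])
      }
    } else if (state == "I") {
      if (i < L) recurse("I", k, i + 1, w * tr[k, "ii"])
      if (k < M && i < L) recurse("M", k + 1, i + 1, w * tr[k, "im"] * eodds(k + 1, i + 1))
    } else {  # D (silent)
      if (k < M) {
        if (i < L) recurse("M", k + 1, i + 1, w * tr[k, "dm"] * eodds(k + 1, i + 1))
        recurse("D", k + 1, i, w * tr[k, "dd"])
      }
    }
  }
  for (i0 in seq_len(L)) for (k0 in seq_len(M))
    recurse("M", k0, i0, (1 / M) * eodds(k0, i0))
  list(forward = log2(sum(weights)), viterbi = log2(max(weights)))
}

# --- codon-by-codon translation oracle -------------------------------------
CODON_TABLE_STD <- as.list(Biostrings::GENETIC_CODE)

oracle_translate <- function(dna, offset = 0) {
  n_codon <- (nchar(dna) - offset) %/% 3
  if (n_codon < 1) return("")
  starts <- offset + 1 + 3 * (seq_len(n_codon) - 1)
  codons <- substring(dna, starts, starts + 2)
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd)) "X" else CODON_TABLE_STD[[cd]]
  }, character(1))
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
}

# --- random toy profile HMM -------------------------------------------------
random_toy_hmm <- function(M, seed, name = "toy") {
  set.seed(seed)
  em <- matrix(stats::rgamma(M * 20, 0.5) + 1e-3, nrow = M)
  em <- em / rowSums(em)
  colnames(em) <- AA_ALPHABET
  tr <- matrix(0, M, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (k in seq_len(M)) {
    a <- stats::rgamma(3, 1) + 0.05; tr[k, 1:3] <- a / sum(a)
    b <- stats::rgamma(2, 1) + 0.05; tr[k, 4:5] <- b / sum(b)
    d <- stats::rgamma(2, 1) + 0.05; tr[k, 6:7] <- d / sum(d)
  }
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  structure(list(name = name, M = M, match_emissions = em,
                 insert_emissions = rep(1 / 20, 20), transitions = tr,
                 background = rep(1 / 20, 20), match_gap_frac = 0.5,
                 pseudocount = 5, calibration = NULL),
            class = "profile_hmm")
}

# deterministic high-fidelity toy model: one-hot-ish emissions on a given
# consensus, near-certain match-to-match transitions
consensus_toy_hmm <- function(consensus, em_peak = 0.999, mm = 0.999) {
  chars <- strsplit(consensus, "")[[1]]
  M <- length(chars)
  em <- matrix((1 - em_peak) / 19, nrow = M, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(M)) em[k, chars[k]] <- em_peak
  rest <- (1 - mm) / 2
  tr <- matrix(rep(c(mm, rest, rest, 0.5, 0.5, 0.5, 0.5), each = M), nrow = M,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  structure(list(name = "consensus_toy", M = M, match_emissions = em,
                 insert_emissions = rep(1 / 20, 20), transitions = tr,
                 background = rep(1 / 20, 20), match_gap_frac = 0.5,
                 pseudocount = 5, calibration = NULL),
            class = "profile_hmm")
}

# --- naive in-frame ORF oracle (forward strand of a window) ----------------
oracle_orfs <- function(sub, min_orf) {
  stops <- c("TAA", "TAG", "TGA")
  res <- data.frame(start = integer(), end = integer(), len = integer())
  n <- nchar(sub)
  for (s in seq_len(max(0, n - 5))) {
    if (substr(sub, s, s + 2) != "ATG") next
    p <- s
    repeat {
      if (p + 2 > n) { p <- NA; break }
      if (substr(sub, p, p + 2) %in% stops && p > s) break
      p <- p + 3
    }
    if (is.na(p)) next
    len <- p + 2 - s + 1
    if (len >= min_orf) res <- rbind(res, data.frame(start = s, end = p + 2, len = len))
  }
  # keep only the first (most upstream) ATG per (stop, frame)
  if (nrow(res)) {
    key <- paste(res$end, res$start %% 3)
    res <- res[!duplicated(key), , drop = FALSE]
  }
  res
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
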
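# Per-domain profile hidden Markov models: construction from an alignment,
# local forward/Viterbi scoring, Gumbel E-value calibration, and a plain-text
# serialization that round-trips bit-exactly.
#
# State model: match states M_1..M_M with 20-dim emissions; insert states
# I_1..I_{M-1} emitting the background distribution; delete states D. The
# seven per-state transitions are M->M, M->I, M->D, I->M, I->I, D->M, D->D.
# Scoring is local: entry into any match state (uniform weight 1/M), exit from
# any match state (free), unaligned flanks emitted by the background null and
# therefore cancelling in the log-odds ratio. Scores are in bits (log2).

DEFAULT_TRANSITION_PRIOR <- c(mm = 0.90, mi = 0.05, md = 0.05,
                              im = 0.50, ii = 0.50,
                              dm = 0.50, dd = 0.50)

#' Build a profile HMM from a protein alignment
#'
#' Alignment columns whose gap fraction is below `match_gap_frac` become match
#' states. Match emissions use background-mix pseudocounts,
#' `e_i(a) = (c_i(a) + A b(a)) / (C_i + A)` with observed counts `c`, column
#' residue total `C`, background `b` and pseudocount weight `A`. Transitions
#' are estimated from the observed per-row state paths with the same
#' background-mix pseudocount against a fixed transition prior. The rare
#' observed adjacencies I->D and D->I, which the seven-transition state model
#' excludes, are counted toward I->M and D->M. Insert emissions equal the
#' background. Residues outside the 20-letter alphabet (e.g. `X`) contribute
#' no emission counts.
#'
#' @param aln An [as_alignment()] object (>= 1 row; a single row is accepted
#'   with a warning).
#' @param name Model name (e.g. `"FN-plug"`, `"NHL"`, `"YD-shell"`).
#' @param match_gap_frac Columns with gap fraction strictly below this become
#'   match states (default 0.5).
#' @param pseudocount Pseudocount weight `A` (default 5).
#' @param background Length-20 background distribution over [AA_ALPHABET]
#'   (default uniform).
#' @param transition_prior Named 7-vector of prior transition probabilities
#'   (triples `mm,mi,md`, `im,ii`, `dm,dd` each summing to 1).
#' @return Object of class `profile_hmm` with elements `name`, `M`,
#'   `match_emissions` (M x 20), `insert_emissions`, `transitions` (M x 7),
#'   `background`, and `calibration` (`NULL` until [calibrate_hmm()]).
#' @export
build_hmm <- function(aln, name, match_gap_frac = 0.5, pseudocount = 5,
                      background = rep(1 / 20, 20),
                      transition_prior = DEFAULT_TRANSITION_PRIOR) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (length(aln) < 1) stopf("empty alignment")
  if (length(aln) == 1) warning("building HMM from a single sequence")
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9,
            all(background > 0))
  prior <- transition_prior[c("mm", "mi", "md", "im", "ii", "dm", "dd")]
  chars <- do.call(rbind, strsplit(unclass(aln), ""))
  gap <- chars == "-"
  gap_frac <- colMeans(gap)
  match_cols <- which(gap_frac < match_gap_frac)
  M <- length(match_cols)
  if (M == 0) stopf("alignment yields zero match columns")
  A <- pseudocount

  # --- match emissions ---
  em <- matrix(0, nrow = M, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(M)) {
    col <- chars[, match_cols[j]]
    counts <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    C <- sum(counts)
    em[j, ] <- (as.numeric(counts) + A * background) / (C + A)
  }

  # --- transitions from observed state paths ---
  # events per row: M/D at match columns, I for residues in insert columns
  cnt <- matrix(0, nrow = M, ncol = 7,
                dimnames = list(NULL, names(prior)))
  state_of_col <- rep("I", ncol(chars))
  state_of_col[match_cols] <- "M"
  midx_of_col <- integer(ncol(chars))
  midx_of_col[match_cols] <- seq_len(M)
  midx_of_col[state_of_col == "I"] <- cumsum(state_of_col == "M")[state_of_col == "I"]
  for (r in seq_len(nrow(chars))) {
    res <- !gap[r, ]
    ev_type <- character(0); ev_k <- integer(0)
    for (c in seq_len(ncol(chars))) {
      if (state_of_col[c] == "M") {
        ev_type <- c(ev_type, if (res[c]) "M" else "D")
        ev_k <- c(ev_k, midx_of_col[c])
      } else if (res[c]) {
        ev_type <- c(ev_type, "I")
        ev_k <- c(ev_k, midx_of_col[c])
      }
    }
    if (length(ev_type) < 2) next
    for (i in seq_len(length(ev_type) - 1)) {
      from <- ev_type[i]; to <- ev_type[i + 1]; k <- ev_k[i]
      if (k < 1 || k >= M + 1) next
      key <- switch(from,
        M = switch(to, M = "mm", I = "mi", D = "md"),
        I = switch(to, M = "im", I = "ii", D = "im"),  # I->D folded into I->M
        D = switch(to, M = "dm", D = "dd", I = "dm"))  # D->I folded into D->M
      if (k <= M - 1) cnt[k, key] <- cnt[k, key] + 1
    }
  }
  tr <- matrix(0, nrow = M, ncol = 7, dimnames = list(NULL, names(prior)))
  for (k in seq_len(M)) {
    for (grp in list(c("mm", "mi", "md"), c("im", "ii"), c("dm", "dd"))) {
      tot <- sum(cnt[k, grp])
      tr[k, grp] <- (cnt[k, grp] + A * prior[grp]) / (tot + A * sum(prior[grp]))
    }
  }
  # last state has no outgoing transitions; fixed exit row
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)

  hmm <- structure(list(name = name, M = M,
                        match_emissions = em,
                        insert_emissions = background,
                        transitions = tr,
                        background = background,
                        match_gap_frac = match_gap_frac,
                        pseudocount = A,
                        calibration = NULL),
                   class = "profile_hmm")
  validate_hmm(hmm)
  hmm
}

#' Validate a profile HMM
#'
#' Checks normalization of every emission and transition distribution (within
#' 1e-9), strict positivity of emissions, and calibration sanity.
#'
#' @param hmm A `profile_hmm`.
#' @return `hmm`, invisibly; errors on violation.
#' @export
validate_hmm <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (hmm$M < 1) stopf("M must be >= 1")
  if (any(abs(rowSums(hmm$match_emissions) - 1) > 1e-9))
    stopf("match emission rows must sum to 1")
  if (any(hmm$match_emissions <= 0)) stopf("match emissions must be > 0")
  if (abs(sum(hmm$insert_emissions) - 1) > 1e-9 ||
      abs(sum(hmm$background) - 1) > 1e-9)
    stopf("insert/background distributions must sum to 1")
  tr <- hmm$transitions
  if (hmm$M > 1) {
    body <- tr[seq_len(hmm$M - 1), , drop = FALSE]
    sums <- cbind(rowSums(body[, c("mm", "mi", "md"), drop = FALSE]),
                  rowSums(body[, c("im", "ii"), drop = FALSE]),
                  rowSums(body[, c("dm", "dd"), drop = FALSE]))
    if (any(abs(sums - 1) > 1e-9))
      stopf("transition triples must sum to 1")
    if (any(body <= 0)) stopf("transitions must be > 0 after pseudocounts")
  }
  if (!is.null(hmm$calibration) && hmm$calibration$lambda <= 0)
    stopf("calibrated lambda must be > 0")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s': %d match states%s\n", x$name, x$M,
              if (is.null(x$calibration)) " (uncalibrated)"
              else sprintf(" (Gumbel mu=%.3f, lambda=%.4f)",
                           x$calibration$mu, x$calibration$lambda)))
  invisible(x)
}

#' Consensus peptide of a profile HMM
#'
#' Most probable residue of each match state.
#'
#' @param hmm A `profile_hmm`.
#' @return Character scalar of length `M`.
#' @export
consensus_peptide <- function(hmm) {
  paste(AA_ALPHABET[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

# --- scoring -----------------------------------------------------------------

# precompute the C-side representation: log-odds emissions (rows = match
# state, col j = residue code j-1, code 0 = unknown -> log-odds 0) and log2
# transitions.
hmm_scan_form <- function(hmm) {
  lo <- log2(hmm$match_emissions / rep(hmm$background, each = hmm$M))
  lo <- cbind(0, lo)  # code 0 (X / unknown) emits at background odds
  ltr <- log2(hmm$transitions)
  list(M = as.integer(hmm$M), lo = lo, ltr = ltr,
       log2_entry = -log2(hmm$M))
}

#' Local forward bit score
#'
#' Log2 likelihood ratio of the local-alignment forward sum (entry to any
#' match state with uniform weight, exit from any match state, flanks emitted
#' by the background null) against the all-background null.
#'
#' @param hmm A `profile_hmm`.
#' @param peptide Character scalar (length >= 1). Residues outside the
#'   20-letter alphabet emit at background odds.
#' @return Bit score (finite scalar).
#' @export
score_forward <- function(hmm, peptide) {
  validate_hmm(hmm)
  if (!nzchar(peptide)) stopf("empty peptide")
  sf <- hmm_scan_form(hmm)
  cpp_forward_one(peptide, sf$M, sf$lo, sf$ltr, sf$log2_entry)
}

#' Local Viterbi bit score with envelope
#'
#' Best single local alignment path under the same state model as
#' [score_forward()].
#'
#' @inheritParams score_forward
#' @return List with `score` (bits), `env_start`, `env_end` (0-based half-open
#'   peptide envelope of emitted residues on the optimal path) and `k_start`,
#'   `k_end` (1-based inclusive span of matched match states).
#' @export
score_viterbi <- function(hmm, peptide) {
  validate_hmm(hmm)
  if (!nzchar(peptide)) stopf("empty peptide")
  sf <- hmm_scan_form(hmm)
  v <- cpp_viterbi_one(peptide, sf$M, sf$lo, sf$ltr, sf$log2_entry)
  list(score = v$score, env_start = v$env_start, env_end = v$env_end,
       k_start = v$k_start, k_end = v$k_end)
}

# Viterbi scores only, for a batch of peptides (used by calibration)
viterbi_scores <- function(hmm, peptides) {
  sf <- hmm_scan_form(hmm)
  cpp_viterbi_batch(peptides, sf$M, sf$lo, sf$ltr, sf$log2_entry)
}

# --- calibration -------------------------------------------------------------

# Maximum-likelihood Gumbel fit (location mu, scale lambda as the inverse
# scale: F(s) = exp(-exp(-lambda (s - mu)))).
gumbel_mle <- function(x) {
  if (stats::sd(x) < 1e-12) stopf("degenerate calibration scores")
  f <- function(lam) {
    w <- exp(-lam * (x - max(x)))
    mean(x) - sum(x * w) / sum(w) - 1 / lam
  }
  lam0 <- pi / (sqrt(6) * stats::sd(x))  # method-of-moments start
  lo <- lam0 / 50; hi <- lam0 * 50
  lam <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
                  error = function(e) NA_real_)
  if (!is.finite(lam) || lam <= 0) stopf("degenerate Gumbel fit (lambda <= 0)")
  mu <- max(x) - log(mean(exp(-lam * (x - max(x))))) / lam
  list(mu = mu, lambda = lam)
}

#' Sample background peptides
#'
#' @param n Number of peptides.
#' @param len Peptide length.
#' @param background Length-20 residue distribution (default uniform).
#' @return Character vector of `n` peptides.
#' @export
sample_background_peptides <- function(n, len, background = rep(1 / 20, 20)) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE, prob = background),
          collapse = "")
  }, character(1))
}

#' Calibrate Gumbel E-value parameters by simulation
#'
#' Draws `n_cal` i.i.d. background peptides of length `len_cal`, scores them
#' with local Viterbi, and fits a Gumbel null by maximum likelihood. The fit
#' is deterministic given `seed`, which is recorded in the model.
#'
#' @param hmm A `profile_hmm`.
#' @param n_cal Number of calibration peptides (>= 50; default 200).
#' @param len_cal Calibration peptide length (default 400).
#' @param seed Integer seed.
#' @return The `profile_hmm` with `calibration = list(mu, lambda, n_cal,
#'   len_cal, seed)`.
#' @export
calibrate_hmm <- function(hmm, n_cal = 200, len_cal = 400, seed = 1) {
  validate_hmm(hmm)
  if (n_cal < 50) stopf("n_cal must be >= 50")
  peps <- with_seed(seed,
    sample_background_peptides(n_cal, len_cal, hmm$background))
  fit <- gumbel_mle(viterbi_scores(hmm, peps))
  hmm$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                          n_cal = n_cal, len_cal = len_cal, seed = seed)
  validate_hmm(hmm)
  hmm
}

#' Gumbel E-value of a bit score
#'
#' `E = n_targets * (1 - exp(-exp(-lambda (score - mu))))`, the expected
#' number of targets scoring at least `score` in a search of `n_targets`
#' background sequences under the fitted null.
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param score Bit score(s).
#' @param n_targets Number of target sequences in the search (default 1).
#' @return E-value(s), `>= 0`.
#' @export
evalue <- function(hmm, score, n_targets = 1) {
  cal <- hmm$calibration
  if (is.null(cal)) stopf("model '%s' is not calibrated", hmm$name)
  n_targets * (-expm1(-exp(-cal$lambda * (score - cal$mu))))
}

# --- library -----------------------------------------------------------------

#' Combine per-domain models into an HMM library
#'
#' @param models List of calibrated or uncalibrated `profile_hmm` objects.
#' @param order Expected architecture order of model names; defaults to the
#'   models' own order.
#' @return Object of class `hmm_library`.
#' @export
hmm_library <- function(models, order = NULL) {
  nm <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stopf("duplicate model names in library")
  names(models) <- nm
  if (is.null(order)) order <- nm
  if (!all(order %in% nm)) stopf("order refers to unknown model names")
  structure(list(models = models, order = order), class = "hmm_library")
}

#' @export
print.hmm_library <- function(x, ...) {
  cat(sprintf("HMM library (%d models), architecture order: %s\n",
              length(x$models), paste(x$order, collapse = " -> ")))
  for (m in x$models) print(m)
  invisible(x)
}

# --- serialization -----------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

write_hmm_block <- function(hmm, con) {
  writeLines(c("MODEL", paste("name", hmm$name), paste("M", hmm$M),
               paste("match_gap_frac", fmt_num(hmm$match_gap_frac %||% 0.5)),
               paste("pseudocount", fmt_num(hmm$pseudocount %||% 5)),
               paste("background", paste(fmt_num(hmm$background), collapse = " ")),
               paste("insert_emissions",
                     paste(fmt_num(hmm$insert_emissions), collapse = " "))), con)
  writeLines("match_emissions", con)
  writeLines(apply(hmm$match_emissions, 1,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines("transitions", con)
  writeLines(apply(hmm$transitions, 1,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  if (is.null(hmm$calibration)) {
    writeLines("calibration none", con)
  } else {
    cal <- hmm$calibration
    writeLines(paste("calibration", fmt_num(cal$mu), fmt_num(cal$lambda),
                     cal$n_cal, cal$len_cal, fmt_num(cal$seed)), con)
  }
  writeLines("ENDMODEL", con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a profile HMM or HMM library to a plain-text model file
#'
#' The format stores name, state count, background, emission and transition
#' tables and the calibration block (mu, lambda, n_cal, len_cal, seed) with 17
#' significant digits, so [read_hmm()] round-trips bit-exactly.
#'
#' @param x A `profile_hmm` or `hmm_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (inherits(x, "profile_hmm")) {
    writeLines("tlpscan-hmm 1", con)
    write_hmm_block(x, con)
  } else if (inherits(x, "hmm_library")) {
    writeLines(c("tlpscan-hmmlib 1",
                 paste("order", paste(x$order, collapse = " "))), con)
    for (m in x$models) write_hmm_block(m, con)
  } else stopf("x must be a profile_hmm or hmm_library")
  invisible(path)
}

parse_hmm_block <- function(lines) {
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    sub(paste0("^", key, " "), "", ln)
  }
  M <- as.integer(kv("M"))
  bg <- as.numeric(strsplit(kv("background"), " ")[[1]])
  ins <- as.numeric(strsplit(kv("insert_emissions"), " ")[[1]])
  em_start <- which(lines == "match_emissions")[1] + 1
  em <- do.call(rbind, lapply(lines[em_start:(em_start + M - 1)],
                              function(l) as.numeric(strsplit(l, " ")[[1]])))
  colnames(em) <- AA_ALPHABET
  tr_start <- which(lines == "transitions")[1] + 1
  tr <- do.call(rbind, lapply(lines[tr_start:(tr_start + M - 1)],
                              function(l) as.numeric(strsplit(l, " ")[[1]])))
  colnames(tr) <- names(DEFAULT_TRANSITION_PRIOR)
  cal_line <- grep("^calibration", lines, value = TRUE)[1]
  cal <- NULL
  if (cal_line != "calibration none") {
    p <- strsplit(cal_line, " ")[[1]]
    cal <- list(mu = as.numeric(p[2]), lambda = as.numeric(p[3]),
                n_cal = as.integer(p[4]), len_cal = as.integer(p[5]),
                seed = as.numeric(p[6]))
  }
  structure(list(name = kv("name"), M = M, match_emissions = em,
                 insert_emissions = ins, transitions = tr, background = bg,
                 match_gap_frac = as.numeric(kv("match_gap_frac")),
                 pseudocount = as.numeric(kv("pseudocount")),
                 calibration = cal),
            class = "profile_hmm")
}

#' Read a profile HMM or HMM library from a model file
#'
#' @param path Path written by [write_hmm()].
#' @return A `profile_hmm` or `hmm_library` according to the file header.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  starts <- which(lines == "MODEL")
  ends <- which(lines == "ENDMODEL")
  models <- Map(function(s, e) parse_hmm_block(lines[(s + 1):(e - 1)]),
                starts, ends)
  if (grepl("^tlpscan-hmm ", header)) {
    return(validate_hmm(models[[1]]))
  }
  if (grepl("^tlpscan-hmmlib ", header)) {
    ord <- strsplit(sub("^order ", "", lines[2]), " ")[[1]]
    models <- lapply(models, validate_hmm)
    return(hmm_library(models, order = ord))
  }
  stopf("unrecognized model file header: %s", header)
}
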
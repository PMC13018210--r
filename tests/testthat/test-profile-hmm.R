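# Alignment slicing, HMM construction, local scoring against exhaustive
# enumeration, Gumbel calibration and E-values, and model serialization.

test_that("slice_alignment_by_reference maps residue coordinates to columns", {
  aln <- as_alignment(c(ref = "ACDEF", other = "AYDEF"))
  sl <- slice_alignment_by_reference(aln, "ref", 2, 4)
  expect_identical(unclass(sl), c(ref = "CDE", other = "YDE"))

  # gapped reference: residues 2..3 of "A-CD" are C (col 3) and D (col 4)
  aln2 <- as_alignment(c(ref = "A-CD", other = "AWCD"))
  sl2 <- slice_alignment_by_reference(aln2, "ref", 2, 3)
  expect_identical(unclass(sl2), c(ref = "CD", other = "CD"))

  # reference-gap columns between the end residues are retained
  aln3 <- as_alignment(c(ref = "AC-DF", other = "ACWDF"))
  sl3 <- slice_alignment_by_reference(aln3, "ref", 2, 3)
  expect_identical(unclass(sl3), c(ref = "C-D", other = "CWD"))

  expect_error(slice_alignment_by_reference(aln, "ref", 2, 99), "only 5")
  expect_error(slice_alignment_by_reference(aln, "nope", 1, 2), "not found")
})

test_that("splitting the superfold fixture at the domain boundaries gives 3 alignments", {
  aln <- get_superfold_aln()
  bounds <- list(c(673, 928), c(929, 1255), c(1256, 2139))
  subs <- lapply(bounds, function(b)
    slice_alignment_by_reference(aln, "REF_superfold", b[1], b[2]))
  expect_length(subs, 3)
  # reference rows of the slices, ungapped, partition residues 673..2139
  ref_res <- gsub("-", "", vapply(subs, function(s) s[["REF_superfold"]],
                                  character(1)))
  expect_identical(nchar(ref_res), c(256L, 327L, 884L))
})

test_that("build_hmm handles degenerate and threshold cases", {
  # single ungapped sequence: M = L, emission maximal at the observed residue
  expect_warning(h <- build_hmm(as_alignment(c(s = "ACDE")), "solo"),
                 "single")
  expect_identical(h$M, 4L)
  expect_identical(AA_ALPHABET[apply(h$match_emissions, 1, which.max)],
                   c("A", "C", "D", "E"))

  # a column gapped in 2 of 3 rows (gap fraction 0.67 >= 0.5) is not a match
  aln <- as_alignment(c(a = "AC", b = "A-", c = "A-"))
  h2 <- build_hmm(aln, "thr")
  expect_identical(h2$M, 1L)

  expect_error(build_hmm(as_alignment(c(a = "-", b = "-")), "none"),
               "zero match columns")
})

test_that("build_hmm emissions and transitions equal hand-computed pseudocount values", {
  # rows: "ACD" and "A-D"; column 2 has gap fraction 0.5 -> insert column.
  # match states: columns 1 and 3. row 1 path: M1 I1 M2; row 2 path: M1 M2.
  aln <- as_alignment(c(r1 = "ACD", r2 = "A-D"))
  h <- build_hmm(aln, "toy")
  expect_identical(h$M, 2L)
  A <- 5; b <- 1 / 20
  # emissions, state 1: two A observed
  exp_e1 <- rep(A * b / (2 + A), 20); exp_e1[1] <- (2 + A * b) / (2 + A)
  expect_equal(unname(h$match_emissions[1, ]), exp_e1, tolerance = 1e-12)
  # emissions, state 2: two D observed
  exp_e2 <- rep(A * b / (2 + A), 20); exp_e2[3] <- (2 + A * b) / (2 + A)
  expect_equal(unname(h$match_emissions[2, ]), exp_e2, tolerance = 1e-12)
  # transitions out of state 1: counts mm=1 (r2), mi=1 (r1); prior (.9,.05,.05)*A
  expect_equal(unname(h$transitions[1, c("mm", "mi", "md")]),
               c((1 + A * 0.9) / (2 + A), (1 + A * 0.05) / (2 + A),
                 (0 + A * 0.05) / (2 + A)), tolerance = 1e-12)
  # insert transitions at state 1: one observed I->M; prior (.5,.5)*A
  expect_equal(unname(h$transitions[1, c("im", "ii")]),
               c((1 + A * 0.5) / (1 + A), (0 + A * 0.5) / (1 + A)),
               tolerance = 1e-12)
})

test_that("built models are normalized", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(2:8, 1); L <- sample(5:40, 1)
    rows <- vapply(seq_len(n), function(i) {
      chars <- sample(c(AA_ALPHABET, "-"), L, replace = TRUE,
                      prob = c(rep(0.9 / 20, 20), 0.1))
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- sprintf("s%d", seq_len(n))
    aln <- as_alignment(rows)
    h <- tryCatch(build_hmm(aln, "rand"), error = function(e) NULL)
    if (is.null(h)) next  # all-gap columns only
    expect_silent(validate_hmm(h))
    expect_equal(rowSums(h$match_emissions), rep(1, h$M), tolerance = 1e-9)
  }
})

test_that("forward and Viterbi match exhaustive path enumeration (M <= 3, |pep| <= 4)", {
  set.seed(22)
  for (M in 1:3) {
    for (rep in 1:3) {
      hmm <- random_toy_hmm(M, seed = 100 * M + rep)
      for (L in 1:4) {
        for (r in 1:4) {
          pep <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
          o <- oracle_scores(hmm, pep)
          expect_equal(score_forward(hmm, pep), o$forward, tolerance = 1e-9)
          expect_equal(score_viterbi(hmm, pep)$score, o$viterbi,
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("forward score is at least the Viterbi score", {
  set.seed(23)
  for (r in 1:100) {
    hmm <- random_toy_hmm(sample(2:12, 1), seed = 5000 + r)
    pep <- paste(sample(AA_ALPHABET, sample(5:40, 1), replace = TRUE),
                 collapse = "")
    expect_gte(score_forward(hmm, pep) + 1e-9, score_viterbi(hmm, pep)$score)
  }
})

test_that("model-emitted peptides outscore their shuffles nearly always", {
  aln <- get_superfold_aln()
  sub <- slice_alignment_by_reference(aln, "REF_superfold", 673, 928)
  hmm <- build_hmm(sub, "FN-plug")
  cons <- consensus_peptide(hmm)
  set.seed(24)
  wins <- 0
  for (r in 1:100) {
    shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    if (score_forward(hmm, cons) > score_forward(hmm, shuf)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("consensus Viterbi alignment spans the whole model", {
  hmm <- consensus_toy_hmm("ACDEF")
  v <- score_viterbi(hmm, "ACDEF")
  expect_identical(c(v$k_start, v$k_end), c(1L, 5L))
  expect_identical(c(v$env_start, v$env_end), c(0L, 5L))
})

test_that("consensus dominates random equal-length peptides under Viterbi", {
  hmm <- random_toy_hmm(10, seed = 31)
  cons <- consensus_peptide(hmm)
  best_random <- max(viterbi_scores(
    hmm, with_seed(32, sample_background_peptides(1000, nchar(cons)))))
  expect_gt(score_viterbi(hmm, cons)$score, best_random)
})

test_that("an HMM rebuilt from many sampled sequences recovers its emissions", {
  truth <- consensus_toy_hmm(paste(rep(c("A", "C", "D", "W"), 3), collapse = ""),
                             em_peak = 0.9, mm = 1 - 1e-9)
  seqs <- with_seed(33, vapply(1:200, function(i) emit_from_hmm(truth),
                               character(1)))
  expect_true(all(nchar(seqs) == truth$M))  # mm ~ 1: no indels sampled
  names(seqs) <- sprintf("s%03d", 1:200)
  rebuilt <- build_hmm(as_alignment(seqs), "rebuilt")
  expect_identical(rebuilt$M, truth$M)
  l1 <- rowSums(abs(rebuilt$match_emissions - truth$match_emissions))
  expect_true(all(l1 <= 0.15))
})

test_that("calibration is deterministic and E-values behave", {
  hmm <- random_toy_hmm(15, seed = 41)
  c1 <- calibrate_hmm(hmm, n_cal = 60, len_cal = 100, seed = 7)
  c2 <- calibrate_hmm(hmm, n_cal = 60, len_cal = 100, seed = 7)
  expect_identical(c1$calibration, c2$calibration)
  expect_error(calibrate_hmm(hmm, n_cal = 10), "n_cal")

  # E strictly decreasing in score (above the saturation region E ~ n)
  s <- seq(c1$calibration$mu, c1$calibration$mu + 30, length.out = 50)
  expect_true(all(diff(evalue(c1, s)) < 0))
  # closed form at score = mu, and exact linear scaling in n_targets
  expect_equal(evalue(c1, c1$calibration$mu, 1), 1 - exp(-1),
               tolerance = 1e-12)
  s0 <- c1$calibration$mu + 12
  expect_equal(evalue(c1, s0, 2), 2 * evalue(c1, s0, 1), tolerance = 1e-12)
  expect_error(evalue(hmm, 10), "not calibrated")
})

test_that("E-value equals numeric integration of the fitted Gumbel tail", {
  hmm <- calibrate_hmm(random_toy_hmm(10, seed = 42), seed = 9)
  mu <- hmm$calibration$mu; lam <- hmm$calibration$lambda
  dens <- function(s) lam * exp(-lam * (s - mu)) * exp(-exp(-lam * (s - mu)))
  for (s0 in mu + c(0, 2, 5, 8)) {
    tail <- stats::integrate(dens, s0, Inf, rel.tol = 1e-10)$value
    expect_equal(evalue(hmm, s0, 1), tail, tolerance = 1e-6)
  }
})

test_that("held-out background exceedance matches the fitted 1% tail", {
  aln <- get_superfold_aln()
  sub <- slice_alignment_by_reference(aln, "REF_superfold", 929, 1255)
  hmm <- calibrate_hmm(build_hmm(sub, "NHL"), n_cal = 200, len_cal = 400,
                       seed = 55)
  cal <- hmm$calibration
  s_star <- cal$mu - log(-log(1 - 0.01)) / cal$lambda  # P(S >= s*) = 0.01
  held <- with_seed(56, sample_background_peptides(500, 400))
  k <- sum(viterbi_scores(hmm, held) >= s_star)
  ci <- stats::qbinom(c(0.005, 0.995), 500, 0.01)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("unrelated homopolymer peptides are nowhere near significance", {
  lib <- get_superfold_lib()
  hmm <- lib$models[["FN-plug"]]
  polyA <- strrep("A", 400)
  E <- evalue(hmm, score_viterbi(hmm, polyA)$score, 1)
  expect_gt(E, 1e-3)  # far from the E <= 1e-10 shortlist
})

test_that("model files round-trip bit-exactly, singly and as a library", {
  hmm <- calibrate_hmm(random_toy_hmm(7, seed = 61), n_cal = 50,
                       len_cal = 80, seed = 3)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(hmm, f)
  back <- read_hmm(f)
  expect_identical(back$match_emissions, hmm$match_emissions)
  expect_identical(back$transitions, hmm$transitions)
  expect_identical(back$calibration$mu, hmm$calibration$mu)
  expect_identical(back$calibration$lambda, hmm$calibration$lambda)

  lib <- hmm_library(list(hmm, calibrate_hmm(random_toy_hmm(4, seed = 62,
                                                            name = "toy2"),
                                             n_cal = 50, len_cal = 80,
                                             seed = 4)))
  f2 <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(lib, f2)
  lib2 <- read_hmm(f2)
  expect_identical(lib2$order, lib$order)
  expect_identical(lib2$models[["toy"]]$match_emissions,
                   lib$models[["toy"]]$match_emissions)
  # a rewrite of the reread library is byte-identical
  f3 <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(lib2, f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("stockholm and aligned-FASTA alignment import agree", {
  rows <- c(seq1 = "AC-DE", seq2 = "ACWDE")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(as_alignment(rows), fa)
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "seq1 AC-DE", "seq2 ACWDE", "//"), sto)
  expect_identical(read_alignment(fa, "fasta"),
                   read_alignment(sto, "stockholm"))
})
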
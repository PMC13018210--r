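# RHS cleavage motifs, CTD extraction, hydropathy/TM calling, and mass.

test_that("the simple PxxxxDPxG motif is found, including overlaps", {
  expect_identical(scan_simple_motif("PAAAADPAG")$start, 1L)
  expect_identical(nrow(scan_simple_motif("AAAAAAAAA")), 0L)
  # overlapping instances are all reported: matches start at 1 and 5
  s2 <- "PAAAPDPAGDPAG"
  expect_identical(scan_simple_motif(s2)$start, c(1L, 5L))
  expect_identical(scan_simple_motif(s2)$d_pos, c(6L, 10L))
})

test_that("simple motif scan agrees with a pattern oracle on random sequences", {
  set.seed(81)
  for (r in 1:1000) {
    s <- paste(sample(AA_ALPHABET, 200, replace = TRUE,
                      prob = c(rep(1, 12), 4, 1, 1, 1, 1, 1, 1, 1) / 24),
               collapse = "")
    got <- scan_simple_motif(s)$start
    # oracle: slide a window and test the pattern positionally
    chars <- strsplit(s, "")[[1]]
    exp <- which(vapply(seq_len(200 - 8), function(i) {
      chars[i] == "P" && chars[i + 5] == "D" && chars[i + 6] == "P" &&
        chars[i + 8] == "G"
    }, logical(1)))
    expect_identical(got, as.integer(exp))
  }
})

test_that("bipartite motif requires exactly the configured spacer", {
  core <- paste0("DPAG", strrep("A", 18), "DPNG")
  s <- paste0("WWWW", core, "WWWW")
  h <- scan_bipartite_motif(s)
  expect_identical(nrow(h), 1L)
  expect_identical(h$d1_pos, 5L)
  expect_identical(h$d2_pos - h$d1_pos, 22L)
  expect_identical(h$first_motif_variant, "G")

  # G -> L substitution in the first tetrad is accepted and recorded
  hL <- scan_bipartite_motif(paste0("WW", "DPAL", strrep("C", 18), "DPNG"))
  expect_identical(hL$first_motif_variant, "L")
  hR <- scan_bipartite_motif(paste0("DPAR", strrep("C", 18), "DPNG"))
  expect_identical(hR$first_motif_variant, "R")
  # other substitutions are not
  expect_identical(
    nrow(scan_bipartite_motif(paste0("DPAW", strrep("C", 18), "DPNG"))), 0L)

  # 17- and 19-residue spacers do not match the default grammar
  expect_identical(
    nrow(scan_bipartite_motif(paste0("DPAG", strrep("A", 17), "DPNG"))), 0L)
  expect_identical(
    nrow(scan_bipartite_motif(paste0("DPAG", strrep("A", 19), "DPNG"))), 0L)
  # ... but a reconfigured spacer accepts them
  expect_identical(
    nrow(scan_bipartite_motif(paste0("DPAG", strrep("A", 17), "DPNG"),
                              spacer = 17)), 1L)
})

test_that("reported bipartite hits re-validate against the pattern", {
  set.seed(82)
  for (r in 1:200) {
    s <- paste(sample(AA_ALPHABET, 120, replace = TRUE), collapse = "")
    at <- sample(1:(120 - 25), 1)
    v <- sample(c("G", "L", "R"), 1)
    s <- paste0(substr(s, 1, at - 1), "DPQ", v, strrep("H", 18), "DPKG",
                substr(s, at + 26, 120))
    hits <- scan_bipartite_motif(s)
    expect_gte(nrow(hits), 1L)
    for (i in seq_len(nrow(hits))) {
      expect_identical(substr(s, hits$d1_pos[i], hits$d1_pos[i] + 1), "DP")
      expect_true(substr(s, hits$d1_pos[i] + 3, hits$d1_pos[i] + 3)
                  %in% c("G", "L", "R"))
      expect_identical(substr(s, hits$d2_pos[i], hits$d2_pos[i] + 1), "DP")
      expect_identical(substr(s, hits$d2_pos[i] + 3, hits$d2_pos[i] + 3), "G")
      expect_identical(hits$d2_pos[i] - hits$d1_pos[i], 22L)
    }
  }
})

test_that("CTD extraction follows the cleavage-site convention", {
  # second catalytic aspartate at the printed position 2140 -> CTD from 2145
  set.seed(83)
  s <- paste(sample(AA_ALPHABET, 2237, replace = TRUE), collapse = "")
  s <- paste0(substr(s, 1, 2117), "DPYL", strrep("Q", 18), "DPNG",
              substr(s, 2144, 2237))
  hit <- scan_bipartite_motif(s)
  expect_identical(hit$d2_pos, 2140L)
  rec <- extract_ctd(s, hit, parent_id = "ref")
  expect_identical(rec$ctd_start, 2145L)
  expect_identical(nchar(rec$sequence), 2237L - 2145L + 1L)

  # toy arithmetic: d2 = 10, length 30 -> CTD = residues 15..30 (16 aa)
  toy <- paste0("AAAAAAAAA", "DPAG", strrep("W", 17))
  rec2 <- extract_ctd(toy, list(d1_pos = NA, d2_pos = 10), "toy")
  expect_identical(rec2$ctd_start, 15L)
  expect_identical(rec2$sequence, substr(toy, 15, 30))
  expect_identical(nchar(rec2$sequence), 16L)

  # motif at the sequence end leaves no CTD
  expect_error(extract_ctd(substr(toy, 1, 13), list(d2_pos = 10), "x"),
               "empty")
})

test_that("CTD extraction partitions the parent exactly", {
  set.seed(84)
  for (r in 1:100) {
    n <- sample(60:400, 1)
    s <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    at <- sample(1:(n - 40), 1)
    s <- paste0(substr(s, 1, at - 1), "DPAG", strrep("S", 18), "DPTG",
                substr(s, at + 26, n))
    hit <- scan_bipartite_motif(s)
    hit <- hit[hit$d1_pos == at, ]
    rec <- extract_ctd(s, hit, "p")
    expect_identical(paste0(substr(s, 1, rec$ctd_start - 1), rec$sequence), s)
  }
})

test_that("hydropathy profile equals a windowed-mean oracle and calls TM runs", {
  # 30 Leu flanked by 30 Asp on each side: exactly one TM segment in the Leu
  s <- paste0(strrep("D", 30), strrep("L", 30), strrep("D", 30))
  r <- hydropathy_tm(s)
  expect_identical(nrow(r$tm_segments), 1L)
  expect_gte(r$tm_segments$start, 31L)
  expect_lte(r$tm_segments$end, 60L)

  expect_identical(nrow(hydropathy_tm(strrep("D", 80))$tm_segments), 0L)

  set.seed(85)
  for (rep in 1:20) {
    s <- paste(sample(AA_ALPHABET, sample(40:200, 1), replace = TRUE),
               collapse = "")
    prof <- hydropathy_tm(s)$profile
    vals <- KYTE_DOOLITTLE[strsplit(s, "")[[1]]]
    n <- length(vals)
    oracle <- rep(NA_real_, n)
    for (c in 10:(n - 9)) oracle[c] <- mean(vals[(c - 9):(c + 9)])
    expect_equal(prof, unname(oracle), tolerance = 1e-9)
  }
})

test_that("TM segment coordinates are translation-invariant", {
  s <- paste0(strrep("D", 40), strrep("I", 25), strrep("E", 40))
  base <- hydropathy_tm(s)$tm_segments
  shifted <- hydropathy_tm(paste0(strrep("G", 100), s))$tm_segments
  expect_identical(shifted$start, base$start + 100L)
  expect_identical(shifted$end, base$end + 100L)
})

test_that("molecular mass matches monomer arithmetic and a table oracle", {
  expect_equal(molecular_mass("G"), 0.07507, tolerance = 1e-4)
  expect_equal(molecular_mass("GG") * 1000, 132.12, tolerance = 1e-4)
  # independent residue-mass table (monoisotopic-independent, average masses)
  oracle_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  set.seed(86)
  batch <- vapply(1:100, function(i)
    paste(sample(AA_ALPHABET, 100, replace = TRUE), collapse = ""),
    character(1))
  got <- mean(vapply(batch, molecular_mass, numeric(1)))
  exp <- mean(vapply(batch, function(s) {
    (sum(oracle_mass[strsplit(s, "")[[1]]]) + 18.01528) / 1000
  }, numeric(1)))
  expect_equal(got, exp, tolerance = 1e-6)
})

test_that("annotate_rhs_ctd derives CTD records for motif-bearing proteins", {
  set.seed(87)
  good <- paste0(paste(sample(AA_ALPHABET, 150, replace = TRUE), collapse = ""),
                 "DPAL", strrep("N", 18), "DPQG",
                 paste(sample(AA_ALPHABET, 120, replace = TRUE), collapse = ""))
  plain <- paste(sample(setdiff(AA_ALPHABET, "D"), 200, replace = TRUE),
                 collapse = "")
  res <- annotate_rhs_ctd(c(tox = good, dull = plain))
  expect_true("tox" %in% names(res$ctds))
  expect_false("dull" %in% names(res$ctds))
  # d1 at 151, d2 at 151 + 22 = 173, CTD from 173 + 5 = 178
  expect_identical(res$ctds$tox$ctd_start, 151L + 22L + 5L)
  expect_gt(res$ctds$tox$mass_kDa, 0)
})
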
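# Hit filtering, the three-domain architecture rule, downstream ORFs, and
# prevalence summaries.

# hand-built hit rows for pure architecture-filter tests
mk_hit <- function(model, pep_start, pep_end, genome_id = "g1", frame = "+1",
                   segment = 1L, strand = "+", score = 100) {
  data.frame(genome_id = genome_id, model = model, frame = frame,
             segment = segment, pep_start = pep_start, pep_end = pep_end,
             gstart = 3L * (pep_start - 1L) + 1L, gend = 3L * pep_end,
             strand = strand, score = score, evalue = 1e-30,
             model_cov = 1, k_start = 1L, k_end = 10L,
             stringsAsFactors = FALSE)
}

test_that("scan_frames applies the E-value threshold at the boundary", {
  lib <- get_superfold_lib()
  # a partial NHL fragment gives a solid but non-underflowing E-value
  cons <- consensus_peptide(lib$models[["NHL"]])
  frag <- substr(cons, 1, ceiling(0.4 * nchar(cons)))
  sf <- six_frame_translate(reverse_translate(frag, seed = 70), id = "frag")
  hits <- scan_frames(lib, sf, E_max = 1)
  nhl <- hits[hits$model == "NHL", ]
  expect_identical(nrow(nhl), 1L)
  expect_gt(nhl$evalue, 0)
  # inclusion is decided by comparison against E_max
  incl <- scan_frames(lib, sf, E_max = nhl$evalue * 2)
  expect_identical(nrow(incl[incl$model == "NHL", ]), 1L)
  excl <- scan_frames(lib, sf, E_max = nhl$evalue / 2)
  expect_identical(nrow(excl[excl$model == "NHL", ]), 0L)
  # default thresholds are the shortlisting values of the screen
  expect_identical(formals(scan_frames)$E_max, 1e-10)
  expect_identical(formals(scan_frames)$min_model_cov, 0.30)
})

test_that("a consensus-emitted FN-plug peptide is retained with high coverage", {
  lib <- get_superfold_lib()
  cons <- consensus_peptide(lib$models[["FN-plug"]])
  dna <- reverse_translate(cons, seed = 71)
  sf <- six_frame_translate(dna, id = "cons")
  hits <- scan_frames(lib, sf)
  fn <- hits[hits$model == "FN-plug", ]
  expect_identical(nrow(fn), 1L)
  expect_gte(fn$model_cov, 0.30)
  expect_lte(fn$evalue, 1e-10)
})

test_that("call_architecture accepts in-order triples and rejects violations", {
  ordered <- rbind(mk_hit("FN-plug", 1, 250), mk_hit("NHL", 260, 580),
                   mk_hit("YD-shell", 600, 1450))
  loci <- call_architecture(ordered)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$copy_index, 1L)
  expect_identical(loci$gstart, min(ordered$gstart))
  expect_identical(loci$gend, max(ordered$gend))

  # wrong order: YD, NHL, FN
  wrong <- rbind(mk_hit("YD-shell", 1, 850), mk_hit("NHL", 860, 1180),
                 mk_hit("FN-plug", 1190, 1440))
  expect_identical(nrow(call_architecture(wrong)), 0L)

  # frame violation: YD-shell on another frame/segment
  split_frame <- rbind(mk_hit("FN-plug", 1, 250), mk_hit("NHL", 260, 580),
                       mk_hit("YD-shell", 600, 1450, frame = "-2",
                              strand = "-"))
  expect_identical(nrow(call_architecture(split_frame)), 0L)

  # adjacency violation: NHL -> YD gap beyond max_gap
  gappy <- rbind(mk_hit("FN-plug", 1, 250), mk_hit("NHL", 260, 580),
                 mk_hit("YD-shell", 1000, 1850))
  expect_identical(nrow(call_architecture(gappy, max_gap = 300)), 0L)
  expect_identical(nrow(call_architecture(gappy, max_gap = 500)), 1L)

  expect_identical(nrow(call_architecture(ordered[0, ])), 0L)
})

test_that("overlapping candidate triples resolve greedily by combined score", {
  # two FN-plug candidates for the same downstream pair; the stronger wins
  hits <- rbind(mk_hit("FN-plug", 1, 250, score = 80),
                mk_hit("FN-plug", 20, 270, score = 120),
                mk_hit("NHL", 280, 600, score = 100),
                mk_hit("YD-shell", 610, 1460, score = 300))
  loci <- call_architecture(hits)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$combined_score, 520)
  expect_identical(loci$d1_gstart, mk_hit("FN-plug", 20, 270)$gstart)
})

test_that("two planted cassettes on opposite strands are recovered near-exactly", {
  scene <- get_two_cassette_scene()
  loci <- call_architecture(scan_frames(get_superfold_lib(), scene$frames))
  truth <- truth_elements(scene$bench$truth)
  expect_identical(nrow(loci), 2L)
  expect_setequal(loci$strand, truth$strand)
  # local alignment may trim a few weakly matching terminal residues of a
  # sampled domain, so locus ends are recovered to within a few codons
  for (i in 1:2) {
    overlap <- pmin(loci$gend, truth$end[i]) - pmax(loci$gstart, truth$start[i])
    j <- which.max(overlap)
    expect_identical(loci$strand[j], truth$strand[i])
    expect_lte(abs(loci$gstart[j] - truth$start[i]), 12)
    expect_lte(abs(loci$gend[j] - truth$end[i]), 12)
  }
})

test_that("find_downstream_orf reports a planted same-strand ORF first", {
  set.seed(72)
  # locus at [1001, 1300] on +; plant ATG + 90 codons + stop 200 nt downstream
  g <- random_dna_str(5000)
  orf <- paste0("ATG", reverse_translate(paste(
    sample(AA_ALPHABET, 90, replace = TRUE), collapse = "")), "TAA")
  start_orf <- 1300L + 200L + 1L
  g <- paste0(substr(g, 1, start_orf - 1), orf,
              substr(g, start_orf + nchar(orf), nchar(g)))
  locus <- list(gstart = 1001L, gend = 1300L, strand = "+")
  found <- find_downstream_orf(locus, g, window = 5000, min_orf = 150)
  expect_gte(nrow(found), 1L)
  expect_identical(found$start[1], start_orf)
  expect_identical(found$end[1], start_orf + nchar(orf) - 1L)
  expect_identical(found$strand[1], "+")

  # no ATG downstream -> empty
  g2 <- paste0(substr(g, 1, 1300), strrep("C", 2000))
  found2 <- find_downstream_orf(list(gstart = 1001L, gend = 1300L,
                                     strand = "+"), g2, window = 1500)
  expect_identical(nrow(found2), 0L)
})

test_that("downstream ORF detection agrees with a codon-walk oracle", {
  set.seed(73)
  for (rep in 1:50) {
    g <- random_dna_str(3000)
    locus <- list(gstart = 101L, gend = 400L, strand = "+")
    got <- find_downstream_orf(locus, g, window = 1000, min_orf = 60)
    sub <- substr(g, 401, 3000)
    exp <- oracle_orfs(sub, min_orf = 60)
    exp <- exp[exp$start <= 1000, , drop = FALSE]
    expect_identical(sort(got$start), as.integer(sort(exp$start + 400)))
    expect_identical(sort(got$end), as.integer(sort(exp$end + 400)))
  }
})

test_that("reverse-strand ORF search mirrors the forward search", {
  set.seed(74)
  g <- random_dna_str(4000)
  rc <- oracle_revcomp(g)
  fwd <- find_downstream_orf(list(gstart = 101L, gend = 600L, strand = "+"),
                             g, window = 800, min_orf = 90)
  # same locus on the mirrored genome, reverse strand
  rev <- find_downstream_orf(list(gstart = 4000L - 600L + 1L,
                                  gend = 4000L - 101L + 1L, strand = "-"),
                             rc, window = 800, min_orf = 90)
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(sort(4000L - fwd$end + 1L), sort(rev$start))
  expect_identical(sort(4000L - fwd$start + 1L), sort(rev$end))
})

test_that("summarize_prevalence computes percentages and copy numbers", {
  md <- data.frame(genome_id = sprintf("g%02d", 1:10),
                   species = sprintf("sp%02d", 1:10),
                   taxon_group = "X")
  loci <- data.frame(genome_id = c("g01", "g01", "g02"))
  s <- summarize_prevalence(loci, md)
  expect_identical(s$by_taxon$genomes_screened, 10L)
  expect_identical(s$by_taxon$genomes_positive, 2L)
  expect_identical(s$by_taxon$pct_positive, 20)
  expect_identical(s$multi_copy, "g01")
  expect_identical(sum(s$copy_number$Freq), 2L)

  s0 <- summarize_prevalence(loci[0, , drop = FALSE], md)
  expect_identical(s0$by_taxon$pct_positive, 0)
})

test_that("prevalence on the benchmark equals truth-table tallies", {
  bench <- get_benchmark()
  loci <- get_benchmark_loci()
  s <- summarize_prevalence(loci, bench$metadata)
  truth <- truth_elements(bench$truth)
  truth_counts <- table(factor(truth$genome_id,
                               levels = bench$metadata$genome_id))
  expect_identical(s$per_genome$n_loci, as.integer(truth_counts))
  expect_identical(sum(s$by_taxon$genomes_positive),
                   sum(truth_counts > 0))
})

test_that("stricter thresholds never increase the locus count", {
  lib <- get_superfold_lib()
  scene <- get_two_cassette_scene()
  base <- nrow(call_architecture(scan_frames(lib, scene$frames)))
  for (args in list(list(E_max = 1e-30), list(min_model_cov = 0.8),
                    list(E_max = 1e-50, min_model_cov = 0.9))) {
    n <- nrow(call_architecture(do.call(scan_frames,
                                        c(list(lib, scene$frames), args))))
    expect_lte(n, base)
  }
})

test_that("disabling the prefilter leaves the hit table unchanged", {
  lib <- get_superfold_lib()
  scene <- get_two_cassette_scene()
  with_f <- scan_frames(lib, scene$frames)
  without_f <- scan_frames(lib, scene$frames, filter_bits = -Inf)
  attr(with_f, "n_targets") <- NULL; attr(without_f, "n_targets") <- NULL
  expect_identical(with_f, without_f)
})
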
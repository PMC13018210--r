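Package: tlpscan
Title: Profile-HMM Screening and Annotation of Bacterial Teneurin-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-screening and sequence-analysis toolkit for bacterial
    Teneurin-like proteins (TLPs). Builds per-domain profile hidden Markov
    models (FN-plug, NHL beta-propeller, YD-repeat shell) from a superfold
    multiple sequence alignment split at reference residue boundaries, scans
    six-frame-translated genome assemblies with local Viterbi/forward scoring
    and simulation-calibrated Gumbel E-values, and applies a three-domain
    architecture filter (same reading frame, correct order, bounded gaps) to
    call TLP loci. Also annotates RHS core cleavage motifs (PxxxxDPxG and the
    bipartite DPxG-X18-DPxG with G-to-L/R first-motif variants), derives
    C-terminal toxin domain records with Kyte-Doolittle hydropathy and mass,
    detects candidate downstream immunity open reading frames, summarizes
    prevalence and copy number by taxon, and computes a membrane-deformation
    statistic (mean absolute dot product of patchwise surface normals with the
    z axis) for coordinate frames. A synthetic-genome generator with planted
    cassettes and decoys provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
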
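#!/usr/bin/env Rscript
# Step 4 -- RHS cleavage motifs and the C-terminal toxin domain.
#
# Annotates the synthetic reference protein (the ungapped reference row of
# the superfold alignment): finds the simple PxxxxDPxG and bipartite
# DPx[G/L/R]-X18-DPxG cleavage motifs, derives the CTD downstream of the
# cleavage site, and reports its mass and Kyte-Doolittle
# hydropathy-predicted transmembrane segment.

suppressPackageStartupMessages(library(tlpscan))

aln <- read_alignment("results/benchmark/superfold_alignment.fasta")
ref <- gsub("-", "", aln[["REF_superfold"]])
message(sprintf("Reference protein: %d residues", nchar(ref)))

ann <- annotate_rhs_ctd(c(REF_superfold = ref))
write.table(ann$motifs, "results/rhs_motifs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
bip <- ann$motifs[ann$motifs$pattern_id == "bipartite", ]
message(sprintf("Bipartite RHS motif: D1 at %d, D2 at %d (%s)",
                bip$start[1], bip$d_pos[1], bip$detail[1]))

ctd <- ann$ctds$REF_superfold
print(ctd)
message(sprintf("CTD starts at residue %d (cleavage after the second DPxG tetrad); mass %.2f kDa",
                ctd$ctd_start, ctd$mass_kDa))
if (nrow(ctd$tm_segments)) {
  seg <- ctd$tm_segments
  message(sprintf("Hydropathy-predicted TM segment at parent residues %d-%d",
                  seg$start[1] + ctd$ctd_start - 1L,
                  seg$end[1] + ctd$ctd_start - 1L))
}
write_fasta(setNames(ctd$sequence,
                     sprintf("REF_superfold_CTD start=%d", ctd$ctd_start)),
            "results/ctd.fasta")
message("Wrote results/rhs_motifs.tsv and results/ctd.fasta")
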
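#!/usr/bin/env Rscript
# Step 3 -- the genome screen.
#
# Six-frame translates every benchmark genome, scans all stop-free peptide
# segments against the domain library (E <= 1e-10, model coverage >= 30%),
# assembles hits into TLP loci with the architecture filter (same reading
# frame, FN-plug -> NHL -> YD-shell order, bounded gaps), looks for
# downstream immunity-like ORFs, summarizes prevalence by taxon group, and
# checks the calls against the planted truth.

suppressPackageStartupMessages(library(tlpscan))

lib <- read_hmm("results/superfold_library.hmm")
genomes <- read_fasta("scratch/benchmark/genomes.fasta", type = "DNA")
metadata <- read_genome_metadata("results/benchmark/metadata.tsv")
truth <- read.delim("results/benchmark/truth.tsv")

message(sprintf("Translating %d genomes in six frames ...", length(genomes)))
frames <- lapply(names(genomes), function(id)
  six_frame_translate(genomes[[id]], id = id))

message("Scanning segments against the HMM library ...")
hits <- scan_frames(lib, frames)
message(sprintf("  %d domain hits passing E <= 1e-10 and coverage >= 30%% (of %d segments)",
                nrow(hits), attr(hits, "n_targets")))
write_hits_tsv(hits, "results/domain_hits.tsv")

loci <- call_architecture(hits)
loci_to_gff3(loci, "results/tlp_loci.gff3")
message(sprintf("  %d TLP loci pass the architecture filter", nrow(loci)))

# downstream immunity-candidate ORFs
orf_rows <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
  orfs <- find_downstream_orf(loci[i, ], genomes[[loci$genome_id[i]]])
  if (nrow(orfs) == 0) return(NULL)
  cbind(genome_id = loci$genome_id[i], copy_index = loci$copy_index[i],
        orfs[1, , drop = FALSE])
}))
write.table(orf_rows, "results/downstream_orfs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("  nearest downstream same-strand ORF found for %d / %d loci",
                nrow(orf_rows), nrow(loci)))

prev <- summarize_prevalence(loci, metadata)
write_prevalence_json(prev, "results/prevalence.json")
write.table(prev$by_taxon, "results/prevalence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(prev)

# --- comparison against planted truth --------------------------------------
cass <- truth[truth$kind == "cassette" & truth$part == "element", ]
recovered <- vapply(seq_len(nrow(cass)), function(i) {
  any(loci$genome_id == cass$genome_id[i] & loci$strand == cass$strand[i] &
        pmin(loci$gend, cass$end[i]) - pmax(loci$gstart, cass$start[i]) + 1 >=
          0.8 * (cass$end[i] - cass$start[i] + 1))
}, logical(1))
locus_true <- vapply(seq_len(nrow(loci)), function(i) {
  any(cass$genome_id == loci$genome_id[i] & cass$strand == loci$strand[i] &
        pmin(cass$end, loci$gend[i]) - pmax(cass$start, loci$gstart[i]) + 1 >=
          0.5 * (loci$gend[i] - loci$gstart[i] + 1))
}, logical(1))
message(sprintf("Sensitivity vs planted truth: %.3f (%d / %d cassettes)",
                mean(recovered), sum(recovered), nrow(cass)))
message(sprintf("Decoy/false loci: %d (must be 0: order, strand-split and partial decoys never assemble)",
                sum(!locus_true)))
write.table(data.frame(metric = c("sensitivity", "false_loci"),
                       value = c(mean(recovered), sum(!locus_true))),
            "results/screen_vs_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
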
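#!/usr/bin/env Rscript
# Step 1 -- synthetic study inputs.
#
# Generates the two inputs every later step consumes: (a) a superfold-like
# protein family alignment whose reference row carries the paper-style
# residue numbering (domain boundaries 673-928 / 929-1255 / 1256-2139, RHS
# bipartite motif at D2118/D2140, hydrophobic CTD stretch at 2165-2185), and
# (b) the fixed screening benchmark: 20 genomes x 200 kb with 30 planted
# three-domain cassettes, 30 decoys (wrong order / strand-split / partial)
# and downstream immunity-like ORFs, plus the ground-truth table.
#
# Small tables go to results/benchmark/; the bulky genome FASTA (4 Mb,
# regenerated deterministically from seed 1337) goes to scratch/benchmark/.

suppressPackageStartupMessages(library(tlpscan))

dir.create("results/benchmark", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/benchmark", showWarnings = FALSE, recursive = TRUE)

message("Simulating the superfold family alignment (seed 101) ...")
aln <- simulate_superfold_alignment(seed = 101)
write_alignment(aln, "results/benchmark/superfold_alignment.fasta")
message(sprintf("  %d rows x %d columns; reference 'REF_superfold' has %d residues",
                length(aln), nchar(aln[[1]]),
                nchar(gsub("-", "", aln[["REF_superfold"]]))))

message("Building the domain HMM library needed to sample cassettes ...")
lib <- build_superfold_library(aln)

message("Generating the fixed benchmark (seed 1337) ...")
cfg <- benchmark_config()
bench <- generate_benchmark(cfg, lib)
write_fasta(bench$genomes, "scratch/benchmark/genomes.fasta")
write.table(bench$metadata, "results/benchmark/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(bench$truth, "results/benchmark/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

elem <- bench$truth[bench$truth$part == "element", ]
message("Planted elements by kind:")
print(table(elem$kind))
message(sprintf("Wrote %d genomes (%.1f Mb), metadata and truth tables.",
                length(bench$genomes),
                sum(nchar(bench$genomes)) / 1e6))
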
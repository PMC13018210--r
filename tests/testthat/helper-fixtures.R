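# Shared fixtures, built once per test run and memoized. The superfold
# library and the fixed benchmark (20 genomes x 200 kb, 30 cassettes, 30
# decoys, seed 1337) are used by several files; building them lazily keeps
# unrelated test files fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

get_superfold_aln <- function() {
  memo("aln", simulate_superfold_alignment(seed = 101))
}

get_superfold_lib <- function() {
  memo("lib", build_superfold_library(get_superfold_aln()))
}

get_benchmark <- function() {
  memo("bench", generate_benchmark(benchmark_config(), get_superfold_lib()))
}

get_benchmark_frames <- function() {
  memo("frames", {
    bench <- get_benchmark()
    lapply(names(bench$genomes), function(id)
      six_frame_translate(bench$genomes[[id]], id = id))
  })
}

get_benchmark_hits <- function() {
  memo("hits", scan_frames(get_superfold_lib(), get_benchmark_frames()))
}

get_benchmark_loci <- function() {
  memo("loci", call_architecture(get_benchmark_hits()))
}

# a small positive-control scene: one genome with two planted cassettes on
# opposite strands (and nothing else), plus its truth
get_two_cassette_scene <- function() {
  memo("two_cassette", {
    cfg <- benchmark_config(n_genomes = 1, genome_length = 40000,
                            n_cassettes = 2, n_decoy_order = 0,
                            n_decoy_strand_split = 0, n_decoy_partial = 0,
                            plant_immunity_orf = FALSE, min_spacing = 1500,
                            seed = 42)
    bench <- generate_benchmark(cfg, get_superfold_lib())
    frames <- six_frame_translate(bench$genomes[[1]],
                                  id = names(bench$genomes)[1])
    list(bench = bench, frames = frames)
  })
}

# truth cassettes as one row per element
truth_elements <- function(truth, kind = "cassette") {
  truth[truth$kind == kind & truth$part == "element", , drop = FALSE]
}

# does a called locus table recover a truth element (same strand, >= frac
# reciprocal overlap of the truth span)?
recovers <- function(loci, g, s, e, st, frac = 0.8) {
  any(loci$genome_id == g & loci$strand == st &
        pmin(loci$gend, e) - pmax(loci$gstart, s) + 1 >= frac * (e - s + 1))
}
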
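---
title: "Methods: profile-HMM screening and annotation of bacterial Teneurin-like proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM screening and annotation of bacterial Teneurin-like proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bacterial Teneurin-like proteins (TLPs) are polymorphic toxins built around a
conserved three-domain "superfold" — an FN-plug, an NHL β-propeller, and a
large YD-repeat shell — that encapsulates a hypervariable C-terminal toxin
domain (CTD) released by autoproteolysis at an RHS-family cleavage motif.
`tlpscan` implements the computational side of a TLP genome screen and its
companion sequence and biophysics analyses as a tested, reusable package:

1. build one profile hidden Markov model (HMM) per superfold domain from a
   family alignment split at reference residue boundaries;
2. six-frame translate genome assemblies and score every stop-free peptide
   segment against the domain library with calibrated E-values;
3. keep only genomes where all three domains co-occur adjacently, in order,
   on the same reading frame (the architecture filter), and summarize
   prevalence and copy number by taxon;
4. annotate RHS cleavage motifs and CTDs (mass, hydropathy, candidate
   transmembrane stretch) and detect candidate downstream immunity genes;
5. quantify membrane deformation in coordinate frames exported from
   simulations via a patchwise surface-normal statistic.

Because the original screen ran over a dated snapshot of a very large genome
database, its headline counts are not reproducible at desk scale. The package
therefore ships a synthetic-genome generator that plants ground-truth
cassettes and decoys, so every stage is validated end to end against known
truth.

## Sequence handling (seqio)

Six conceptual translations are produced per genome record: frames `+1..+3`
read the forward strand at offsets 0–2, `-1..-3` read the reverse complement
at offsets 0–2. Trailing partial codons are dropped and codons containing `N`
translate to `X` (which is scored at background odds). The genetic code
defaults to the standard table, matching the default of the translation tool
the screening protocol names; the bacterial table 11 is selectable.

Each full-frame translation is split at stop codons into *segments*
(default minimum 30 aa). Stops have no amino-acid emission, and an in-frame
stop between two domains breaks a single open reading frame, so scanning
segments rather than whole frames implements the same-reading-frame
requirement structurally: two domains separated by a stop can never
co-localize.

Coordinates are 0-based half-open internally; every user-facing table, the
GFF3 export, and residue numbering in this vignette are 1-based inclusive,
matching how reference residue ranges such as 673–2139 are quoted in the
field. Reverse-strand features are reported on the forward strand with
`strand = "-"`, and `map_to_genome()` guarantees that re-translating a mapped
interval reproduces the peptide slice exactly (this round-trip is
property-tested on hundreds of random slices).

## Domain models (profile_hmm)

**Architecture.** Match states $M_1..M_M$ with 20-dimensional emissions,
insert states emitting the background distribution, and delete states, with
per-state transitions $\{M\!\to\!M, M\!\to\!I, M\!\to\!D, I\!\to\!M,
I\!\to\!I, D\!\to\!M, D\!\to\!D\}$. This is deliberately simpler than a full
Plan7 profile (no multi-hit J state, no composition filters); parity with
HMMER is a non-goal — what matters for the screen is a local domain score
with a calibrated tail.

**Construction.** Alignment columns with gap fraction < 0.5 become match
states. Emissions use background-mix pseudocounts,
$e_i(a) = (c_i(a) + A\,b(a)) / (C_i + A)$ with weight $A = 5$ (default
background: uniform 1/20). Transitions are estimated from the observed
per-row state paths with the same pseudocount form against a fixed prior
(0.9/0.05/0.05 for match, 0.5/0.5 for insert and delete). Observed
$I\!\to\!D$ / $D\!\to\!I$ adjacencies, which the seven-transition model
excludes, are counted toward $I\!\to\!M$ / $D\!\to\!M$. Insert emissions are
fixed to the background: at fixture scale there is too little data to
estimate them, and this choice makes inserts score-neutral.

**Scoring.** Local alignment semantics: entry into any match state with
uniform weight $1/M$, free exit from any match state, unaligned flanks
emitted by the background null so they cancel in the log-odds ratio. Scores
are bits. `score_forward()` is the log2 sum over all local paths;
`score_viterbi()` is the best single path and also returns the peptide
envelope and the matched model span. Both are verified against an exhaustive
enumeration of every local path on small instances ($M \le 3$, peptides
$\le 4$ aa) to 1e-9 bits, and forward ≥ Viterbi is property-tested.

**Calibration and E-values.** The screen's shortlist rule is an E-value
threshold, so each model carries an explicit, reproducible null: `n_cal`
(default 200) i.i.d. background peptides of `len_cal` (default 400) aa are
scored with Viterbi, and a Gumbel law
$F(s) = \exp(-e^{-\lambda (s - \mu)})$ is fitted by maximum likelihood. The
calibration seed is recorded in the model file, so calibration is
deterministic and serializes with the model. Then
$E(s) = n \cdot (1 - F(s))$ with $n$ = the number of segments scanned in the
run, a database-size correction in the spirit of large-database search
statistics. The fit is validated on held-out background: the empirical
exceedance of the fitted 1% tail quantile must fall inside a 99% binomial
confidence interval.

Viterbi is the hit statistic throughout (calibration and scanning use the
same statistic); the forward score is exposed for completeness and oracle
testing but takes no part in hit calling.

**Prefilter.** Scanning megabases of translated peptide against a
~1,500-state library is dominated by hopeless segments. A banded, ungapped
prefilter (the best run of consecutive match states, including entry weight
and $M\!\to\!M$ costs — a strict lower bound on the Viterbi score) is
computed first, and full Viterbi alignment runs only on segments reaching
`filter_bits` (default 25). At benchmark scale the E ≤ 1e-10 shortlist
requires roughly 60–70 bits, and true domains score hundreds, so the
25-bit gate leaves a ≥ 35-bit margin below anything that could matter;
`filter_bits = -Inf` disables the gate, and a test asserts the hit table is
identical either way.

**Serialization.** Models and libraries round-trip bit-exactly through a
plain-text format (17 significant digits, calibration block with seed
included); a test asserts byte-identical rewrite.

## The screen (archscan)

Hits require `E <= 1e-10` and model coverage `>= 0.30`, the shortlisting
thresholds of the protocol. "30% domain overlap" is read model-side — the
aligned model span must cover ≥ 30% of the HMM's match states — which
matches domain-report semantics of profile search tools more closely than
target-side coverage.

The architecture filter works within each (genome record, frame, stop-free
segment): hits are scanned N→C for triples in the expected order
FN-plug → NHL → YD-shell with inter-envelope gaps ≤ 300 aa and pairwise
envelope overlap ≤ 50% of the shorter envelope. The 300-aa "adjacency" bound
is a package choice (surfaced in configuration): the superfold is contiguous
in the reference protein, so genuine inter-domain linkers are short, but the
protocol itself does not state a maximum. Overlapping candidate triples are
resolved greedily by highest combined bit score, ties broken by leftmost
genomic start — deterministic and score-consistent. Loci are numbered per
genome by genomic start.

Because local Viterbi envelopes may trim a few terminal residues whose
sampled emissions score below background (exactly as domain-search envelope
reporting does), called locus bounds can differ from planted truth by a few
codons; recovery is therefore assessed by overlap, and the near-exact test
allows ±4 codons per end.

`find_downstream_orf()` implements the immunity-gene signature — a naive
ATG-to-stop ORF on the same strand, 5'→3' downstream of the locus within a
5 kb window — and is checked against an independent codon-walk oracle.
`summarize_prevalence()` tallies screened/positive genomes per taxon group,
the copy-number histogram, and multi-copy genomes.

## Motifs and the CTD (motif_ctd)

Two grammars, scanned with overlapping matches reported:

* simple RHS core cleavage motif `P-x(4)-D-P-x-G`;
* bipartite `D-P-x-[G/L/R] - x(18) - D-P-x-G`, recording both catalytic
  aspartate positions and the observed first-tetrad terminal residue
  (glycine canonically; leucine and arginine substitutions occur in some
  species and are accepted and recorded).

The default spacer is 18 intervening residues, the `DPxG-X18-DPxG` reading;
under it the aspartate-to-aspartate distance is 22. Prose descriptions of
the two tetrads as "twenty residues apart" cannot be reconciled with X18
(that would put the aspartates 24 apart); the package follows the X18
pattern and leaves the spacer configurable.

The CTD convention is `ctd_start = d2_pos + 5`: cleavage falls between the
glycine of the second tetrad (`d2_pos + 4`) and the next residue. This is
the unique offset consistent with the printed reference numbering — second
catalytic aspartate at 2140, last shell-ordered residue 2144, CTD reported
as residues 2145–2237. (That span is quoted as "92 amino acids" although the
inclusive count is 93; the package reports the actual sequence length and
does not adjudicate.) A partition property is enforced: prefix + CTD
reconstructs the parent exactly.

Transmembrane segments are called from a centered Kyte–Doolittle
moving-average (window 19, threshold 1.6, runs merged across gaps ≤ 3 and
reported at length ≥ 15). No specific predictor is named by the source
protocol, so outputs are labelled *hydropathy-predicted* and are not claimed
to reproduce residue-exact boundaries; on the synthetic reference protein
the call lands within the planted 2165–2185 hydrophobic stretch. Masses are
average residue masses minus one water per peptide bond, reported in kDa.

## Synthetic data (synthetic_data)

The generator emulates the screen's inputs with planted ground truth:

* **Alignment**: a full-length (2237 aa) reference protein plus mutated
  homologs (~70% identity, short deletions, insertion columns gapped in the
  reference). The reference carries the bipartite RHS motif at 2118/2140
  (leucine first-tetrad variant) and a hydrophobic stretch at 2165–2185, so
  the motif/CTD/TM analyses have a worked example with the field's
  reference numbering.
* **Genomes**: i.i.d. background DNA at configured GC; cassettes =
  reverse-translated `FN-plug + linker + NHL + linker + YD-shell` samples
  from the HMM library (linkers 2–20 aa: the superfold is contiguous in the
  reference, so true linkers are short), inserted on a random strand.
  Decoys map one-to-one onto the three failure modes the architecture rule
  must reject: shuffled domain order, domains split across strands, and
  single partial domains. Optionally an ATG-initiated immunity-like ORF is
  planted 50–500 nt downstream of each cassette on the same strand.
* **Spacing**: planted elements are kept ≥ 2 kb apart. Across 2 kb of random
  DNA the probability of no stop codon in a fixed frame is ≈ 3e-14, so
  independently planted elements essentially never share a stop-free
  segment, and decoys cannot borrow domains from a neighbouring cassette.

The fixed benchmark used throughout validation is 20 genomes × 200 kb with
30 cassettes, 10 decoys of each kind, and seed 1337; generation is
byte-deterministic given the configuration. A truth-consistency property
verifies that every planted domain re-translates at exactly its truth
coordinates through the package's own frame maps.

**What passing does and does not show.** The background is i.i.d. (no
repeats, no real codon usage, no gene structure), decoys are the designed
adversarial cases only, and planted domains are genuine samples from the
search models. Passing therefore demonstrates the pipeline's mechanics —
coordinate exactness, filter semantics, architecture logic, calibration
sanity, determinism — not the sensitivity/specificity the screen would
achieve on real genomes against real domain divergence.

## Membrane statistic (membrane_metric)

A frame is a set of membrane marker positions (plus optional protein
positions and periodic box extents). The x–y plane is tiled into
`patch_size` squares; each occupied patch's plane is fitted by total least
squares (smallest principal direction of the centred covariance, oriented to
positive z), and the deformation index is
$D = \mathrm{mean}_\text{patches}\, |\hat{n} \cdot \hat{z}|$: exactly 1 for
a flat bilayer, smaller with deformation. Patches with fewer than 3 points,
or whose x–y footprint is numerically one-dimensional (minor/major spread
ratio below 1e-6) — where a plane normal is unidentified — are skipped and
counted in a QC field rather than imputed. The patch size is exposed as a
parameter; validation uses closed forms (flat plane, tilted plane
$D = \cos\theta$) and numeric quadrature of $|\cos\theta(x)|$ over sinusoid
families, including monotonicity in amplitude. `min_distance_series()` is
the brute-force protein–membrane minimum distance per frame, with
minimum-image wrapping in x/y when a box is given.

The molecular-dynamics systems themselves are out of scope; only the
analysis statistic is implemented, over a documented CSV of coordinates.

## Problem sizes, determinism, seeds

All randomness flows through explicit seeds (alignment 101, benchmark 1337,
per-model calibration seeds derived from a master seed and recorded in the
model files); identical configurations produce byte-identical FASTA, TSV,
GFF3 and model files, which is asserted by checksum in the tests. The test
suite validates the full benchmark scan (≈ 4 Mb of genome, ≈ 88k segments
against three models), strand-mirror symmetry on complete genomes, a
200-genome prevalence-control experiment, and the enumeration oracles; the
sizes were chosen so the whole suite runs in a few minutes on one CPU.

## Known limitations

* The profile HMM is single-hit local; tandem duplications of one domain
  within a segment yield one (best) hit per model per segment, which the
  architecture caller then pairs greedily.
* E-value calibration fits the full Viterbi score distribution rather than
  a censored tail; with 200 calibration samples the 1e-10 threshold is an
  extrapolation, mitigated by the held-out tail check and by the fact that
  true-domain scores sit hundreds of bits above threshold.
* `find_downstream_orf` is a naive ATG-to-stop scanner, not a gene finder;
  in random DNA it reports spurious short ORFs, so results are ranked by
  proximity and filtered by minimum length, and real use would post-filter.
* The hydropathy TM caller is a deliberately simple windowed mean, labelled
  as such; it is not a topology predictor.
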
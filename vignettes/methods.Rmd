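---
title: "Measuring basecall accuracy: read identity, reference-guided consensus, and error taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring basecall accuracy: read identity, reference-guided consensus, and error taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontbench)
```

## The measurement problem

Nanopore basecalling turns a noisy single-molecule current trace into a
nucleotide sequence. Judging how well a basecaller does this requires a
trusted reference genome and two complementary accuracy notions:

* **Read accuracy** — how close each individual read is to the truth.
  Errors here are dominated by the stochastic nature of the signal.
* **Consensus accuracy** — how close an assembly built from many
  overlapping reads is to the truth. Random read errors are outvoted at
  adequate depth, so what remains in a consensus is the *systematic*
  component: errors that many reads make in the same way at the same
  locus. In bacterial genomes two systematic families dominate: miscalls
  at Dcm-methylated CCAGG/CCTGG motifs (models not trained on methylation
  mis-read the methylated cytosine) and homopolymer length errors (the
  pore measures a run of identical bases poorly).

`ontbench` implements this measurement pipeline end to end on haploid,
single-contig (typically circular bacterial) references, together with a
synthetic-data generator that reproduces exactly this random-vs-systematic
error structure with a complete ground-truth ledger.

## Read accuracy

Each read receives one best alignment from a seeded, banded affine-gap
aligner (below). Read identity is **BLAST identity**: matching bases
divided by all alignment columns, including inserted and deleted bases.
Two edge rules protect the summary statistic from flattering artefacts:

* a read aligned over **less than half** its length (strictly `< 0.5`)
  scores 0% — a partial alignment of a junk read should not count as a
  good read;
* a read the basecaller was expected to emit but did not also scores 0% —
  otherwise a tool could inflate its average by dropping hard reads.

The set-level accuracy is the **median identity over all expected reads**,
also reported on the Phred scale (`q = -10 log10(1 - identity)`, so Q10 =
90%, Q20 = 99%, Q30 = 99.9%). Read sets can first be restricted to reads
with a reference-spanning alignment of at least `min_align_bp`; the
threshold is a free parameter because the appropriate value scales with
genome size and depth. The mean per-read quality used for the Q7 'fail'
fraction averages per-base *error probabilities*, not raw Phred values,
before converting back.

## The aligner

Alignment is internal so that every identity and every error event comes
from one deterministic, inspectable code path.

* **Seeding**: the reference is k-mer indexed once (k = 15 by default;
  k-mers occurring at more than 100 positions are skipped as repeats).
  Read k-mer hits are bucketed by diagonal (50 bp buckets, adjacent
  buckets merged) and the best collinear bucket on either strand selects
  the window and orientation; fewer than 3 collinear seeds means
  unaligned. For circular references the doubled sequence is indexed, so
  origin-spanning reads align contiguously; coordinates are reported
  modulo the length.
* **Banded affine DP**: semi-global (query end-to-end, target end-gaps
  free) with ONT-style scoring (match 2, mismatch 4, gap open 4, gap
  extend 2; a gap of length g costs `open + g*extend`). The band is a
  ±128-diagonal corridor around the seeded diagonal, doubled up to 4096
  whenever the optimal path touches the band edge, so the band is
  self-validating in practice. Traceback tie-breaks prefer
  match/mismatch over deletion over insertion, which makes alignments —
  and therefore error events — reproducible to the byte.
* One best alignment per read; no split or supplementary alignments.

On random instances up to 200 bp the banded scores equal an independent
full-DP implementation (`Biostrings::pairwiseAlignment`, type
`"global-local"`), which the test suite uses as an oracle.

## Reference-guided consensus

The consensus stage follows the replace-then-polish scheme of
reference-guided assembly:

1. **Tile**: greedily cover the reference with the highest-identity read
   alignments and substitute each covered span with the read's aligned
   subsequence. The draft inherits the reference's large-scale structure,
   but its base-level content comes entirely from reads.
2. **Polish**: realign all reads to the draft and take a column-wise
   pileup plurality vote — base, deletion, or base plus insertion — for up
   to `polish_rounds` rounds (default 4), stopping early when a round
   changes nothing. An insertion is emitted only when its most common
   inserted string is carried by at least half the covering reads, which
   suppresses depth-1 insertion noise. Vote ties keep the current draft
   symbol by default (`tie_rule = "prefer_current"`), keeping polishing a
   contraction; positions below `min_depth` coverage keep the draft base.
3. **Iterate**: run the whole assembly `iterations` times (default 10),
   each with the reads shuffled under a seeded RNG and, for circular
   references, the reference rotated to a new start
   (`floor(i*L/iterations)`, evenly spaced); rotate each result back to
   the canonical start by locating a 1 kbp anchor from the original
   reference start, then feed the per-iteration assemblies as the 'reads'
   of a final meta-assembly.

The polisher is a deliberate, documented stand-in for a partial-order
window polisher such as Racon: plurality voting is deterministic and
dependency-free, and it preserves the property the analysis turns on —
independent errors are outvoted, while an error carried by more than half
the reads at a locus survives into the consensus. It is *not* a Racon
reimplementation, and one consequence matters for interpreting results
(see *Iteration benefit*, below).

Rotation is only applied to circular references; for linear references the
iteration stage shuffles reads only.

## Consensus accuracy and the error taxonomy

The final assembly is cut into 10 kbp chunks (a trailing piece of at least
half a chunk is kept, smaller tails merge into the previous piece), each
chunk is aligned like a read, and consensus accuracy is the **median chunk
identity** with its qscore; the spread across chunks is reported as a
sample standard deviation.

Every chunk-vs-reference difference becomes an error event: mismatch runs
split into per-base substitutions; each gap run is a single insertion or
deletion event carrying its full allele. Events are classified by
reference context with precedence **Dcm > homopolymer > plain**:

* **dcm** — the event's reference footprint touches a CCAGG/CCTGG
  occurrence (any deleted base for deletions; the junction's right
  neighbour for insertions). The motif pair is its own reverse
  complement, so a forward-strand scan covers both strands. All five
  motif positions count as "inside", and membership intervals are unioned.
* **homopolymer_insertion / homopolymer_deletion** — the event adds or
  removes copies of base *b* within or adjacent to (either flank of) a
  reference run of *b* of length ≥ 3.
* **insertion / deletion / substitution** otherwise.

Counting conventions differ between tools on whether a multi-base length
change is one error or several, so profiles report both event counts and
error-base tallies; `total_error_pct` uses error bases over reference
length.

## The synthetic benchmark

`simulation_config()` defaults define the study conditions used throughout
the tests and the acceptance script: a 50 kbp circular genome at 57.6% GC
(the GC of the *K. pneumoniae*-like benchmark genome this emulates), 100
planted motif sites and a 4-base x {4,6,8} x 3 grid of planted homopolymer
runs, depth 40, read lengths ~N(5 kbp, 1.5 kbp) truncated at 200 bp, and
5% random error split as 2.5% substitutions, 1.25% insertions, 1.25%
deletions. Systematic channels default to off; when enabled, the Dcm
channel substitutes the methylated (second) C of a planted site with a
*per-site fixed* miscall base with probability `dcm_error_rate` per read,
and the homopolymer channel changes a planted run's length by ±1 in a
*per-run fixed* direction. Fixing the direction per locus is what makes
these channels systematic: at per-read rates above 0.5 they survive
majority voting, which `expected_profile()` turns into a closed-form
oracle for end-to-end recovery tests.

The generator guarantees exact motif truth: accidental CCAGG/CCTGG
occurrences outside the recorded sites are patched (middle base set to C,
which provably cannot create a new motif), and planted runs are recorded
at their final maximal extents. Every injected event is logged with its
channel, and replaying the ledger against the reference reconstructs each
read byte-for-byte — a property the tests assert.

What the generator does **not** model: signal-level artefacts, chimeras,
adapters and barcodes, quality-score calibration (qualities are uniform
per read, derived from realised identity), and empirical read-length
distributions. Passing tests therefore demonstrate the correctness of the
measurement pipeline and the majority-vote logic, not basecaller
performance on real flowcells.

Read lengths, genome sizes and depths used in the tests (10–50 kbp
genomes, depths 5–40) were chosen as the smallest scales at which the
statistical behaviour under study — majority-vote convergence, systematic
error survival, chunked identity spread — is clearly expressed.

## Iteration benefit: what majority voting can and cannot show

The iterative shuffle/rotate meta-assembly exists because window-POA
polishers do not always converge to the best sequence; their residual
errors differ between runs, and a final vote across runs removes a share
of them (the benchmark this package emulates reports roughly a 20%
error reduction, e.g. 99.33%/Q21.74 for single assemblies against
99.47%/Q22.76 iterated).

With this package's plurality polisher, a single assembly at depth 40
under 5% i.i.d. error is already within 0–1 error bases of the reference
per 50 kbp: per-column plurality converges, so there is next to no
residual error pool for iteration to reduce, and the measured relative
reduction under the default study conditions is ~0 rather than ~20%. The
iteration machinery is still fully implemented, seeded and deterministic —
`iterative consensus >= single assembly` holds as an inequality — but the
*magnitude* of the published benefit is a property of a non-converging
polisher and should not be expected from majority voting at this depth.
The acceptance suite reports the measured reduction as computed.

## Numerical and degenerate-input choices

* Perfect identity maps to the qscore cap (default Q90) so error-free
  runs summarise finitely; the cap is configurable everywhere it is used.
* Identity/qscore conversions are exact inverses to < 1e-12 across the
  representable range.
* Even-count medians average the two central values (`stats::median`).
* Zero alignable reads: the evaluation warns and reports 0% accuracies
  rather than failing.
* Chunks that fail to align score identity 0 with a warning.
* Multi-contig references are rejected outright — the pipeline's rotation
  and wrap-around logic presumes a single (optionally circular) contig.
* All randomness (read placement, channel sampling, shuffling) flows
  through explicit integer seeds held in the configuration objects; the
  session RNG state is never disturbed.

## Known limitations

* The seeding heuristic can misplace reads in highly repetitive
  references; repeat-heavy genomes are outside the intended scope (the
  emulated benchmark's longest repeat is far shorter than its reads).
* Band widening is triggered by the optimal in-band path touching the
  band edge; a strictly better path entirely outside a never-touched band
  would go unnoticed. With seeded windows this was not observed in
  testing.
* The per-read aligned fraction is 1 for any read the semi-global aligner
  accepts in full; sub-half alignment arises only from clipping at
  reference ends or windows, so the under-half rule mostly guards real
  data, not the simulator's output.
* `run_evaluate()` assumes reads fit in memory as a tibble; the intended
  scale is desk-sized benchmarks, not production genome runs.
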
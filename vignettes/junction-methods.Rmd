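---
title: "Methods: junction queries, the significance filter, and the read simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction queries, the significance filter, and the read simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionr)
library(dplyr)
```

## The model

`junctionr` asks a deliberately narrow question: *is there direct read
evidence for each splice event of each isoform in a sample?* The unit of
evidence is the exon–exon junction. For a transcript with exons
$e_1, \dots, e_n$ (in transcript 5'→3' order) there are $n - 1$ junctions;
junction $k$ is identified by the genomic coordinates of the **donor** (the
last exonic base of $e_k$ in transcript orientation) and the **acceptor**
(the first base of $e_{k+1}$), together with chromosome and strand.
Identity is coordinate-based, not sequence-based: two isoforms that splice
the same donor to the same acceptor produce *the same* junction, whatever
their exon labels, and read support at such a junction is intrinsically
ambiguous between them. This is decidable from the coordinate table alone,
with no genome in hand, and it is what drives the asterisk flags in the
reports. On the packaged KCNJ6/DSCR4 models the shared identities are the
two internal KCNJ6 junctions (E2-E3 and E3-E4/E3-E4b, whose downstream
exons start at the same base) and the promoter-proximal first junction
common to KCNJ6-202 and all three DSCR4 isoforms.

The query of a junction is the last $f$ transcript-oriented bases of the
upstream exon joined to the first $f$ bases of the downstream exon. The
default flank $f = 25$ nt gives 50-bp queries; flanks may be asymmetric in
configuration, and a flank is truncated (with a warning, and recorded on
the query row) when the exon is shorter than requested — real terminal
exons can be short, so truncation is not an error. Queries are always
emitted 5'→3' in transcript orientation; for reverse-strand transcripts the
forward-strand extraction is reverse-complemented. A useful internal
consistency property, exercised in the tests: an untruncated query equals
the $2f$-base window of the fully spliced transcript sequence centred on
the junction.

## Alignment and the significance filter

Reads are scored against queries with a local (Smith–Waterman) aligner
with affine gaps, delegated to `Biostrings::pairwiseAlignment()`. The
scoring scheme is configuration, not contract: defaults are BLASTN-like
(+2 match, −3 mismatch, −5 gap open, −2 gap extend) and any scheme with
match > 0 > mismatch preserves the package's filter properties. `N` bases
are penalized against everything, themselves included, so an `N` column
can never count toward identity.

The filter keeps an alignment when

* **query cover** $= 100 \cdot (q_{end} - q_{start} + 1) / |query| \ge 95\%$, and
* **identity** $= 100 \cdot \text{matches} / \text{alignment columns} \ge 97\%$,

both thresholds inclusive. The denominators are a genuine modelling choice:
identity is computed over alignment columns *including gap columns* and
cover over the *full* query length (BLAST conventions). Two consequences
shape everything downstream. First, a 50-bp query passing at ≥ 95% cover
must align from position ≤ 3 to position ≥ 48, i.e. every significant
alignment straddles the junction midpoint — a read lying wholly inside one
exon can match at most one flank, capping cover at 50%, so exon-interior
reads cannot masquerade as splice evidence (asserted on simulated genomes
with independent random intron sequence; a genome whose intron happened to
duplicate a flank could defeat this, which is a property of the genome,
not the method). Second, at full cover the identity boundary sits between
one and two mismatches in 50 columns: 49/50 = 98% passes, 48/50 = 96%
fails. Substitutions within ~2 bases of the query ends are instead trimmed
by the local aligner, trading a little cover (≥ 96%) for identity — the
filter is therefore slightly more forgiving of edge errors than of
interior ones, which is inherent to local alignment.

Each read is aligned in both orientations (read sets are treated as
unstranded) and only its better-scoring orientation is kept, forward
winning ties, so each read contributes at most one result — and one
potential vote — per junction. Counting distinct read ids ("one read, one
vote") avoids double-counting multiple high-scoring pairs from a single
read. Traceback determinism is delegated to the aligner, which is
deterministic for fixed inputs; byte-identical reports for identical
configs and seeds are asserted in the tests, which is the property that
matters. The aligner's optimum is cross-checked in the tests against an
independent exhaustive oracle that enumerates every ungapped offset of the
query against the read and both orientations: gap-free optima must match
the oracle exactly, gapped ones can only improve on it.

## Isoform calls

Per sample: **full** means every junction of the isoform has ≥ 1
significant read; **none** means no junction has any; **partial** is
everything in between — any significant alignment counts as detection,
with no minimum read count beyond 1. Completeness deliberately counts
shared junctions too (an isoform whose junctions are all supported is
called full even if some of that support is ambiguous), but every shared
junction is flagged, and `uniquely_confirmed` reports whether at least one
*supported* junction belongs to the isoform alone. Shared counts are never
apportioned probabilistically between isoforms; flagging is the honest
output at this evidence level. "Partial" as "≥ 1 but not all junctions" is
an interpretive choice: no minimum fraction of junctions defines partial
support here.

## The coordinate layer

External coordinates are 1-based inclusive throughout; BED12 (0-based
half-open, block-encoded) is converted on read and write. Strand is
inferred from the printed coordinate direction: exon tables conventionally
print reverse-strand transcripts 5'→3' with descending coordinates, so a
descending transcript is strand "−" and coordinates are normalized to
start ≤ end internally. Abutting exons (a zero-length intron) are a
validation error rather than a silent merge — a model that lists two exons
with no gap is malformed input. Region overlap classification
(`classify_overlap()`) is exhaustive and mutually exclusive (disjoint /
feature within region / feature contains region / partial overlap; equal
intervals report "within"), and is verified against a brute-force
base-membership oracle on random interval pairs.

The packaged exon table is kept exactly as printed in its source, including
the KCNJ6-201 E1 entry (37,961,457–37,915,884) which overlaps the HR-DSCR
interval even though that region is usually described as intergenic — most
likely a typo in the source annotation. The table is the package's input,
not its editorial product; the discrepancy is left visible through
`classify_overlap()` rather than silently corrected.

## The simulator and what passing tests mean

`simulate_genome()` draws an i.i.d. uniform A/C/G/T sequence over the
21q22.13 window (chr21:37,600,000–38,130,000; 530,001 nt) and anchors it at
real coordinates, so the models address it exactly as they would GRCh38.
`simulate_reads()` emits three read classes with per-read ground-truth
labels: junction reads sampled from the spliced transcript so that the
footprint spans the junction with ≥ flank + 5 bases on each side
(guaranteeing a filter-passing alignment at zero error rate — hence read
length must be ≥ 2·flank + 10, a validation error otherwise);
exon-interior reads from single exons at least one read long; and
background reads from the genome outside every model exon. Errors are
i.i.d. substitutions only — the filter is identity/cover-based, so
substitutions are the failure mode worth modelling and indel error modes
are left out of scope. Orientation is randomized. Everything is
deterministic per seed, with no hidden global RNG state.

Default scenario parameters are chosen as a plausible low-depth tissue
panel: 100-nt reads (a standard short-read length), junction depth 5 and
exon depth 5 (enough that per-junction detection is near-certain while
keeping runs instant), 30 background reads, and a 0.002 per-base
substitution rate (of the order of Illumina substitution error). The
tissue presets encode expression at whole-transcript level — the cerebral
tissues express KCNJ6-201, placenta DSCR4-201, testis DSCR4-201 +
DSCR4-202, the rest background only — so end-to-end runs reproduce the
qualitative support-table shapes (which junctions light up, which are
starred). They do not attempt absolute read counts, partial
single-junction expression (a tissue where only one internal junction of
an isoform has support), expression-level realism, paired ends, quality
modelling, or non-uniform genomic sequence. Consequently, passing tests
demonstrate the pipeline's arithmetic and its discrimination geometry —
not performance on real tissue RNA-seq, where repeated sequence, paralogs
and splice-site homology can make junction flanks less unique than an
i.i.d. genome guarantees.

Scenario recovery is the headline property: for every distinct preset
expression pattern, at junction depth 3 and error rate 0.005, the set of
isoforms with uniquely attributable support equals the planted expressed
set across ten seeds. With ~3% probability that any one read drops below
the identity threshold at that error rate, three reads per junction leave
roughly a 3-in-100,000 chance of losing a junction entirely, so exact
recovery is the expected outcome, not a tuned one.

## Problem sizes and runtime choices

The test suite runs the full catalog (5 isoforms, 22 exons, 17 transcript
junctions, 12 identities) against simulated samples of ~45–65 reads, 40
simulate–align–call runs for scenario recovery, 1,000 random pairs for the
aligner oracle, and 2,000 random interval pairs for the overlap oracle —
desk-scale sizes chosen so the whole suite completes in well under five
minutes on one CPU. One surrogate genome is shared across read-seed
variations in tests, since genome construction is the single most
expensive simulation step.

## Primer QC

The primer utility applies the classic design rules: Wallace-rule
annealing temperature $T_a = 2(A{+}T) + 4(G{+}C)$ °C (a documented,
deliberately simple default — no nearest-neighbour thermodynamics in this
version), $55 \le T_a \le 65$ per primer, pair difference < 2 °C (note
Wallace temperatures are always even, so the smallest failing gap in
practice is 4), GC content within an inclusive 40–60% band, and a
secondary-structure heuristic that flags any perfect antiparallel
complementarity run of ≥ 6 bases within a primer (hairpin/self-dimer) or
between the pair (cross-dimer), computed as the longest common substring
of one primer and the reverse complement of the other. A pair passes iff
every criterion passes. The run threshold of 6 matches the descriptive
level of standard primer-design guidance; it is a heuristic, not a
thermodynamic model.

## Known limitations

* Junction identity ignores sequence: two different donor/acceptor pairs
  with identical flanking sequence would be treated as distinct (and their
  reads would cross-align); the i.i.d. simulator cannot produce this, real
  genomes occasionally can.
* One-read-one-vote discards secondary alignments entirely; for the
  presence/absence readout this is the conservative choice.
* No paired-end awareness, no expression quantification, no normalization
  — the unit of output is raw significant-read counts per junction.
* The aligner is exact dynamic programming over every read × query pair;
  fine for panel-scale questions (dozens of junctions, thousands of
  reads), not a substitute for an indexed aligner at transcriptome scale.
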
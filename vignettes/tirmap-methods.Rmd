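---
title: "Methods: TIR-anchored insertion mapping, deletion consensus and divergence landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIR-anchored insertion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tirmap)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical conventions adopted where a
choice had to be made.

## The junction-query model

Class-II (DNA) transposons end in terminal inverted repeats (TIRs) and,
being mobilised by cut-and-paste, leave a short target site duplication
(TSD) of host sequence on both sides of every insertion (8 nt for the
P-element). These two signals make insertions detectable from an assembly
alone, without reads:

* **Discovery (WF1).** For each family the two discovery queries are the
  TIR plus `internal_ext_bp` (default 100 bp, in sequence units) of
  element-internal sequence; the extension is what makes the 5' and 3'
  ends distinguishable, since the TIRs themselves are reverse complements
  of each other. Queries are aligned against contigs on both strands.
  Every significant hit is extended with `flank_len_bp` (default 3000 nt)
  of element-*external* contig sequence into a junction query (JQ) that
  always reads flank → matched TIR span; hits whose external side lies
  downstream in contig coordinates are reverse-complemented first.
* **Mapping (WF2).** The JQ's flank is located on the reference by exact
  k-mer seeding and a forced (global-in-pattern) affine alignment. The
  placement is then interpreted: if the TIR-side remainder of the JQ also
  continues in the reference genome immediately past the flank (identity
  ≥ `cont_identity`, default 90%), the element is present in both genomes
  — a *conserved* insertion, further split into annotated/unannotated by
  intersection with the reference TE annotation. If instead the remainder
  aligns to the canonical element (identity ≥ `te_identity`, default
  80%), the flank's endpoint is an insertion breakpoint absent from the
  reference — a *specific* insertion.

### Coordinates, TSDs and the two junctions

The insertion coordinate is defined as the 1-based reference coordinate
of the last base before the inserted material (fully-closed interval
conventions throughout, as in GFF). The junction upstream of the element
5' end ("left") yields this coordinate directly as the last aligned flank
base. The downstream ("right") junction underestimates it by exactly the
TSD length, because the duplicated k-mer at the element's 3' side aligns
onto its template upstream of the true insertion point. The TSD is
detected independently, in contig space, as the longest k in 4–12 for
which the k-mers immediately outside the paired element ends are
identical; right-junction coordinates of specific calls are then
corrected by +k. For conserved insertions seen from their right junction
the element's upstream boundary is recovered by scanning back one
canonical length for the leading TIR. Calls of the same family within
`coord_tolerance` (default 20 bp) are merged, left-junction coordinates
taking precedence; this is also what collapses the two junctions of one
copy, and the same junction seen in overlapping contigs, into a single
supported call.

### Ambiguity and the 6000-nt rescue

A placement is *ambiguous* when a second locus scores within `delta`
(default 0.95, a scale-free relative margin — no absolute score threshold
would transfer across flank lengths) of the best, on a locus more than
10 kb away or on another chromosome. Ambiguous JQs are re-extracted with
the flank extended to `flank_ext_bp` (default 6000 nt) where the contig
allows — the re-mapping is attempted only when the extension is
meaningful (≥ 1.5× the original flank) — and upgraded if a unique best
locus emerges. JQs that are unplaced, or whose flank is shorter than
`min_flank` (default 500 bp), are *unresolvable*; when every candidate
locus lies on one chromosome that chromosome is reported as a hint, the
coordinate-free analogue of a "most probably in" call.

### Alignment engine and scoring

Pairwise alignment is Biostrings' Smith–Waterman / Needleman–Wunsch with
a custom substitution matrix (A/C/G/T matches `match`; IUPAC ambiguity
codes and N score as mismatches) and affine gaps costing
`gap_open + L·gap_ext` for a gap of length L. Defaults — match +2,
mismatch −3, gap open 5, gap extend 2, significance at identity ≥ 85%
over ≥ 80% of the query — were chosen to tolerate a few percent of
assembly noise in a 131-nt TIR query while keeping random 131-nt matches
below threshold; they are exposed in `scoring_params()` because no
reference values exist for them. Exhaustive search is used whenever
|query|·|subject| ≤ 10⁶; larger subjects are screened with exact 21-mer
(WF1) or 31-mer (WF2) seeds, diagonal-clustered into candidate windows,
and the dynamic programming confined to those windows. All hit lists are
sorted with deterministic tie-breaking (score, then contig, coordinate,
strand), so identical inputs give byte-identical outputs. In WF2, loci
whose seed support is under half of the best locus's are discarded before
the costly window alignment: they cannot score within the 95% ambiguity
margin.

## Internally deleted variants and consensus

Copies of a family are found by chaining collinear local alignments of
the canonical sequence along a contig; an internally deleted copy
(KP-style) appears as two chained blocks whose canonical coordinates jump
while contig coordinates do not. The extracted copy is then re-aligned
globally to the canonical (compiled affine NW in `src/`), and gaps of at
least `min_gap` (20 nt) strictly inside the element are reported as
internal deletions; terminal gaps are truncation, not deletion. Copies
shorter than `min_complete` (800 bp) are flagged incomplete and excluded
from consensus building.

Deletion intervals are **left-normalized**: the interval slides leftwards
while the base before the gap equals the last deleted base. An internal
deletion flanked by repeated sequence has several equivalent coordinate
representations — the same phenomenon that makes independent studies
report near-identical but offset KP breakpoints — and a canonical
representation is required for exact comparisons. The simulator's truth
tables and all detectors use the same normalization.

The multiple alignment is progressive: full pairwise NW distances give
the join order (closest pair first, then nearest-to-the-set), and each
new sequence is aligned to the growing profile using count-weighted mean
column scores. For two sequences this reduces exactly to the pairwise NW
alignment, which is what the test oracles assert. The consensus is
emitted per column as the most frequent residue when its fraction of all
rows (gaps included in the denominator) reaches `plurality_fraction`
(default 0.5), otherwise `N`; columns where gaps hold a strict majority
are dropped; residue ties resolve alphabetically for determinism. The
consensus deletion interval comes from re-aligning the consensus to the
canonical, taking the largest internal gap (smaller gaps are listed but
not folded in), left-normalized.

## Kimura divergence landscapes

Family activity profiles use the Kimura two-parameter distance
d = −½·ln((1 − 2p − q)·√(1 − 2q)) over the ungapped columns of each
copy-to-consensus alignment, with p the transition and q the transversion
fraction. The plain K2P form is used, without CpG adjustment. Saturated
alignments (non-positive logarithm argument) are flagged `NA` rather than
clamped. Each copy contributes its full length in bp to the bin
containing its distance (`bin_width` default 0.05), so the landscape
conserves total sequence mass — an invariant the tests check.

## Annotation statistics

Gene assignment distinguishes *hit* genes (span contains the insertion
coordinate) from *close* genes (within `window_bp`, default 3000 nt — the
JQ flank length, since closeness is defined by the gene sequence being
present in the extracted flank). Distances are counted to the gene's
first base, so a gene starting 2999 bp away is close and one at 3001 bp
is not. Densities per gene class count insertion→gene incidences (an
insertion hitting two overlapping genes counts once per gene); displayed
densities truncate at the second decimal — the convention under which the
published incidence counts reproduce their printed per-gene values — with
full precision retained in the report object. Heterochromatin membership
is interval-based (an explicit BED set plus wholly heterochromatic
chromosomes such as Y), because pericentromeric polytene bands have no
coordinate representation of their own. A site is an insertional hotspot
when at least `min_count` (3) annotated insertions fall within
±`window_bp` (50 bp; the count is a published definition, the window is
this package's choice).

## What the simulator emulates — and what it does not

`sim_params()` defaults define the study conditions: a 2 Mb reference in
five 400-kb chromosomes; 30 implants (10 conserved, 20 specific) drawn
across all five synthetic families; 8-nt TSDs; 30% of conserved implants
deliberately omitted from the TE annotation; 20% of implants carrying the
806–2561 internal deletion where the family is long enough; 50-kb contigs
with 8-kb overlap (so every junction plus its 3000-nt flank fits in one
contig); and configurable substitution/indel noise and forced element
truncation (< 800 bp remnants). Implant spacing (12 kb) and edge margins
(10 kb) guarantee well-separated junctions with full flanks.

The generator validates the pipeline's *logic*, not its robustness to
everything real assemblies do. Random chromosomes have no genome-wide
repeat structure, so flank placement is nearly always unique; real
pericentromeric regions will produce many more ambiguous and unresolvable
calls. Elements are implanted in plus orientation by default (the mapping
machinery itself handles minus-strand hits and is so tested), nested or
tandem insertions are not simulated, and contig noise is i.i.d. rather
than the bursty error profile of long-read assemblies. Passing recovery
tests therefore demonstrates correctness of coordinates, status logic,
TSD arithmetic and deletion calling under controlled noise — not
performance on heterochromatic repeat clusters.

## Degenerate inputs and edge cases

Empty contig sets, empty hit lists and zero-gene classes return empty
results or `NA` rather than errors; a JQ with zero available flank is
rejected with the reason recorded; TSD detection reports why it abstains
(no duplication in range, or flanks unavailable for single-TIR
detections); libraries reject sequence/metadata length mismatches hard
but report invariant violations (for instance a TIR length of at least
half the element) row by row instead of dropping them silently. Ranged
TIR annotations ("29–31") store the maximum: a longer anchor only extends
the query into genuinely element-internal sequence.

## Problem sizes used in validation

The bundled checks run the full pipeline on the 2 Mb / 30-implant
simulation at zero and 1% substitution noise, rebuild the KP-style
consensus from 11 copies at 1% SNPs, and verify the aligners against
brute-force oracles on all instances with |query|·|subject| ≤ 10⁴ —
sizes at which exhaustive dynamic programming is itself the independent
oracle.

## Known limitations

Single-TIR detections (one end truncated) are retained but cannot yield
a TSD, and their coordinate can be off by the TSD length when only the
right junction is seen. Conserved-insertion boundary recovery assumes an
intact leading TIR within one canonical length of the breakpoint. The
progressive MSA has no iterative refinement and is meant for the tens of
copies typical of one family, not thousands. Kimura distances are
computed against the family consensus, so a consensus built from few or
biased copies biases the landscape accordingly.
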
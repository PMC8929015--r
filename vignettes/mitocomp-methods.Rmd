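---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp analyses annotated circular insect mitochondrial genomes: 13
protein-coding genes (PCGs), 22 tRNAs, two rRNAs and the non-coding
A+T-rich control region. This vignette records the conventions, models and
numerical choices behind each analysis, the reasoning where the design was
genuinely open, and what the validation on synthetic data does and does not
establish.

## Coordinates and the record container

Coordinates are 1-based inclusive on the *major strand* — the deposited
strand, which in these genomes encodes ND2, COI–COIII, ATP6/8, ND3, ND6 and
CytB. Minor-strand features (ND1, ND4, ND4L, ND5, nine tRNAs, both rRNAs)
are flagged, never stored reverse-complemented; `extract_gene_sequence()`
reverse-complements on demand. `start <= end` is an invariant: a feature
spanning the origin would be represented as two rows sharing a name with a
`part` tag. None of the packaged genomes needs this, which is why the
simpler invariant was kept testable.

Ingest normalizes the label chaos of deposited records (COX1 → COI,
s-rRNA → srRNA, `trnL(taa)` → trnL2, D-loop → AT_rich, ...), logging every
nontrivial mapping. Deviations from the canonical 37 + 1 feature set warn
rather than error, so partial genomes remain analysable.

One transcription note on the packaged coordinate tables: the *Salurnis
marginella* lrRNA row is published with size 1205 while its coordinates
12294–13497 span 1204 bp. The coordinates are taken as authoritative; the
test suite documents the single 1-bp disagreement rather than silently
adjusting either number.

## Composition, skew and codon usage

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C). Both are always
computed from major-strand letters, *including* for minor-strand gene sets:
the biological signal of interest is precisely the strand asymmetry, so
reverse-complementing before measuring would erase it. A zero denominator
leaves that component `NA`. N bases are excluded from every denominator.

Codon usage counts all complete in-frame codons of each PCG read in its
own orientation, excludes a complete terminal stop codon, and discards the
1–2 nt remainder of a truncated stop. This single rule reproduces the
published codon total for *S. marginella* (3637) exactly and gives 3657
for the *Metcalfa pruinosa* haplotypes where 3656 is published — the two
published totals are mutually inconsistent under any single truncation
rule, so the package applies one rule and documents the one-codon
difference instead of special-casing a genome. `expected_codon_total()`
computes the same quantity from coordinates alone, which is what ties the
sequence-level count to the annotation in tests.

The genetic code is fixed to the invertebrate mitochondrial code
(translation table 5: ATA = Met, TGA = Trp, AGA/AGG = Ser) everywhere.

## Spacers and overlaps on the circle

Features are sorted by start (both strands interleaved) and every
consecutive pair plus the wrap-around pair is scored with
`gap = start(next) − end(prev) − 1`. Positive gaps are intergenic spacers,
negative gaps overlaps, zero contributes to neither. The A+T-rich region
is *not* an intergenic spacer: its two flanking junctions are reported
separately (`control_flank`) and excluded from the totals. This boundary
rule is what makes the hand-counted totals of the study genomes (147 bp
over 21 regions; 68 bp over 11) come out exactly, and it is consistent
with treating the control region as its own analysis subject. Ties for the
longest spacer break by genome order, for determinism.

`circle_conservation()` asserts the bookkeeping identity
`sum(feature lengths) + spacers − overlaps + control + control flanks =
genome length`; it returns 0 for all three packaged genomes.

## Gene-order typing and breakpoint distance

A gene order is a signed circular permutation, canonically rotated to
start at trnI (falling back, with a warning, to the lowest-coordinate
tRNA). The ancestral arrangement (type A) is embedded as a constant,
transcribed from the packaged annotation, which carries it. Type B
performs the two Delphacinae rearrangements (trnC–trnW transposition;
ND4L–CytB block rewritten to ND6(inverted), trnP, trnT), B′ adds a
triplicated trnC, and C moves trnH before ND6. Because the inversion
status of the translocated ND6 is not stated unambiguously in the
literature this package draws on, classification tolerates either ND6
orientation in the derived types and notes the discrepancy in its
evidence, rather than guessing.

Breakpoint distance counts signed circular adjacencies of one order absent
from the other, after collapsing duplicated tRNAs (distance is defined on
permutations; the duplication map is kept separately and is what
distinguishes B′ from B). Each adjacency is identified with its
reverse-complement reading, so the distance is symmetric and
rotation-invariant. It is a premetric, property-tested against an
independent adjacency-set oracle.

## Junction motif scanning

The junction "point" between two features is the midpoint of their facing
coordinates; the scan scores every motif-length window lying within a
configurable distance (default 30 bp) of that point by Hamming distance —
substitutions only, since the conserved-pentanucleotide alignments that
motivate the analysis show substitution variants, not indels. Because the
canonical junction (ND1/trnS2) has its flanks on opposite strands, hits
are reported on both strands with the strand labelled. The location class
(within either flank, within the spacer, or spanning) is assigned purely
from coordinate overlap. The default mismatch tolerance of 1 is a
configurable choice, not a literature value.

## Control-region architecture

The tandem-repeat finder is deliberately small and dependency-free, since
its outputs — unit length, copy number (fractional final copies allowed),
identity, boundaries — are all the downstream analysis needs. For each
candidate period *p* (default 10–200 bp) the sequence is compared to
itself at lag *p*; a maximal run of exact matches at least one unit long
seeds an array, which is extended in whole-unit blocks accepted only when
the block's own match fraction reaches the identity threshold (default
0.85), then by exactly matching positions, and finally trimmed to matching
ends. Block-local acceptance matters: a low-complexity A+T-rich flank has
a chance lag-*p* match rate near 0.45, and a global identity budget would
let boundaries creep far into it; with block acceptance, recovered
boundaries stay within half a unit of truth. Overlapping candidates at
different periods are resolved by longer span, then higher identity, then
smaller unit — which is how a 21-bp array outranks its own period-42
reading. Homopolymer "arrays" are excluded (a 23-bp poly-A is technically
a period-10 tandem repeat); homopolymers belong to the poly-run report
(poly-A, poly-T, poly-AT runs of at least 8 bp, configurable — the
threshold is a choice, as the literature flags long runs without defining
one).

`region_architecture()` runs the finder on the control region taken in
major-strand orientation (srRNA side to trnI side), labels inter-array
gaps nonrepeat, and reports per-segment A+T content. The segments tile the
region exactly, by construction.

`compare_repeat_units()` aligns unit pairs globally (Needleman–Wunsch,
match 1, mismatch −1, gap open 4, gap extend 1) and defines identity as
matching positions over the longer unit. Under this scoring, random
60-mers land near 0.3 identity and identical units at 1.0, so the default
alignability threshold of 0.6 cleanly separates shared-origin from
unrelated units. An overlap-type (end-gap-free) alignment was considered
and rejected: on random pairs it aligns only a short terminal fragment and
reports misleadingly low identities (~0.07).

## Ka/Ks

The package implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction rather than a model-averaged estimator suite: the scientific
claim being supported is a selection *regime* (ratios well below 1,
minor-strand genes above major-strand genes), which NG86 recovers, and a
14-model averaging apparatus would be out of proportion to that claim.
Consequently validation is property-based — simulated dN/dS is recovered
within ±0.05 at ω ≤ 0.1 and within [0.9, 1.1] at ω = 1 — and no published
model-averaged value is used as a numeric target.

Sites per codon follow the stated convention S = 3·syn/(9 − s), where the
nine single-nucleotide changes are classified synonymous/nonsynonymous
under table 5 and the *s* changes creating stop codons are excluded from
the denominator. Differences between codon pairs average equally over all
mutational pathways that avoid stop intermediates; a codon pair with no
stop-free pathway is skipped and counted. Gap or ambiguous codons are
skipped pairwise; terminal stops are trimmed. Proportions at or above 3/4
leave the corrected distance undefined, and a zero or undefined Ks leaves
the ratio `NA` (excluded, with a count, from group summaries).

One caveat the tests make explicit: when a simulation at ω = 0 hits the
same codon several times, pathway averaging can attribute a small
fractional nonsynonymous count to a purely synonymous history (e.g. the
serine pair AGT/TCT), so Ka is near — not identically — zero even though
the two proteins are identical.

## Intraspecies divergence

"Pairwise distance" is implemented as the uncorrected p-distance with
pairwise deletion of gap/N columns. At intraspecific divergences (well
under 5%) the difference between p-distance and any model correction is
far below the differences being ranked, and the ranking of per-gene
medians is the analysis output. The DNA-barcode region is the 5′ 658-bp
prefix of COI in reading orientation (the standard animal barcode length),
configurable. Genes missing from any record, or with unequal extracted
lengths (alignment is the caller's responsibility), are skipped with a
warning.

## tRNA structures

Cloverleaf structures are *evaluated, not predicted*: pairing comes from
annotation (dot-bracket strings with arm spans) or from the generator,
because published structures derive from external predictors plus hand
curation, and re-implementing folding would make the package's claims
untestable. Each annotated pair is classed Watson–Crick, G–U wobble, or
mismatch; canonical dimensions (7-bp acceptor stem, 5-bp anticodon stem,
7-nt anticodon loop) are flagged, and an empty DHU arm marks the truncated
form typical of trnS1.

## The synthetic generator

`simulate_mitogenome()` emulates the statistical structure of a flatid
mitogenome, with defaults chosen once to match the study system: ~16 kb
genome, whole-genome A+T 0.766, AT skew 0.25, GC skew −0.26 on the major
strand; a control region with a truncated 2.5-copy two-part repeat near
the srRNA end, a 21 bp × 20 array near the trnI end, repeat units
markedly less A+T-rich (0.64) than the nonrepeat core (0.88), and planted
poly-A (23 bp), poly-T and poly-AT runs; a TAGTA motif at the ND1/trnS2
junction in a configurable placement class; PCG lengths from the study
annotation, all open reading frames under table 5, ND5 starting GTG and
ATP6 ending in a truncated "T" stop; tRNAs of 65 bp except trnS1 (54) and
trnV (73).

Composition targeting solves per-base probabilities analytically from
(A+T, AT skew, GC skew). Two refinements keep the realised genome on
target without any stochastic fitting: the sense-codon sampling
distribution is calibrated by a short fixed iteration so that excluding
stop codons does not bias PCG composition, and all sampling draws exact
largest-remainder multisets in random order, so targets are met by
construction (observed absolute errors below 0.002 at 15 kb) while the
arrangement stays random and fully seeded. Minor-strand genes sample from
the complement-reflected distribution so their major-strand projection
hits the same target; an optional `minor_at_skew` plants the T-rich minor
strand of real genomes. Infeasible targets (any base probability
outside a workable range) error before sampling. For motif placement
inside the 3′ end of minor-strand ND1, the gene's final codons are chosen
(Tyr TAC + stop TAA) so the major strand reads TAGTA without breaking the
reading frame; the generator verifies the plant and errors rather than
silently overlapping an ORF.

What the generator does *not* emulate: indels and length variation,
realistic rRNA/tRNA secondary structure, codon-usage correlations beyond
composition, origin-spanning features, or heteroplasmy. Passing tests on
synthetic data therefore establish that the algorithms recover planted
structure under the stated statistical conditions — not that real
annotations are error-free, and not that the NG86 assumptions (equal
mutation rates, no transition bias) hold in real mitogenomes.

`simulate_cds_pair()` evolves a uniformly drawn sense-codon ancestor by
single-nucleotide proposals accepted with probability 1 (synonymous) or ω
(nonsynonymous), rejecting stops, so the realised instantaneous dN/dS is ω
by construction. `simulate_population()` applies independent per-gene,
per-site substitutions at stated rates.

## Problem sizes and determinism

The test suite validates at sizes chosen to make sampling error negligible
relative to the tolerances: ω-recovery over 200 replicates (500 at ω = 1)
of 500-codon pairs at proposal density 0.2 per site; gene-order
classification over 50 random origin rotations per arrangement type;
breakpoint distance against an independent oracle on 100 random signed
permutations; repeat recovery over 100 random plantings; skew antisymmetry
over 1000 random strings; divergence ordering on a six-individual
population with per-gene rates spanning 0.001–0.016 (adjacent rates a
factor two apart, comfortably separable with 15 pairwise distances per
gene). Every stochastic computation is seeded; the generator is
byte-deterministic given (config, seed).

## Known limitations

* GenBank parsing covers the flat-file subset needed for mitogenome
  records (single-span and single-`join` locations, the common feature
  keys); it is not a general GenBank reader.
* Breakpoint distance collapses duplications, so tandem copy-number
  changes are invisible to the distance (by design; they are reported in
  the duplication map).
* The repeat finder reports maximal non-crossing arrays; genuinely nested
  or crossing repeat structures are resolved greedily, not enumerated.
* NG86 with Jukes–Cantor saturates near p = 3/4; deeply diverged pairs
  return `NA` rather than a number.
* p-distance is uncorrected by design; for interspecific comparisons a
  model-corrected distance should be used instead.
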
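# mitocomp

Comparative analysis of circular insect mitochondrial genomes, written for
the kind of question a planthopper (or any insect) mitogenome study asks:
how biased is the nucleotide composition and how does it differ between the
two strands; how tightly are the 37 genes packed on the circle (intergenic
spacers vs. overlaps); has the gene order rearranged relative to the
ancestral insect arrangement; what tandem-repeat architecture does the
A+T-rich control region carry; how strong is purifying selection on the
protein-coding genes; and which genes are most variable within a species.

The package is aimed at people annotating and comparing newly sequenced
mitogenomes. Everything operates on a single container, the `mitogenome`
record: a circular genome length, an ordered feature table (1-based
inclusive coordinates on the major strand, minor-strand features flagged),
and optionally the sequence. Records come from GenBank flat files, from
plain TSV feature tables, or from the built-in simulator.

## The statistics at the core

* **Compositional skew.** AT skew = (A − T)/(A + T), GC skew =
  (G − C)/(G + C), always computed from major-strand letters. Minor-strand
  gene sets are deliberately *not* reverse-complemented, so the
  characteristic T-richness of the minor strand is visible as a strongly
  negative AT skew.
* **Circular spacer/overlap accounting.** For consecutive features
  (both strands interleaved, plus the wrap-around pair),
  gap = start(next) − end(prev) − 1; positive gaps are intergenic spacers
  (ISS), negative gaps overlaps. The A+T-rich region is treated as a
  boundary: its two flanking junctions are reported separately and excluded
  from ISS totals. Feature lengths + spacers − overlaps + control region +
  its flanks tile the circle exactly.
* **Gene-order typing.** Gene orders are signed circular permutations
  rotated to start at trnI. Type A is the ancestral insect arrangement;
  B adds a trnC–trnW transposition at the ND2/trnY junction and rewrites
  the ND4L–CytB block from trnT,trnP,ND6 to ND6(inverted),trnP,trnT;
  B′ triplicates trnC; C additionally moves trnH from the ND5/ND4 junction
  to just upstream of ND6. Anything else is "novel", reported with the
  nearest type by signed breakpoint distance.
* **Ka/Ks.** Nei–Gojobori (NG86) counting under the invertebrate
  mitochondrial code (translation table 5) with equal-weight averaging over
  stop-free mutational pathways and Jukes–Cantor correction; ratios well
  below 1 indicate purifying selection.
* **Control-region architecture.** A seeded self-match tandem-repeat finder
  (period-p lag comparison, exact-run seeds, block-wise extension)
  decomposes the A+T-rich region into repeat arrays and nonrepeat segments
  with per-segment A+T content and poly-A/T/AT runs.
* **Intraspecies divergence.** Uncorrected p-distances with pairwise
  deletion per gene (and for the 658-bp COI barcode prefix), summarised as
  min/median/mean/max across all record pairs.

A seeded generator (`simulate_mitogenome()`) produces annotated genomes
with all of this structure planted at known coordinates — gene order types,
composition and skew targets, open reading frames under table 5, a junction
motif, repeat arrays — so every analysis can be validated against exact
truth.

## Worked example

```r
library(mitocomp)

h1 <- example_mitogenome("Mpruinosa_H1")   # packaged coordinate table
h1
#> <mitogenome> Mpruinosa_H1 (Metcalfa pruinosa (haplotype H1))
#>   length: 16312 bp, circular
#>   features: 38 (13 PCG, 22 tRNA, 2 rRNA, 1 control)
#>   sequence: absent

adjacency_report(h1)
#> <adjacency_report> Mpruinosa_H1
#>   spacers: 147 bp over 21 regions; overlaps: 21 bp
#>   longest spacer: 25 bp (trnR-trnN)
```

The 147 bp over 21 regions and the 25-bp trnR–trnN spacer are the genome's
hand-countable packing statistics, recomputed from coordinates alone;
`circle_conservation(h1)` returns `0`, confirming the annotation tiles the
16,312-bp circle exactly.

With sequence (here simulated), the composition, control-region and
selection analyses come into play:

```r
sim <- simulate_mitogenome(sim_config(seed = 42))
skew(sim$record$sequence)
#> AT skew: 0.2481   GC skew: -0.2593

region_architecture(sim$record)
#> <region_architecture> sim_A_42 (1542 bp)
#>   repeat        1-  152    152 bp  AT 63.8%
#>   nonrepeat   153- 1082    930 bp  AT 88.6%
#>   repeat     1083- 1502    420 bp  AT 61.9%
#>   nonrepeat  1503- 1542     40 bp  AT 92.5%

p <- simulate_cds_pair(500, omega = 0.1, t = 0.2, seed = 42)
pairwise_kaks(p$cds1, p$cds2)
#> <kaks_result> 500 codons (0 skipped)
#>   S=377.52 N=1122.48  Sd=74.00 Nd=26.00
#>   Ks=0.2272 Ka=0.02353  Ka/Ks=0.1036
```

The genome-wide skews sit on the configured targets (0.25 / −0.26); the
control region shows the four-part architecture (a truncated 2.5-copy
two-part repeat, an A+T-rich core, a 21 bp × 20 array, a short tail) with
the repeat arrays markedly less A+T-rich than the core; and the Ka/Ks of a
pair simulated under dN/dS = 0.1 is estimated at 0.104 — purifying
selection recovered.

A thin command-line wrapper over the same functions is included at
`inst/scripts/mitocomp.R`
(`Rscript inst/scripts/mitocomp.R spacers <record.tsv>`, `order-classify`,
`motif-scan`, `control-region`, `kaks`, `divergence`, `simulate`,
`summarize`, `run`).

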
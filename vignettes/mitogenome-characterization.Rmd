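---
title: "Characterizing circular mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
library(dplyr)
```

`mitochar` computes the standard characterization battery for animal
mitochondrial genomes: annotation arithmetic on circular coordinates,
per-region nucleotide composition and strand skews, codon usage and RSCU
under the invertebrate mitochondrial code, gene-order rearrangement
detection, and control-region element scanning. This vignette explains the
underlying procedures, their assumptions, the tunable parameters, and the
design decisions taken where conventions in the literature are ambiguous.
The running example is the box tree moth *Cydalima perspectalis*
mitogenome (GenBank KY865331), whose published annotation and codon-count
tables ship with the package as plain-text fixtures.

## Annotations and circular coordinates

An annotation is a plain tibble: one row per feature with 1-based inclusive
coordinates (the GenBank convention), a strand in {F, R} (majority and
minority strand), and a category in {PCG, tRNA, rRNA, control}. A feature
with `end < start` wraps the circular origin; its length is
`genome_length - start + 1 + end`. The intergenic spacer after feature *i*
is `start(i+1) - end(i) - 1`, so overlapping neighbours produce negative
spacers, and the last feature pairs with the first across the origin. This
gives the tiling identity — feature lengths plus spacers sum exactly to the
genome length, overlaps entering as negative spacers — which the test suite
checks on random annotations.

Parsing is deliberately forgiving about the dialects found in published
summary tables: `Location` ranges with en-dash or hyphen, thousands
separators, RNA-alphabet anticodons (normalized to DNA), and aliased gene
labels (`16S`/`12S`/`A + T-rich` map to `rrnL`/`rrnS`/`control_region`).
It is deliberately strict about arithmetic: a declared `Size` column that
disagrees with the computed length raises a warning reporting both values,
because published tables do contain slips and silently trusting either
number would hide them. In the shipped *C. perspectalis* table every
printed size and every printed intergenic value is consistent with the
coordinates under the definitions above, including the circular closure
after the control region.

## Composition and skew

For a region with base counts $A, T, G, C$:

$$\mathrm{AT\text{-}skew} = \frac{A-T}{A+T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G-C}{G+C}$$

Both are scale-invariant (percentages and raw counts give the same value),
antisymmetric under swapping the paired bases, and bounded in $[-1, 1]$. A
zero denominator is an explicit undefined-skew error in the scalar
functions; inside `composition_table()` it is flagged as `NA` instead, so
one degenerate region cannot abort a whole report.

Region classes are built by concatenating the strand-corrected member
feature sequences, counting overlapping bases once per feature, so a region
size is the plain sum of feature sizes. This matches how the published
composition table for this mitogenome totals its tRNA (1473 bp) and rRNA
(2139 bp) rows. Its PCG row prints 11,202 bp, which is neither the plain
sum of the printed PCG sizes (11,209) nor that sum minus the annotated
overlaps; `mitochar` reports the plain-sum semantics consistently rather
than reproducing the printed value, and the same table's control-region row
prints positive skews although its printed percentages imply negative
ones — here too the package reports the formula's signed value. Raw doubles
are kept everywhere; rounding (half away from zero, via `round_half_up()`)
is applied only in the writers, at the conventional printed precision
(one decimal for percentages, three for skews, two for RSCU).

## Codon usage under translation table 5

Coding sequences are read in frame from position 1 of the strand-corrected
sequence. The remainder modulo 3 becomes trailing bases and drives the stop
classification:

* remainder 0 with terminal TAA/TAG → `complete_TAA` / `complete_TAG`;
* trailing exactly `T` or `TA` → `incomplete_T` / `incomplete_TA`
  (completed to TAA by polyadenylation of the transcript);
* anything else → `non_canonical`.

The flag matters in practice: the shipped annotation lists a single-T stop
for four genes whose annotated lengths are divisible by three, which cannot
both hold. `decompose_gene()` surfaces such rows as `non_canonical` instead
of guessing. Trailing bases other than exact `T`/`TA` (for example `TT`)
are also classified `non_canonical` rather than treated as incomplete
stops; the conservative reading keeps the incomplete classes unambiguous.

The genetic code is injected, not hardcoded: `mito_genetic_code(5)` derives
the invertebrate mitochondrial table (ATA→Met, TGA→Trp, AGA/AGG→Ser, stops
TAA/TAG) from the standard NCBI tables, so other translation tables can
reuse the module. Synonymous families group codons by amino acid — Leu 6,
Ser 8 (UCN + AGN), Arg CGN only — and the stop pair {TAA, TAG} forms its
own two-codon family, mirroring published codon tables that assign the
terminal-codon class an RSCU (11 terminal UAA over a family mean of 5.5
gives RSCU 2). Terminal stop codons are excluded from the default counts
("codons except for the termination codons") while in-frame internal
TAA/TAG occurrences are kept; `include_stops = TRUE` exposes the other
tally. Internally codons live in the DNA alphabet; the RNA alphabet is used
only for display.

On the shipped printed counts, every one of the 64 published RSCU values is
reproduced at two decimals, the 62 sense-codon counts sum to 3723, and the
amino-acid class totals (Leu(UUR) 484, Ile 469, Phe 374) match.

## Gene order

`extract_gene_order()` orders gene features (control region excluded) by
start coordinate on the majority strand; a tie is an error because the
order would be ambiguous. Two circular orders are compared by rotating both
to a shared anchor gene (default `cox1`, present and syntenic in both
orders here; configurable) and taking a longest common subsequence of the
gene names. The complement of the LCS is a minimum set of genes whose
relocation explains the difference — the test suite verifies minimality
against exhaustive subset search for orders of up to eight genes, and
verifies that the moved set for a single translocation is independent of
the anchor. When several minimum sets exist the LCS backtrack prefers
keeping earlier reference genes; only the set size is guaranteed canonical.
Strand signs are carried but ignored by default, since the typical tRNA
rearrangement is a translocation, not an inversion; `strict = TRUE`
additionally flags strand flips. For the shipped annotation against the
ancestral insect arrangement the moved set is exactly `{trnM}`: the derived
trnM–trnI–trnQ cluster of Lepidoptera.

`ancestral_insect_order()` returns the canonical 37-gene ancestral
arrangement with *Drosophila*-like strand assignments; the diagnostic
trnI–trnQ–trnM segment is the part that matters for the comparisons made
here, and the default name-only comparison is insensitive to the strand
column in any case.

## Control-region scanning

Four scanners cover the structural elements reported for insect control
regions, each returning 1-based hits with a literal unit/copies
description (`verify_hits()` re-extracts every hit and checks it):

* `find_motif()` — all, possibly overlapping, occurrences; `N` wildcards;
  implemented on exact matching because the elements of interest are exact.
  The "ATAGG(A)-like" element is reported as the exact motif ATAGG extended
  by one base when an A follows.
* `find_homopolymer_runs()` — maximal single-base runs above a length
  threshold.
* `find_microsatellites()` — maximal perfect arrays of a given 1–6 bp
  unit, left-maximal on whole units, with a trailing partial unit counted
  in `end` but floored out of `copies`.
* `find_tandem_repeats()` — all maximal perfect arrays reported once, at
  their smallest period. The smallest-period rule keeps a dinucleotide
  microsatellite from being re-reported as a period-4 or period-6 repeat.

Defaults in `cr_scan_defaults()`: poly-T minimum 10 and poly-A minimum 8
(below the 17 bp and 10 bp stretches observed in this mitogenome, so both
are detectable with margin); AT-microsatellite minimum 10 copies (targeting
the long (AT)ₙ arrays of lepidopteran control regions while ignoring the
short chance arrays that AT-rich sequence produces constantly); tandem
repeats with minimum unit 5 and 2 copies. The unit-5 floor reconciles two
conventions in the literature — control regions are said to be rich in
tandem repeats, yet a region whose only repetitive element is a
dinucleotide microsatellite is reported as having "no repeats" — by
classifying period-≤4 arrays as microsatellites, not tandem repeats. All
thresholds are configurable per call.

Only the annotated strand of the control region is scanned, matching how
these elements are reported; scanning the reverse strand is a matter of
calling the scanners on the reverse complement.

## The synthetic generator

`generate_mitogenome()` exists so that every stage above can be tested
against known ground truth. Sequence is sampled i.i.d. per region class
from configurable base probabilities, then the discrete features are
overwritten at fixed positions: planned start codons, planned stop codons
or incomplete-stop trailing bases, and planted control-region elements. The
RNG is seeded explicitly per call and no global state is touched; identical
seeds give byte-identical artifacts.

Three mechanisms keep the ground truth exact:

1. **Critical overwrite pass.** Features are written in category order
   (RNAs, then PCG bodies, then the control region), with later writes
   winning inside annotated overlaps; afterwards every PCG start and stop
   is re-asserted at its exact coordinates. Two critical elements that
   demand different bases at one position are an infeasibility error — in
   the shipped profile the single shared position (the atp6 stop and cox3
   start both requiring an A) is compatible.
2. **Guarded planting.** Each planted control-region element is flanked by
   guard bases chosen so runs and arrays cannot extend past their planned
   span (left guard differs from the unit's last base, right guard from its
   first), keeping planted copy numbers exact.
3. **Background cleanup.** AT-rich background sequence constantly produces
   chance homopolymer runs and short repeats. After planting, the control
   region is re-scanned at the profile's thresholds and chance elements are
   broken by greedy point mutations (A/T substitutions across the offending
   span are tried before C/G, to preserve AT-richness), until the scanners
   report exactly the planted set. The manifest is then verified against
   the emitted sequence before return.

The default `perspectalis_profile()` reproduces the published layout of the
*C. perspectalis* mitogenome: 15,180 bp, the published coordinates, strands
and anticodons (hence the annotated overlaps, e.g. atp8/atp6 at −7 bp), the
published start codons including the CGA cox1 start, the published
per-region base composition, a 288 bp control region with the four
published elements planted, and the derived trnM–trnI–trnQ gene order. For
the four genes whose printed single-T stop is inconsistent with a length
divisible by three, the profile plans a complete TAA — the only stop
realizable at those coordinates; cox2 (682 bp) keeps its genuine
incomplete-T stop.

What the generator deliberately does **not** emulate: codon usage bias
beyond base composition (interior codons are i.i.d. sense codons, so
simulated RSCU is flatter than real mitogenomes), tRNA secondary structure,
substitution processes along a phylogeny, and sequencing error. Passing
recovery tests on generator output therefore demonstrates that the
analysis stages compute their statistics correctly on sequences with the
right layout and composition — not that they would resolve biological
signal from noise in real data.

Manifest recovery is exact for discrete quantities (region base counts,
codon counts, gene order, planted hits). The sampled composition hits its
target only in expectation: for the 288 bp control region at a 96% AT
target the binomial standard error is about 1.2 points, and the test suite
checks a ±2-point band under a fixed seed.

## Problem sizes and runtime

The property-based suite runs 1000 random scanner instances against naive
brute-force oracles (sequences up to 2 kb for the linear-time scanners;
up to ~220 bp for the quadratic tandem-repeat oracle, whose cost is in the
oracle, not the scanner), 40 random gene-order instances of up to 8 genes
against exhaustive search, and a handful of full 15.2 kb generator round
trips. The whole suite runs in about a minute on one core.

## Limitations

* Scanners find perfect repeats only; no k-difference or fuzzy repeat
  detection.
* Gene-order comparison reports a moved-gene set, not a rearrangement
  scenario (no tandem-duplication/random-loss reconstruction, no
  rearrangement distances).
* Whole-region skews only; no sliding-window or cumulative-skew
  origin-of-replication detection.
* The annotation model assumes unique gene names and at most one control
  region per genome.
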
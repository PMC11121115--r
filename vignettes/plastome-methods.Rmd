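---
title: "Comparative plastome analysis with plastomeDiag: methods and design"
author: "plastomeDiag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomeDiag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeDiag)
```

# Scope

`plastomeDiag` implements the comparative analyses that recur in studies
of closely related chloroplast genomes: characterising the quadripartite
structure and its junction sites, profiling intrageneric variation
(SNPs, indels, nucleotide diversity) along genus-level alignments,
locating diagnostic nucleotides ("diagnostides") that delimit genera or
species and ranking candidate superbarcode regions, and analysing
relative synonymous codon usage (RSCU) with clustering and tribe-level
rank tests. A synthetic-data layer generates plastome-like genomes,
grouped alignments with planted variation, and codon-biased coding
sets, so every stage of the pipeline can be validated against known
ground truth without downloading any accession.

The package does not perform read QC, assembly, annotation transfer,
alignment computation, phylogenetic inference or divergence dating;
alignments and trees are consumed, not produced.

# Quadripartite structure

A typical plastome is a circle of roughly 155 kb with two identical
inverted repeats (IRA/IRB, ~26 kb) separating a large and a small
single-copy region (LSC ~85 kb, SSC ~17 kb).  `findInvertedRepeats()`
finds the maximal pair of disjoint, **exact** reverse-complement
repeats on the circle by seeding with chunks of the reverse complement
(length half the minimum IR length, so any repeat above threshold
contains a full chunk), matching them exactly against the tripled
forward strand, and extending each anchor base-by-base in both
directions.  The genome is then rotated to the canonical linearization
LSC, IRB, SSC, IRA, with the longer single-copy region as LSC.

Design choices:

* **Exact matching, no mismatch tolerance.**  Real plastome IR pairs
  are near-identical and published IR lengths are single numbers,
  which presumes exact repeat arithmetic.  If a genome's IRs contain a
  mismatch, the detected length may differ by a few bases from an
  annotation that tolerated it; the package reports what is exactly
  repeated rather than silently correcting.
* **Minimum IR length 1000 bp** by default: far below real IRs and far
  above the longest chance inverted repeats in ~150 kb of sequence.
* **Ties abort.**  Two distinct maximal pairs of equal length signal a
  pathological input, so detection raises an error listing the
  candidates instead of picking one silently.
* Genomes with no repeat above threshold raise a distinct "no-IR"
  error: the genome is reported as non-quadripartite.

`junctionContext()` reports, for each junction (JLB, JSB, JSA, JLA),
the nearest gene and its signed distance -- negative with both split
lengths when the gene straddles the junction, as `rps19`, `ndhF` and
`ycf1` commonly do.  `geneInventory()` counts CDS/tRNA/rRNA per region,
assigning multi-region features to the region holding their larger
part, and flags genes duplicated across the two IRs.

Correctness is checked two ways: planted-truth recovery (the synthetic
generator knows its region lengths) and equivalence with an independent
O(n²) diagonal run-length scan on small circular genomes.

# Variation tracks

`callSNPs()` treats a column as polymorphic iff at least two distinct
unambiguous bases occur among the selected rows; gaps and IUPAC
ambiguity codes are never states.  This is the only defensible reading
of variant calling on a small multiple alignment -- the coverage-style
p-value cutoff of read-mapping variant callers has no analogue on an
8-row MSA, and the difference is documented rather than imitated.

`callIndels()` emits one event per maximal run of columns where exactly
one of (row, reference) is gapped; a gap in the row is a deletion, a
gap in the reference an insertion.  Events identical in (start, length,
side) across rows are counted once by default -- "number of indels"
counts events, not row-occurrences -- and the raw per-row view is a
switch away (`unique = FALSE`).

`nucleotideDiversity()` computes sliding-window pi: per window, the
mean over all row pairs of the pairwise difference proportion, with
**pairwise deletion** (each pair is compared over the columns where
both rows carry unambiguous bases).  Pairwise deletion loses the least
data in gap-sparse plastome alignments; complete deletion is available
as `deletion = "complete"` for sensitivity analysis.  Windows with no
comparable sites get value 0 and a flag.  The default window is 500 bp
with a non-overlapping step, the scan width conventional for plastome
divergence profiles; per-100 bp count tracks use window = step =
100 bp.  Both are parameters, since the step behind published "500 bp
window" scans is often unstated.

Alignment columns can be projected onto the ungapped coordinates of a
named reference row (columns gapped in the reference collapse onto the
preceding reference position); `regionPercentages()` uses this to
report per-region percentages, `100 * variants / region length`, over
genes, introns and derived spacers.

# Diagnostides and barcode ranking

Column *c* is a diagnostide for group *G* with state *s* iff every row
of *G* carries the same unambiguous base *s* at *c* and no other row's
state can be *s*.  Ambiguity codes expand to their base sets, so an
outgroup `R` (= A/G) blocks a focal A: a character that *might* be the
focal state disqualifies the column.  Gaps within *G* disqualify (a
diagnostic gap is an indel, which the variation module handles); gaps
in outgroup rows do not by themselves, since a gap neither equals nor
contains a base -- a stricter mode (`requireNonGapOutgroup = TRUE`) is
provided.  Only "pure/simple" diagnostics are reported (fixed within,
absent without); partly-diagnostic relaxations are out of scope.

The contrast is one-vs-rest within the supplied alignment (each genus
against the pooled others), which is what parallel per-genus tracks
over a common tribe alignment imply.  The predicate is monotone: adding
outgroup rows can only remove diagnostides, never add them -- a
property the test suite exercises directly.

`rankBarcodeRegions()` projects each group's diagnostides onto the
reference annotation, ranks genes/introns/spacers by diagnostide count
(with per-region window peaks and optional pi peaks alongside), and
intersects the per-group top-k lists into a "shared" list: regions that
delimit every group at once are the superbarcode candidates.

# Codon usage

`codonCounts()` splices multi-interval CDS features in transcription
order, reverse-complements minus-strand genes, trims to a codon
multiple and skips ambiguity-containing codons (reporting the skip
count).  IR-duplicated genes count once per annotated occurrence by
default; `dedupeByName = TRUE` collapses them, since published
analyses rarely state their handling.

RSCU is the observed codon count divided by the count expected were
all synonymous codons of the amino acid used equally:
RSCU~ij~ = X~ij~ / ((1/n~i~) Σ~j~ X~ij~).  The three stop codons
{TAA, TAG, TGA} form a family of their own so stop-codon preference is
analysable like any other; single-codon families (ATG, TGG) always give
1 when observed; unobserved families give `NA`, never 0.  Per species
and family the values sum to n~i~ -- an identity the tests assert
matrix-wide.  Genus-level RSCU pools counts first and then computes
(`genusRSCU()`); averaging per-species RSCU is a different, biased
quantity, and the tests demonstrate the difference.

`clusterRSCU()` clusters species by Euclidean distance between RSCU
vectors with complete linkage by default (the convention of the heatmap
tooling used for such figures; average and Ward linkage are switches).
`NA` values are imputed with 1, the no-preference value, so unobserved
families carry no signal.  Rows are sorted by species id first, making
leaf order deterministic.

`compareClustersToClades()` finds, per tribe, the smallest dendrogram
cluster and the smallest phylogenetic clade maximizing F1 against the
tribe's species set and reports membership differences: tribe members
in the clade but outside the cluster ("left the cluster") and foreign
intruders.  Identical topologies therefore give an empty report
regardless of whether tribes are monophyletic.

`tribeCodonTests()` runs, per codon, a Kruskal-Wallis test across
tribes (base R `kruskal.test`, tie-corrected) followed by pairwise Dunn
z tests with Bonferroni adjustment over the tribe pairs (conservative
and standard; the adjustment is a parameter).  Significance tiers are
`*`/`**`/`***` at adjusted p < .05/.01/.001; the top tier `****` is
reserved for pairs whose value ranges do not overlap at all, the
"complete separation" reading used in the figures this analysis
emulates -- a p-based 1e-4 cutoff would be unreachable for adjacent
groups at realistic tribe sizes.  Codons constant across all species
have an undefined H and are reported flagged with p = 1.

# Synthetic data: what it emulates, what it does not

`simulatePlastome()` builds LSC + IRB + SSC + revcomp(IRB) from i.i.d.
background at GC 37% (the plastome norm), places non-overlapping genes
per region, mirrors IR genes into both copies, and plants genes
straddling the JLB and JSB junctions to mimic the rps19/ndhF layout.
Two boundary characters are resampled so the planted IR pair cannot
extend by a chance complementary base across a junction -- without
this, "exact recovery of the planted lengths" would fail in roughly
7 of 16 draws for reasons that have nothing to do with the detector.
Default lengths (84,976 / 17,127 / 26,254 bp) match a real Galium-type
plastome; tests and the acceptance script use scaled-down draws
(LSC 6-10 kb, SSC 1.5-3.5 kb, IR 1.2-2.8 kb) so the whole suite runs in
minutes while exercising identical code paths.

`simulateGroupedAlignment()` plants group-shared diagnostic states,
then adds private SNPs and private gap runs per row.  Planted columns
are kept noise-free in **all** rows: a private substitution in an
outgroup row could otherwise recreate the focal state and destroy the
diagnostic property, making exact-recovery guarantees impossible by
construction rather than by implementation error.  Gap runs overwrite
characters, so rows keep the base length; a gap run planted in the row
used later as reference is what `callIndels()` reports as an insertion
in the other rows.  The returned truth ledger (planted columns, SNP
positions, gap events per row) is sufficient to score recovery for
every downstream operation.

`simulateCodingSet()` draws codons i.i.d. within each synonymous family
from user weights (uniform by default), with the analytic expectation
RSCU = n~i~ w~ij~ returned alongside.

What the generators do **not** emulate: phylogenetic correlation
between rows (rows are i.i.d. around the base), aligner-induced gap
placement artefacts, mutational spectra (transition bias), IR
mismatches, or realistic gene content.  Passing the planted-truth suite
therefore shows the statistics are computed correctly, not that the
biological conclusions drawn from any particular real data set are
robust to alignment error.

All generators are pure functions of their integer seed and leave the
global RNG untouched.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally (the Biostrings/GRanges
  convention); the BED-like track TSVs are 0-based half-open, and
  `bedToGenbank()`/`genbankToBed()` is the single conversion point.
* pi uses integer difference/comparable counts per pair; no floating
  accumulation differences from the brute-force oracle (the acceptance
  check requires max |deviation| = 0).
* GC content excludes ambiguity codes from numerator and denominator;
  an all-ambiguous sequence is an error, not 0.
* Empty feature lists, all-gap columns, constant codon values and
  single-species genera each have a defined behaviour (error, empty
  result, flagged p = 1, species-equal RSCU respectively) chosen to
  fail loudly where silence would bias results.

# Pipeline

`runPipeline()` drives structure → variation → diagnostides → codon
usage from a single config (R list or YAML), writing TSV/JSON outputs
and a manifest with config echo and per-file MD5s; identical config and
inputs give byte-identical outputs.  `simulateFixtures()` writes a
complete synthetic input bundle (annotated GenBank genome, aligned
FASTA, group map, coding set, truth JSON) whose config feeds straight
into `runPipeline()`.

```{r pipeline-example, eval = FALSE}
fx <- simulateFixtures(tempfile("fixtures"), seed = 1)
runPipeline(fx$config)
```

# Known limitations

* IR detection is exact-match only; a single mismatch inside a real IR
  truncates the detected repeat at that mismatch.
* The junction report assumes features near a junction do not span
  three regions.
* Diagnostide analysis treats rows as exchangeable within groups; it
  does not model within-group polymorphism ("partly diagnostic"
  columns are simply not reported).
* The GenBank parser covers the subset of the format that plastome
  records use (LOCUS, FEATURES with join/complement locations, ORIGIN);
  it is not a general-purpose GenBank implementation.
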
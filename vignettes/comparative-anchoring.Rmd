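---
title: "Methods: anchoring and comparing a haplotype-resolved genome pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchoring and comparing a haplotype-resolved genome pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`anchorpair` implements the post-assembly comparative workflow that follows
trio or hifi assembly of the two parental genomes of an F1 hybrid: placing
one assembly's contigs on linkage groups using genetic maps, interpreting a
whole-genome alignment between the two assemblies, quantifying repeat
content and its association with assembly breaks, characterising tandem
satellite repeats at the k-mer level, and matching gene models across the
two annotations. Every stage consumes and produces plain tabular data
(tibbles), and a fully truth-tracked simulator generates inputs for all of
them, so the package validates itself without any external download.

All internal coordinates are 0-based half-open. The 1-based conventions of
GFF3, AGP and tabular hit files are converted at the I/O boundary only, so
no module ever re-parses a file or re-shifts a coordinate.

# Linkage anchoring

Markers are short genotyping-by-sequencing loci aligned to the assembly as
nucleotide hits. Hits are kept when their E-value is strictly below
`e_max = 4e-24` — a stringency that tolerates several SNPs in a ~90-bp
locus while rejecting paralogous placements — and each marker keeps its
single best placement (lowest E-value, then highest bit score; a tie drops
the marker, since it cannot be placed uniquely).

A contig joins the linkage group holding the strict majority of its
markers; when two or more groups are represented the winner must hold at
least two-thirds of the markers, otherwise the contig is flagged as a
chimera candidate and left unassigned. Within a group, contigs are ordered
by the median genetic position (cM) of their markers, with deterministic
tie-breaks (marker count, contig length, contig id).

Orientation uses the sign of the Spearman rank correlation between genetic
(cM) and physical (bp) marker positions. The correlation sign equals the
sign of the recombination-distance trend for any monotone signal, which is
what pairwise recombination fractions measure, but it works directly from
map positions. A contig is *eligible* for orientation only with at least
`min_markers = 3` markers spanning at least `min_span = 30` kb — with fewer
markers or a shorter baseline the rank correlation is dominated by marker
placement noise. Both thresholds are exposed as arguments.

Contigs mapped only by secondary crosses are inserted using contigs shared
between that cross and the primary placement: the candidate's nearest
placed neighbours in the secondary map order must exist on one primary
linkage group and be adjacent there; anything weaker is flagged
`unresolved_insertion` and the contig stays unplaced. This conservative
rule never reorders primary placements.

A reference-guided order (for example, from scaffolding against the other
haplotype's assembly) fills in orientation where linkage was silent; where
both sources orient a contig and disagree, the linkage orientation is kept
and the disagreement flagged. Scaffolds are emitted one per linkage group
with fixed 100-bp `U` gaps (AGP v2.1, gap type `scaffold`, linkage `yes`,
evidence `map`); unoriented contigs are written with orientation `?` and
used in their forward sense.

# Whole-genome alignment interpretation

The PAF of assembly B against assembly A is filtered by block identity
(`matches/alnlen >= 0.9`) and length (>= 10 kb), then any block whose query
interval overlaps another retained block is removed, leaving uniquely
aligning sequence. The identity and length defaults are deliberate,
exposed parameters: the workflow's intent is "drop low identity and
multi-mapped sequence", and 0.9/10 kb are sensible for congeneric species
at sub-percent divergence. Multiplicity is judged on the query axis by
default (switchable), matching the direction the alignment was computed in.

From the filtered set the package computes the fraction of each genome in
one-to-one alignment (per-base depth exactly 1, via run-length coverage);
nonaligning regions of at least 100 kb, each classified
`repeat_associated` when at least half its bases fall in the merged repeat
set (annotation tracts plus tandem-finder tracts) and `unique` otherwise;
and inversions, as maximal runs of opposite-strand blocks within a
(query contig, target contig) pair whose query span reaches 100 kb, the
pair's majority strand (by aligned bp) serving as the flanking strand.
Runs touching the end of a pair's block list are reported but flagged low
confidence, since the orientation of a whole contig is arbitrary. The
duplication screen deliberately uses alignments *before* multiplicity
filtering — multiple alignment is the very signal — and reports maximal
runs of depth >= 2 over >= 100 kb.

# Repeat statistics

Repeat annotations are collapsed per contig into disjoint tracts (abutting
intervals merge), each tract remembering the set of contributing repeat
classes. Tract counts and the cumulative length distribution are computed
on these merged units; per-class tables attribute a multi-class tract once
to every class, so by-class totals may exceed the merged total (flagged in
the output).

Terminal intervals are the first and last 5 kb of every contig at least
10 kb long — the floor avoids counting one short contig as both of its own
termini. Random windows are drawn with the contig chosen proportionally to
its number of eligible start positions and the start uniform; overlaps
among windows are permitted. Enrichment of repeat bp in terminal versus
random windows is tested with a two-tailed Welch t-test (the groups have
very different sizes and variances; equal-variance pooling would be
wrong). Two degenerate cases are defined rather than errors: identical
constant groups give t = 0, p = 1; constant groups with different means
give p = 0.

# Tandem satellites at the k-mer level

Canonical k-mer counting (lexicographic minimum of a window and its
reverse complement, windows containing N skipped) is implemented in C++
with 2-bit packing for k <= 32; 28 is the unit length of the satellite this
workflow was built around. Tandem arrays are found by exact self-match at
lag k — positions where the word at `i` equals the word at `i + k` —
chained with spacers up to `2k` tolerated inside one array, so short
interspersed elements do not fragment an array. Copy number is the union
coverage of the seed windows divided by k, which is exact for clean arrays
and robust to interruptions. Because a tandem motif has arbitrary phase
and strand, arrays are grouped by their *canonical rotation class*: the
lexicographic minimum over all rotations of the motif and of its reverse
complement, an invariant of both operations.

Cross-sample screening sums counts of all class members and normalises to
copies per megabase, so assemblies and unassembled read sets of different
sizes are comparable; the presence threshold (default 1 copy/Mb) is
configurable because no universal cutoff exists.

The general tandem-tract finder (`find_tandem_repeats()`) is a simplified
match-fraction model: for each period p it grows maximal runs where the
base at `i` matches the base at `i - p` in at least `min_match = 0.8` of
positions, resolves overlapping calls by `copy_number x match_fraction`
(ties to the smaller period), and reports the per-column majority
consensus. It is *not* an alignment-based tandem finder: at
`min_match = 1` it provably returns the maximal exact tandem runs (this is
property-tested against a quadratic brute force), and at lower thresholds
it is a desk-scale characterisation tool, not a genome-wide annotator.

# Gene-model comparison

Reciprocal best hits use bit score (ties: lower E-value, then lexicographic
subject) and keep a pair only when both directions agree; the result is
symmetric in its inputs. Annotation concordance is scored as
`AED = 1 - (SN + SP)/2` at nucleotide resolution, where SN and SP are the
shared bp over evidence bp and over model bp — 0 means identical
nucleotide sets, 1 disjoint.

The lift-over is a block transform through the filtered one-to-one
alignment: an exon lifts when at least half its bases are covered by
blocks of one consistent strand, endpoints mapped by offset (reflected
through minus blocks, with the strand flipped) and clipped to block
bounds; a gene lifts when any exon lifts. At zero divergence the
round-trip lift is the identity, which the tests assert. Lifted genes are
matched to the other annotation by any same-strand exon overlap of at
least 1 bp; a lifted gene overlapping two or more genes is flagged as a
fragmentation (`split`) event. Open-reading-frame validity of a
concatenated CDS requires length >= 6 and divisible by 3, an ATG start, a
terminal stop, and no internal stop under the standard code; ambiguous
characters make a CDS invalid rather than erroring.

The linkage-group-to-chromosome correspondence matrix bins reciprocal
pairs by the linkage group of one gene and the chromosome label of the
other, ignoring gene order, row-normalises, assigns each linkage group its
argmax chromosome, and flags a chromosome as split when two or more
linkage groups each hold at least 20% of its pairs — a threshold loose
enough that any genuinely two-armed split passes while stray single pairs
do not.

# The synthetic study

The generator (`sim_config()`, `simulate_study()`) emulates the study
design end to end. One simulated ancestor per chromosome receives planted
repeat tracts (long tracts of 6–12 kb are the contig-break targets;
short background tracts diversify composition), one tandem array of a
28-bp satellite per chromosome, tandem gene arrays and singleton genes
(valid ORFs, some with two exons), and inversions. The ancestor serves
directly as species A's coordinate backbone (A receives substitutions
only), while species B carries all structural divergence: satellite
expansion by the configured bias, extra gene-array copies (a configurable
fraction planted with an in-frame premature stop), optional large
duplication or unique insertion, small indels, and the inversions. Which
lineage carries a change is unidentifiable from a pairwise comparison, so
this convention costs no generality and keeps every truth coordinate
exact. Substitutions are applied at half the configured rate per lineage,
so `snp_rate` is the pairwise divergence.

Defaults are chosen to mirror the study conditions at desk scale: five F2
intercrosses (the first is the primary map; one mid-chromosome contig per
chromosome is hidden from it so secondary-map insertion is genuinely
exercised; the second cross carries every marker), 0.5% pairwise
divergence (congeneric species), a two-fold satellite expansion in B,
gene arrays gaining two copies in B with 40% of new copies ORF-broken,
80% of contig breaks placed inside long repeat tracts, and inversions of
120–200 kb so the 100-kb structural-variant threshold is meaningful. The
default genome is three chromosomes totalling 4.7 Mb — large enough that
every stage's thresholds (30-kb orientation spans, 10-kb alignment blocks,
100-kb inversions) operate at their defaults, small enough that the full
pipeline runs in about two minutes.

Evidence is emitted from truth, not from external tools: marker hits place
each marker at its true contig offset with passing E-values drawn
log-uniform on (1e-60, 1e-30) and decoy or false hits that exercise the
filter (decoys fail the 4e-24 cutoff; false hits pass it but point at the
wrong contig, at the configured rate); the PAF follows the truth blocks,
split at inversions, insertions and contig boundaries, with match counts
computed by comparing the actual sequences; protein hit tables score
orthologs above within-array paralogs above decoys, so reciprocal-best
analysis is non-trivial; and the reference-guided order table is derived
from the fragmentation truth.

What the simulator does *not* emulate: sequencing errors and read-level
artefacts, alignment-method idiosyncrasies (chaining breaks, soft
clipping), gene-structure complexity beyond one or two exons, segregation
distortion, and genotyping error in the crosses. Passing tests therefore
demonstrate the correctness of the downstream logic under a faithful data
model, not robustness to every artefact of real pipelines.

# Numerical and degenerate-input choices

* Kendall and Spearman correlations, Welch tests, isotonic regression and
  binomial draws come from base R (`stats`); interval arithmetic from
  IRanges.
* Map noise is applied in cM and clamped monotone by isotonic regression,
  then shifted to start at zero — emitted maps are valid maps by
  construction.
* The Haldane map function (no crossover interference) backs the cross
  simulator: `cM = -50 ln(1 - 2r)`, exact inverse used throughout.
* Ties: hit filtering (bit score, then drop), ordering (marker count,
  length, id), overlap resolution in the tandem finder (score, then
  smaller period), RBH best hits (E-value, then subject id) are all
  deterministic, so equal inputs give byte-identical outputs.
* Empty inputs return typed empty tibbles rather than NULL; truly
  undefined statistics (e.g. overlap percentages with no long tracts)
  return 0 with a warning.

# Validation strategy and problem sizes

The test suite runs the generator at two scales: a ~0.9 Mb two-chromosome
study for unit-level checks and a 4.7 Mb three-chromosome study for the
end-to-end recovery checks. At zero noise the pipeline must recover the
truth exactly: linkage-group assignment 100%, Kendall tau of 1 per linkage
group, all eligible orientations correct, inversion precision and recall
of 1, the satellite's rotation class and consensus exactly, the planted
two-fold expansion ratio, and all true ortholog pairs with no false pairs.
Under 5% marker false hits and 1 cM map noise, orientation accuracy is
required to stay at or above 0.9 across ten seeds. Core primitives are
checked against independent brute-force oracles (per-base bitmaps for
interval collapse and coverage, a naive dictionary for k-mer counting, a
quadratic scan for exact tandem runs, a double loop for reciprocal best
hits). `scripts/acceptance.R` re-runs all of this from scratch at a
caller-supplied seed and writes the headline numbers as JSON.

# Known limitations

* The tandem-tract finder's match-fraction model has no indel handling;
  tracts with frequent length-changing mutations are fragmented or missed.
* Secondary-map integration only inserts between adjacent primary
  neighbours; denser secondary maps that could resolve longer-range
  placements are left flagged instead.
* The lift-over maps each exon through blocks independently; it does not
  stitch exons across distant blocks or detect trans-lifts.
* Coverage profiles are exact but in-memory per contig; chromosome-scale
  mammalian assemblies would want an Rle-backed streaming variant.
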
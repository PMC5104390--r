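---
title: "Neoepitope discovery with cancertope: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoepitope discovery with cancertope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancertope)
```

## The problem

A tumor's somatic mutations produce proteins that the patient's healthy
tissue never expresses. Short peptides spanning the altered residues —
neopeptides — can be presented by HLA molecules and recognized by T
cells, or bound by antibodies, making them attractive vaccine and
immunotherapy candidates. Two failure modes dominate candidate design:
picking peptides that also occur somewhere in the normal human peptide
space (cross-reactivity and autoimmune risk, or simply tolerance), and
picking peptides that no arm of the immune system responds to. This
package implements the computational pipeline that addresses both: exact
screening of candidate peptides against layered "self" proteomes, and
pluggable per-arm immunogenicity classification, wrapped around the
variant-to-peptide translation machinery that produces the candidates in
the first place.

## From mutation record to mutant protein

Mutation records use 1-based cDNA coordinates on the coding sequence,
starting at the A of the initiator ATG, with a small grammar
(`c.4G>T`, `c.4_5insA`, `c.4_6del`, `c.4del`). Four protein-level
classes are supported: missense, frameshift (insertion or deletion whose
length is not a multiple of three), and in-frame insertion/deletion.
A record whose declared class contradicts its parsed edit (for example a
two-nucleotide "in-frame" insertion) is a row-level error — reported,
never silently dropped. Insertions are anchored *after* the stated
position; upstream conventions that write an insertion between positions
p and p+1 collapse to the same anchor.

Translation is codon-by-codon with the standard genetic code, stopping
at the first stop codon. Three flags describe mutant-specific anomalies:
`start_lost` (the edit destroyed the ATG; the empty protein is kept,
flagged), `new_stop_gained` (premature stop, the frameshift norm) and
`no_stop_found` (the frameshift ran off the end of the transcript; all
complete codons are kept — we retain such products rather than discard
them, since their upstream novel sequence is real).

The **altered mask** marks which mutant residues differ from wild type:

* missense and in-frame events: compare mutant and wild type from the
  N-terminus and from the C-terminus inward; the unmatched middle
  segment of the mutant (including inserted residues) is altered. This
  two-pointer trim is the production path; it is the *definition* of
  altered, not an approximation.
* frameshift: every residue from the first codon overlapping the edit
  through the new C-terminus is altered — the downstream peptide is
  genuinely non-self.

Two consequences are worth stating plainly. A pure in-frame deletion
leaves no unmatched mutant residue, so it yields an empty mask and hence
no neopeptides: the junction windows it creates are not counted as
mutation-covering. And a frameshift whose first affected codon is
immediately a stop codon truncates the protein without introducing any
new residue; such records carry an all-false mask and produce nothing
downstream. Both are deliberate readings of the altered-residue
definition rather than oversights.

Mask placement inside repeated motifs deserves a note. When an in-frame
indel falls into a repeat, several minimal-edit alignments explain the
same mutant, and their changed-residue sets can differ. The trim
definition resolves the ambiguity deterministically (maximal prefix
first, i.e. rightmost placement). The test suite therefore checks the
production mask exactly against an independent re-derivation of the trim
definition, and checks *consistency* with a global pairwise alignment
oracle (an optimal alignment never needs more changed residues than the
trimmed middle segment holds) rather than exact equality, which
tie-broken gap placement cannot guarantee.

Each record yields one mutant protein. Co-occurring mutations in the
same gene and sample are not phased onto a single haplotype; no phasing
procedure is defined for the input data. Synonymous edits are flagged
silent and excluded before extraction.

## Neopeptides

The window length k defaults to 9 because both HLA class I and class II
binders have a nine-residue binding core; it is configurable but every
index, peptide and matrix in a run must share it. Extraction keeps
exactly the windows covering at least one altered residue, so a single
missense in the interior of a long protein yields nine windows, and
min(p, L−8) − max(1, p−8) + 1 in general. Windows containing the
ambiguous residue X are dropped (and counted): both exact self-matching
and matrix scoring are undefined for X.

De-duplication merges identical sequences, takes the union of sample and
tissue provenance, keeps the smallest window start, and sorts output
lexicographically — which makes it idempotent and insensitive to input
order ("first seen" would not be). Antigen scope (one row per gene and
sequence) is the default and feeds per-gene accounting; cohort scope
(one row per sequence) serves database building, pooling per-gene unions
over samples.

## The self-filter cascade

Self screening is exact 9-mer membership: a peptide is self if it occurs
verbatim as a window of any indexed sequence. Exactness is a deliberate
choice — the screen's published description is identity mapping, and the
fixed query length makes a hash set of distinct k-mers sufficient; no
substring automaton is needed, and isoleucine/leucine are not conflated
(no equivalence classes are defined for the screen). Near-match
(1-mismatch) tolerance modeling is out of scope.

The canonical cascade order is: reference protein of the same antigen,
reference proteome, population-variant forms of the antigen,
population-variant proteomes. A peptide is eliminated at the *first*
stage containing it and later stages are not consulted, so survival
flags are monotone and per-stage surviving counts are non-increasing —
the structural property the per-gene filter reports exhibit. Index
construction streams sequences and keeps only distinct k-mers, so peak
memory tracks the distinct k-mer count.

The standalone cross-reactivity screen is the same machinery applied to
*all* windows of a user antigen (no mutation masking), and the fully
personalized mode is the same cascade with the patient's normal proteome
compiled into an index and placed first. A normal input contributing no
k-mers contributes no stage, which makes a fully personalized run with
an empty normal byte-identical to the partially personalized run — a
tested identity.

## Candidate-gene prioritization

The cancer-association statistic is the ratio f_D/f_P of
deleterious (cancer-associated) to polymorphism/neutral variant counts
per gene. Ratios are rounded half-up to one decimal: half-up, not
round-half-even, because published per-gene tables print 58/8 = 7.25 as
7.3. f_P = 0 gives +Inf (the gene sorts first); both counts zero is an
undefined input. The selection rule keeps genes with ratio ≥ 2 and
f_D ≥ 20, ordered by descending ratio with f_D and gene id as
tie-breaks. The package ships the 34-gene reference table of counts
(`canProVarTargets()`); recomputing every ratio from its printed counts
reproduces the printed ratio column exactly, and the selection rule
admits all 34 rows.

The cohort frequency rule selects genes mutated in at least
floor(frac × cohort_size) *distinct* samples — 10% of a 905-sample
cohort is 90 — and the two rules merge as a union with per-rule
provenance recorded (the published candidate lists were disjoint; the
merge handles overlap should it occur). Expression binning counts cell
lines with expression at or above cutoffs 3, 7, 9 and 12 (≥, following
the column labels of the published table, whose prose says "more
than"); values at or above 9 are conventionally "highly expressed", and
genes absent from the matrix are reported as NA rather than zero.

## Immune arms

External epitope predictors (matrix and machine-learning tools for
HLA I, CTL, HLA II and B-cell arms) are interfaces here, not
dependencies: an arm predictor is any deterministic function from a
9-mer to a call. The built-in engine is an additive position-specific
scoring matrix (sum over nine positions of per-residue weights, the
log-transformed quantitative-matrix convention) with an *absolute*
per-allele threshold stored in the matrix file. Absolute thresholds are
deterministic and fixture-friendly; a percentile helper
(`percentileThreshold`) serves users who prefer "top x% of a reference
peptide set" semantics. Promiscuity is the count of alleles bound;
`min_alleles` defaults to 1 for "binder" and is configurable because no
fixed definition of "a large number of alleles" exists.

Aggregation is per peptide across configured arms: positive anywhere →
neoepitope; positive everywhere → promiscuous epitope. A predictor
failure on a peptide is recorded per peptide and treated as a negative
call; the run continues. Validated-epitope mapping reports every exact,
possibly overlapping occurrence of every query epitope by grouping
epitopes by length and matching all same-length antigen windows through
a hashed lookup — linear-ish in antigen length per distinct epitope
length, comfortably handling 10^4 epitopes against 10^4-residue
antigens.

## The synthetic-data generator

All tests run on generated data with known ground truth; nothing is
downloaded. The generator emulates the *structure* of the real inputs,
not their statistics: random sense-codon coding sequences (3 genes of
40–80 codons and 5 cell lines by default for unit tests; scale knobs for
larger smoke tests), a mutation class mix dominated by missense events
(60% missense, 20% frameshift split evenly between insertion and
deletion, 10% each in-frame class) mirroring the observed dominance of
missense calls in somatic profiles, decoy self proteomes of 20 random
proteins of 80–200 residues, a 5-allele matrix panel, and uniform
expression values on the log-scale range 2–15 observed in microarray
summaries. It does **not** emulate codon usage, mutation spectra,
proteome composition or HLA binding physics — so green tests demonstrate
algorithmic correctness (masks, window arithmetic, set membership,
thresholds, mode identities), not predictive validity on real genomes.

Ground truth comes from naive paths kept deliberately separate from
production code: translation via a different library, masks via the
vectorized codepoint trim re-derivation plus an alignment consistency
check, scores via an explicit double loop. Peptide planting into decoy
proteomes is verified by naive substring scan and retried until the
source contains *exactly* the recorded planted set — junction windows
around an inserted peptide can complete one of its overlapping sibling
windows by chance (about 1/20 per boundary), which is why construction
is scan-verified rather than assumed. Threshold calibration for the
matrix panel is done at generation time as a score quantile so a known
fraction of peptides pass; with fraction 0 the threshold sits above
every achievable score.

Generation is a pure function of (seed, spec); each generator operation
derives an independent RNG stream from the seed, so fixture files are
byte-identical across runs and machines.

## Numerical and procedural choices

* Rounding: half-up at a fixed decimal count (see above); no other
  floating-point comparisons are threshold-sensitive.
* Determinism: report bundles are byte-stable for fixed inputs — output
  rows are sorted, JSON log lines carry counters but no timestamps.
* Degenerate inputs: empty mutation tables produce header-only reports
  with a warning; unknown transcripts, reference mismatches and
  unparseable rows are logged with row context and skipped; sequences
  shorter than k contribute nothing to an index (counted); an antigen
  shorter than k is an error for the screen.
* Coordinates: all sequence coordinates in reports are 1-based and
  inclusive.
* The mutation dialect is deliberately minimal (six columns); full MAF
  files and genome-coordinate VCFs are adapter concerns — any annotator
  that emits cDNA-coordinate edits against a named transcript can feed
  the pipeline, and an explicit transcript id is required rather than
  guessed when transcript versions disagree.

## Problem sizes used in the shipped suites

Unit suites run on the 3-gene × 5-cell-line default fixture; the
mutant-builder oracle comparison uses 500 generated records over 6
genes; the membership oracle is probed with 10^4 random peptides; the
window-count identity is exhaustively enumerated for all protein lengths
up to 60. These sizes exercise every code path and property while
keeping the default test run fast.

## Known limitations

* Cohort-scale published counts (per-gene neopeptide tables, epitope
  tallies, promiscuous-epitope counts) depend on the original proteome,
  variant and expression databases and on external predictor tools;
  they are covered here by structural properties and planted-truth
  recovery at fixture scale, not by numeric reproduction.
* One record, one mutant: no haplotype phasing, no splice/UTR/promoter
  effects, no selenocysteine or non-standard codes.
* Exact self-matching does not model near-match tolerance or binding
  competition.
* The built-in matrix scorer is a testing-grade engine; for real
  predictions, wrap the external tools of your choice in the predictor
  interface.
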
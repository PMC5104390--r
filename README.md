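# cancertope

Discovery and prioritization of cancer neoepitopes from somatic mutation
profiles.

Tumor genomes carry protein-altering somatic mutations whose products —
neoantigens — are absent from healthy tissue and can direct the immune
system specifically against cancer cells. `cancertope` implements the
full computational path from mutation records to vaccine-ready peptide
candidates:

1. **Mutant building** — somatic mutation records (missense, frameshift,
   in-frame insertion/deletion) in cDNA coordinates are applied to
   reference coding sequences and re-translated; a per-residue *altered
   mask* records which residues of the mutant protein differ from wild
   type.
2. **Neopeptide extraction** — all overlapping 9-mers of each mutant
   protein are enumerated (both HLA class I and class II binders have a
   nine-residue binding core) and those covering at least one altered
   residue are kept as *neopeptides*, de-duplicated with provenance
   (samples, tissues) merged.
3. **Self filtering / cross-reactivity screening** — neopeptides are
   screened by exact 9-mer membership against an ordered cascade of
   "self" peptide spaces: the reference protein of the same antigen, the
   reference proteome, population variants of the antigen, and
   population-variant proteomes. A peptide is eliminated at the first
   stage that contains it; surviving counts per stage are reported per
   gene.
4. **Candidate-gene prioritization** — genes are ranked by the
   cancer-association statistic *f_D/f_P* (deleterious vs.
   polymorphism/neutral variant counts, selection rule
   f_D/f_P ≥ 2 and f_D ≥ 20), by cohort mutation frequency (mutated in
   ≥ 10% of cell lines), and profiled by expression binning (cell lines
   with expression ≥ 3, 7, 9, 12).
5. **Immune-arm classification** — a pluggable predictor layer calls
   each surviving peptide per immune arm (HLA I, CTL, HLA II, B cell); a
   built-in additive position-specific scoring-matrix engine handles
   allele panels and promiscuity counting. A peptide positive in at
   least one arm is a *neoepitope*; positive in every configured arm, a
   *promiscuous epitope*.

Three screening modes tie these together: **cohort** (database build
over a mutation table), **partially personalized** (tumor input vs. the
reference proteome) and **fully personalized** (tumor vs. the patient's
matched normal proteome, which becomes the first filter stage). A
synthetic-data generator produces every input type with known ground
truth, so the entire pipeline is testable without external downloads.

## Worked example

A toy KRAS-like transcript with the classic glycine-to-valine missense
at cDNA position 35:

```r
library(cancertope)

tx <- Transcript("KRAS", "NM_TEST",
                 "ATGACTGAATATAAACTTGTGGTAGTTGGAGCTGGTGGCGTAGGCAAGTAA")
muts <- tempfile(); writeLines(c(
  "gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
  "KRAS\tNM_TEST\tc.35G>T\tmissense\tCL1\tlung"), muts)
rec <- readMutationTable(muts)

mp <- buildMutant(tx, rec[1, ])
proteinSeq(tx)        # "MTEYKLVVVGAGGVGK"
mutantSeq(mp)         # "MTEYKLVVVGAVGVGK"
which(alteredMask(mp))  # 12

peps <- extractNeopeptides(mp)
peps$sequence
# "YKLVVVGAV" "KLVVVGAVG" "LVVVGAVGV" "VVVGAVGVG" "VVGAVGVGK"
```

The altered residue sits at protein position 12, so exactly the five
9-mer windows covering it are extracted (window starts 4–8). Screening
them against the wild-type protein confirms that all five are
tumor-specific:

```r
idx <- buildPeptideIndex(proteinSeq(tx), label = "reference_protein")
flt <- filterCascade(peps, list(idx))
sum(flt$survives)     # 5 of 5
```

The candidate-gene statistic reproduces published per-gene ratios from
their variant counts, e.g. TP53 with (f_D, f_P) = (1353, 7) and ATM with
(134, 52):

```r
associationRatio(1353, 7)   # 193.3
associationRatio(134, 52)   # 2.6
```

For a full run, generate a synthetic cohort and execute it:

```r
cfg <- writeFixtureBundle(fixtureSpec(seed = 1), "fixtures")
res <- runCohort(do.call(runConfig, cfg))
res$filter_counts   # per-gene surviving counts across the four stages
```

A thin command-line wrapper ships in `inst/scripts/cancertope`
(`cancertope cohort|partial|full|xreact|epimap|candidates|fixtures`).

## Package layout

- `R/` — implementation: IO (`readFasta`, `readMutationTable`,
  `readScoringMatrices`), mutant building (`applyEdit`, `translateCds`,
  `buildMutant`), extraction (`extractNeopeptides`,
  `dedupeNeopeptides`), filtering (`buildPeptideIndex`,
  `filterCascade`, `crossReactivityScreen`), prioritization
  (`associationRatio`, `selectCanProVar`, `selectByFrequency`,
  `expressionBins`), immune arms (`scorePeptide`,
  `promiscuousBinders`, `classifyArms`, `mapValidatedEpitopes`), modes
  (`runCohort`, `runPartial`, `runFull`) and the synthetic-data
  generator (`fixtureSpec`, `makeTranscripts`, `makeMutations`,
  `makeSelfProteome`, `makeMatricesAndExpression`,
  `writeFixtureBundle`).
- `vignettes/cancertope-methods.Rmd` — the model, its assumptions, the
  numerical choices and known limitations.
- `tests/testthat/` — unit, property and end-to-end suites with
  independent naive oracles.
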
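# Test-tree oracle helpers: naive, independent re-derivations of the
# quantities the production code computes.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# naive substring scan: is `pep` a substring of any sequence?
scanContains <- function(pep, seqs) {
  vapply(pep, function(p) any(grepl(p, seqs, fixed = TRUE)), logical(1),
         USE.NAMES = FALSE)
}

# brute-force k-mer enumeration of one sequence
bruteKmers <- function(s, k = 9L) {
  L <- nchar(s)
  if (L < k) return(character())
  vapply(seq_len(L - k + 1L), function(i) substr(s, i, i + k - 1L),
         character(1))
}

# one-row mutation record through the public parser
mkRecord <- function(change, mclass, gene = "G1", tx = "T1",
                     sample = "CL1", tissue = "lung") {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(c("gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
               paste(gene, tx, change, mclass, sample, tissue, sep = "\t")),
             f)
  readMutationTable(f)
}

# a MutantProtein built directly from a sequence and mask (for window tests)
mkMutant <- function(seq, mask, gene = "G1", sample = "CL1",
                     tissue = "lung") {
  rec <- data.frame(gene_id = gene, transcript_id = "T1",
                    cdna_change = "c.4A>C", position = 4L,
                    end = NA_integer_, ref_nt = "A", alt_nt = "C",
                    kind = "substitution", mclass = "missense",
                    sample = sample, tissue = tissue,
                    stringsAsFactors = FALSE)
  methods::new("MutantProtein", record = rec, sequence = seq,
               altered = mask, flags = character(), silent = FALSE)
}

randomPeptides <- function(n, k = 9L) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, k, replace = TRUE), collapse = ""), character(1))
}

# truth-derived neopeptide sequences per record (from generator truth, not
# the production extractor)
truthWindows <- function(truth, k = 9L) {
  if (truth$silent || !any(truth$mask)) return(character())
  L <- nchar(truth$protein)
  if (L < k) return(character())
  cums <- cumsum(c(0L, as.integer(truth$mask)))
  starts <- seq_len(L - k + 1L)
  keep <- (cums[starts + k] - cums[starts]) > 0L
  substring(truth$protein, starts[keep], starts[keep] + k - 1L)
}

# lazily built shared cohort fixture bundle (generated once per run)
.fixture_cache <- new.env(parent = emptyenv())
cohortFixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "cancertope-cohort-fixture")
    .fixture_cache$spec <- fixtureSpec(seed = 42L, n_genes = 3L,
                                       n_cell_lines = 5L, n_mutations = 30L)
    .fixture_cache$bundle <- writeFixtureBundle(.fixture_cache$spec, dir)
  }
  list(spec = .fixture_cache$spec, config = .fixture_cache$bundle)
}
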
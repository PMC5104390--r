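test_that("FASTA reading validates structure and round-trips", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_identical(readFasta(f, "dna"), c(a = "ACGT"))

  writeLines(c(">a desc here", "acg", "t", ">b", "GGCC"), f)
  got <- readFasta(f, "dna")
  expect_identical(got, c(a = "ACGT", b = "GGCC"))  # order, case, wrapping

  writeLines(c(">a", "ACGT", ">a", "GG"), f)
  expect_error(readFasta(f, "dna"), "duplicate")

  writeLines(c("ACGT", ">a", "GG"), f)
  expect_error(readFasta(f, "dna"), "line 1")

  writeLines(c(">a", "ACGU"), f)
  expect_error(readFasta(f, "dna"), "RNA")

  # protein stop-symbol handling
  writeLines(c(">p", "MAW*"), f)
  expect_warning(got <- readFasta(f, "protein"), "terminal stop")
  expect_identical(got, c(p = "MAW"))
  writeLines(c(">p", "MA*W"), f)
  expect_error(readFasta(f, "protein"), "internal stop")

  # write/read round-trip with wrapping
  seqs <- c(x = paste(rep("MAWTEYLKQ", 20), collapse = ""), y = "MK")
  out <- tempfile(fileext = ".fa")
  writeFasta(seqs, out, width = 17L)
  expect_identical(readFasta(out, "protein"), seqs)
})

test_that("mutation table parsing follows the cdna_change grammar", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
               "G1\tT1\tc.4G>T\tmissense\tCL1\tlung",
               "G1\tT1\tc.4_5insA\tframeshift_ins\tCL1\tlung",
               "G2\tT2\tc.6_8del\tinframe_del\tCL2\tbreast",
               "G2\tT2\tc.7del\tframeshift_del\tCL2\tbreast"), f)
  recs <- readMutationTable(f)
  expect_equal(nrow(recs), 4L)
  expect_equal(recs$position, c(4L, 4L, 6L, 7L))
  expect_equal(recs$kind,
               c("substitution", "insertion", "deletion", "deletion"))
  expect_equal(recs$ref_nt[1], "G")
  expect_equal(recs$alt_nt[1:2], c("T", "A"))
  expect_equal(recs$end[3:4], c(8L, 7L))

  # class contradicting the parsed edit is a row error, not a silent drop
  writeLines(c("gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
               "G1\tT1\tc.4G>T\tinframe_del\tCL1\tlung"), f)
  expect_error(readMutationTable(f), "contradicts")
  loose <- readMutationTable(f, strict = FALSE)
  expect_equal(nrow(loose), 0L)
  expect_equal(attr(loose, "row_errors")$row, 1L)

  # a 2-nt insertion cannot be in-frame
  writeLines(c("gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
               "G1\tT1\tc.4_5insAA\tinframe_ins\tCL1\tlung"), f)
  expect_error(readMutationTable(f), "contradicts")

  writeLines(c("gene\ttranscript\tcdna_change\tclass\tsample\ttissue",
               "G1\tT1\tc.whatever\tmissense\tCL1\tlung"), f)
  expect_error(readMutationTable(f), "unparseable")

  writeLines(c("gene\ttranscript\tcdna_change\tclass",
               "G1\tT1\tc.4G>T\tmissense"), f)
  expect_error(readMutationTable(f), "missing required column")
})

test_that("scoring-matrix dialect reader enforces the 9 x 20 block shape", {
  zero_block <- paste(rep("0", 20), collapse = "\t")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ALLELE A1 THRESHOLD 0", rep(zero_block, 9)), f)
  mats <- readScoringMatrices(f)
  expect_length(mats, 1L)
  expect_s4_class(mats[[1]], "ScoringMatrix")
  expect_equal(binderThreshold(mats[[1]]), 0)
  expect_true(all(mats[[1]]@weights == 0))

  writeLines(c("ALLELE A1 THRESHOLD 0", rep(zero_block, 8)), f)
  expect_error(readScoringMatrices(f), "missing weight rows")

  writeLines(c("ALLELE A1 THRESHOLD 0", rep(zero_block, 9),
               "ALLELE B1 THRESHOLD 1.5", rep(zero_block, 9)), f)
  expect_length(readScoringMatrices(f), 2L)

  bad <- c("ALLELE A1 THRESHOLD 0", rep(zero_block, 8),
           paste(c(rep("0", 19), "x"), collapse = "\t"))
  writeLines(bad, f)
  expect_error(readScoringMatrices(f), "non-numeric")

  # write/read round-trip
  m <- ScoringMatrix("HLA-T", matrix(seq(-1, 1, length.out = 180), 9, 20),
                     0.25)
  writeScoringMatrices(list(m), f)
  back <- readScoringMatrices(f)[[1]]
  expect_equal(back@weights, m@weights, tolerance = 1e-5)
  expect_equal(binderThreshold(back), 0.25)
})

test_that("report writing is deterministic and round-trippable", {
  df <- data.frame(gene_id = c("G2", "G1", "G3"), n = c(3L, 1L, 2L),
                   score = c(0.5, -1.25, 3), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeReport(df, f, "tsv")
  expect_length(readLines(f), 4L)  # header + 3 records
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back, df)

  writeReport(df[0, ], f, "tsv")
  expect_length(readLines(f), 1L)  # header-only for empty record sets

  j <- tempfile(fileext = ".json")
  writeReport(df, j, "json")
  parsed <- jsonlite::read_json(j)
  expect_length(parsed, 3L)
  expect_identical(names(parsed[[1]]), names(df))
})

test_that("Transcript validity catches inconsistent loads", {
  expect_error(Transcript("G", "T", "ATGGCTTGG"), "stop codon")
  expect_error(Transcript("G", "T", "ATGTAATGGTAA"), "internal stop")
  expect_error(Transcript("G", "T", "GTGGCTTGGTAA"), "ATG")
  expect_error(Transcript("G", "T", "ATGGCTTGGTAA", protein = "MAX"),
               "does not match")
  tx <- Transcript("G", "T", "ATGGCTTGGTAA")
  expect_identical(proteinSeq(tx), "MAW")
})
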
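test_that("applyEdit performs positional string edits with checks", {
  tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
  expect_identical(applyEdit(tx, mkRecord("c.4G>T", "missense")),
                   "ATGTCTTGGTAA")
  expect_identical(applyEdit(tx, mkRecord("c.4_5insA", "frameshift_ins")),
                   "ATGGACTTGGTAA")
  expect_identical(applyEdit(tx, mkRecord("c.4_6del", "inframe_del")),
                   "ATGTGGTAA")
  bad <- mkRecord("c.4C>T", "missense")
  expect_error(applyEdit(tx, bad), "expected C, found G")
  far <- mkRecord("c.99G>T", "missense")
  expect_error(applyEdit(tx, far), "out of range")
})

test_that("translateCds follows the standard code with stop/flag semantics", {
  expect_equal(translateCds("ATGGCTTGGTAA"),
               list(protein = "MAW", flags = character()))
  expect_equal(translateCds("ATGTAA"), list(protein = "M", flags = character()))
  expect_equal(translateCds("ATGGC"),
               list(protein = "M", flags = "no_stop_found"))
  expect_equal(translateCds("ATGTAATGG")$flags, "new_stop_gained")
  expect_equal(translateCds("GTGGCTTAA"),
               list(protein = "", flags = "start_lost"))
  expect_error(translateCds("ATGGNNTAA"), "non-ACGT")
})

test_that("buildMutant computes masks per mutation class", {
  tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
  mp <- buildMutant(tx, mkRecord("c.4G>T", "missense"))
  expect_identical(mutantSeq(mp), "MSW")
  expect_identical(alteredMask(mp), c(FALSE, TRUE, FALSE))
  expect_false(isSilent(mp))

  # synonymous substitution (GCT -> GCA, both Ala) is a silent marker
  silent <- buildMutant(tx, mkRecord("c.6T>A", "missense"))
  expect_true(isSilent(silent))
  expect_error(extractNeopeptides(silent), "silent")

  # in-frame insertion of one codon marks exactly the inserted residue
  tx2 <- Transcript("G2", "T2", "ATGGCTTGGAAATAA")
  ins <- buildMutant(tx2, mkRecord("c.6_7insCAG", "inframe_ins"))
  expect_identical(mutantSeq(ins), "MAQWK")
  expect_identical(which(alteredMask(ins)), 3L)

  # in-frame deletion of one codon: no unmatched mutant residue
  del <- buildMutant(tx2, mkRecord("c.7_9del", "inframe_del"))
  expect_identical(mutantSeq(del), "MAK")
  expect_false(any(alteredMask(del)))
  expect_false(isSilent(del))
})

test_that("frameshift masks run from the first affected codon to the end", {
  # 30-codon toy CDS: insertion after position 4 alters codon 2 onward
  set.seed(1)
  body <- paste(sample(c("GCT", "TGG", "AAA", "CTT", "GAT"), 28,
                       replace = TRUE), collapse = "")
  tx <- Transcript("G1", "T1", paste0("ATG", body, "TAA"))
  fs <- buildMutant(tx, mkRecord("c.4_5insA", "frameshift_ins"))
  mask <- alteredMask(fs)
  expect_true(all(mask[2:length(mask)]))
  expect_false(mask[1])
  expect_true("new_stop_gained" %in% translationFlags(fs) ||
                "no_stop_found" %in% translationFlags(fs))
})

test_that("generated mutants match the naive re-translation/alignment oracle", {
  spec <- fixtureSpec(seed = 5L, n_genes = 4L, n_mutations = 120L)
  txs <- makeTranscripts(spec)
  mm <- makeMutations(spec, txs)
  classes_seen <- character()
  for (i in seq_len(nrow(mm$records))) {
    rec <- mm$records[i, , drop = FALSE]
    truth <- mm$truth[[i]]
    mp <- buildMutant(txs[[rec$gene_id]], rec)
    expect_identical(mutantSeq(mp), truth$protein)
    expect_identical(isSilent(mp), truth$silent)
    expect_identical(alteredMask(mp), truth$mask)
    if (rec$mclass %in% c("inframe_ins", "inframe_del") && !truth$silent) {
      # a minimal-edit alignment never needs more changed residues than
      # the trimmed middle segment holds (placement may differ in repeats)
      amask <- naiveAlignMask(proteinSeq(txs[[rec$gene_id]]), truth$protein)
      expect_lte(sum(amask), sum(truth$mask))
    }
    classes_seen <- union(classes_seen, rec$mclass)
  }
  expect_setequal(classes_seen,
                  c("missense", "frameshift_ins", "frameshift_del",
                    "inframe_ins", "inframe_del"))
})

test_that("fixture missense mutants have single-residue masks and stable length", {
  spec <- fixtureSpec(seed = 9L, n_genes = 3L, n_mutations = 40L,
                      mutation_class_mix = c(missense = 1, frameshift = 0,
                                             inframe_ins = 0, inframe_del = 0))
  txs <- makeTranscripts(spec)
  mm <- makeMutations(spec, txs)
  expect_true(all(mm$records$kind == "substitution"))
  for (i in seq_len(nrow(mm$records))) {
    rec <- mm$records[i, , drop = FALSE]
    mp <- buildMutant(txs[[rec$gene_id]], rec)
    expect_identical(sum(alteredMask(mp)), 1L)
    expect_identical(nchar(mutantSeq(mp)),
                     nchar(proteinSeq(txs[[rec$gene_id]])))
  }
})

test_that("in-frame indels of 3k nt change protein length by k", {
  spec <- fixtureSpec(seed = 13L, n_genes = 3L, n_mutations = 40L,
                      mutation_class_mix = c(missense = 0, frameshift = 0,
                                             inframe_ins = 0.5,
                                             inframe_del = 0.5))
  txs <- makeTranscripts(spec)
  mm <- makeMutations(spec, txs)
  for (i in seq_len(nrow(mm$records))) {
    rec <- mm$records[i, , drop = FALSE]
    mp <- buildMutant(txs[[rec$gene_id]], rec)
    wt_len <- nchar(proteinSeq(txs[[rec$gene_id]]))
    k <- if (rec$kind == "insertion") nchar(rec$alt_nt) / 3L
         else -(rec$end - rec$position + 1L) / 3L
    expect_identical(nchar(mutantSeq(mp)), as.integer(wt_len + k))
  }
})

test_that("a null edit (ref equal to alt) cannot pass as a mutation", {
  tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
  rec <- mkRecord("c.4G>T", "missense")
  rec$alt_nt <- "G"  # force ref -> ref
  mp <- buildMutant(tx, rec)
  expect_true(isSilent(mp))
})
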
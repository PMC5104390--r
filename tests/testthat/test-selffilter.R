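test_that("index construction counts distinct k-mers with set semantics", {
  idx <- buildPeptideIndex(c(a = "ABCDEFGHIJ"), label = "demo")
  expect_equal(nKmers(idx), 2L)
  expect_true(all(containsPeptide(idx, c("ABCDEFGHI", "BCDEFGHIJ"))))
  expect_false(containsPeptide(idx, "XXXXXXXXX"))
  expect_error(containsPeptide(idx, "SHORT"), "length")

  two <- buildPeptideIndex(c(a = "ABCDEFGHIJ", b = "ABCDEFGHIJ"),
                           label = "dup")
  expect_equal(nKmers(two), nKmers(idx))

  expect_warning(short <- buildPeptideIndex(c(a = "TINY"), label = "s"),
                 "shorter than k")
  expect_equal(nKmers(short), 0L)
})

test_that("index membership equals brute-force substring enumeration", {
  set.seed(7)
  prots <- vapply(sample(20:80, 50, replace = TRUE), function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  idx <- buildPeptideIndex(prots, label = "oracle")
  brute <- unique(unlist(lapply(prots, bruteKmers)))
  expect_equal(nKmers(idx), length(brute))
  probes <- c(sample(brute, 100), randomPeptides(200))
  expect_identical(containsPeptide(idx, probes),
                   scanContains(probes, prots))
})

test_that("cascade eliminates at the first containing stage with monotone flags", {
  set.seed(11)
  peps <- data.frame(sequence = randomPeptides(100), gene_id = "G1",
                     stringsAsFactors = FALSE)
  # plant 10 peptides in a stage-2-only proteome
  planted <- peps$sequence[1:10]
  stage1 <- buildPeptideIndex("NOTHINGRELEVANTHERE", label = "ref_protein")
  carrier <- paste0(paste(planted, collapse = ""), "AAAA")
  stage2 <- buildPeptideIndex(carrier, label = "ref_proteome")
  filtered <- filterCascade(peps, list(stage1, stage2))

  expect_true(all(!filtered$survives_ref_proteome[1:10]))
  expect_true(all(filtered$survives_ref_protein[1:10]))
  # junction k-mers of the carrier may catch a few extra random peptides;
  # the oracle is the naive scan
  expect_identical(filtered$survives, !scanContains(peps$sequence, carrier))
  expect_equal(filtered$eliminated_at[1:10], rep("ref_proteome", 10))

  # monotone: no peptide survives a later stage after elimination
  expect_true(all(filtered$survives_ref_proteome <= filtered$survives_ref_protein))
  sc <- attr(filtered, "stage_counts")
  expect_true(all(diff(sc$surviving) <= 0))

  # peptide present in stage 1 only: flags (F, F) and eliminated_at stage 1
  inref <- data.frame(sequence = "NOTHINGRE", gene_id = "G1",
                      stringsAsFactors = FALSE)
  f2 <- filterCascade(inref, list(stage1, stage2))
  expect_false(f2$survives_ref_protein)
  expect_false(f2$survives_ref_proteome)
  expect_identical(f2$eliminated_at, "ref_protein")

  expect_error(filterCascade(peps, list()), "no filter stages")
  k8 <- buildPeptideIndex("ABCDEFGHIJ", k = 8L, label = "k8")
  expect_error(filterCascade(peps, list(stage1, k8)), "k")
})

test_that("cascade output is independent of index build order", {
  set.seed(19)
  prots <- vapply(1:10, function(i)
    paste(sample(AA20, 60, replace = TRUE), collapse = ""), character(1))
  peps <- data.frame(sequence = c(bruteKmers(prots[1])[1:5],
                                  randomPeptides(20)),
                     gene_id = "G1", stringsAsFactors = FALSE)
  idx_fwd <- buildPeptideIndex(prots, label = "s")
  idx_rev <- buildPeptideIndex(rev(prots), label = "s")
  f1 <- filterCascade(peps, list(idx_fwd))
  f2 <- filterCascade(peps, list(idx_rev))
  expect_identical(f1, f2)
})

test_that("cross-reactivity screen labels windows like the cascade", {
  set.seed(23)
  self_prot <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  idx <- buildPeptideIndex(self_prot, label = "ref_protein")

  # an antigen identical to an indexed protein is self everywhere
  scr <- crossReactivityScreen(self_prot, list(idx))
  expect_true(all(!scr$survives))
  expect_true(all(scr$eliminated_at == "ref_protein"))

  # a novel antigen against a small decoy proteome is non-self everywhere
  novel <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  decoys <- vapply(1:5, function(i)
    paste(sample(AA20, 100, replace = TRUE), collapse = ""), character(1))
  scr2 <- crossReactivityScreen(novel, list(buildPeptideIndex(decoys,
                                                              label = "d")))
  expect_identical(scr2$survives,
                   !scanContains(scr2$sequence, decoys))
  expect_true(all(scr2$survives))

  # single-residue variant: exactly the windows covering the variant are
  # non-self
  pos <- 17L
  variant <- self_prot
  old <- substr(variant, pos, pos)
  substr(variant, pos, pos) <- setdiff(AA20, old)[1]
  scr3 <- crossReactivityScreen(variant, list(idx))
  expected_nonself <- scr3$window_start >= pos - 8L &
    scr3$window_start <= pos
  expect_identical(scr3$survives, expected_nonself)
})

test_that("a proteome filtered against itself is eliminated entirely", {
  set.seed(29)
  prots <- vapply(1:5, function(i)
    paste(sample(AA20, 50, replace = TRUE), collapse = ""), character(1))
  idx <- buildPeptideIndex(prots, label = "self")
  for (p in prots) {
    scr <- crossReactivityScreen(p, list(idx))
    expect_true(all(!scr$survives))
  }
})
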
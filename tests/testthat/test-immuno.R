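zeroMatrix <- function(allele = "A1", threshold = 0)
  ScoringMatrix(allele, matrix(0, 9, 20), threshold)

test_that("peptide scoring is additive over positions", {
  pep <- "ACDEFGHIK"
  expect_equal(scorePeptide(pep, zeroMatrix()), 0)

  # identity construction: weight 1 exactly at the peptide's cells
  w <- matrix(0, 9, 20, dimnames = list(NULL, AA20))
  for (i in 1:9) w[i, substr(pep, i, i)] <- 1
  expect_equal(scorePeptide(pep, ScoringMatrix("I", w, 0)), 9)

  # brute-force double-loop oracle on random peptide/matrix pairs
  set.seed(3)
  for (rep in 1:20) {
    p <- randomPeptides(1)
    m <- ScoringMatrix("R", matrix(runif(180, -3, 3), 9, 20), 0)
    expect_equal(scorePeptide(p, m), naiveScorePeptide(p, m))
  }

  expect_error(scorePeptide("ACDEFGHIX", zeroMatrix()), "unknown residue")
  expect_error(scorePeptide("SHORT", zeroMatrix()), "length")
})

test_that("scoring is covariant under joint residue-column permutation", {
  set.seed(5)
  w <- matrix(runif(180), 9, 20, dimnames = list(NULL, AA20))
  pep <- "ACDEFGHIK"
  perm <- sample(20)
  # rename residues by a permutation of the alphabet, permuting columns too
  relabel <- setNames(AA20[perm], AA20)
  w2 <- w; colnames(w2) <- unname(relabel[colnames(w)])
  w2 <- w2[, AA20]
  pep2 <- paste(relabel[strsplit(pep, "")[[1]]], collapse = "")
  expect_equal(scorePeptide(pep2, ScoringMatrix("P", w2, 0)),
               scorePeptide(pep, ScoringMatrix("P", w, 0)))
})

test_that("promiscuity calls count alleles at or above threshold", {
  pep <- "ACDEFGHIK"
  unreachable <- ScoringMatrix("U", matrix(0, 9, 20), 1e6)
  call <- promiscuousBinders(pep, list(unreachable, unreachable), 1L)
  expect_false(call$positive)
  expect_equal(call$n_alleles_bound, 0L)

  allzero <- replicate(3, zeroMatrix(), simplify = FALSE)
  call2 <- promiscuousBinders(pep, allzero, 1L)
  expect_true(call2$positive)          # score 0 >= threshold 0
  expect_equal(call2$n_alleles_bound, 3L)

  # 5 matrices, exactly 2 constructed to pass
  pass <- zeroMatrix("P")
  fail <- ScoringMatrix("F", matrix(0, 9, 20), 5)
  call3 <- promiscuousBinders(pep, list(fail, pass, fail, pass, fail), 2L)
  expect_equal(call3$n_alleles_bound, 2L)
  expect_true(call3$positive)
  expect_false(promiscuousBinders(pep, list(fail, pass, fail, pass, fail),
                                  3L)$positive)

  expect_error(promiscuousBinders(pep, list()), "empty matrix list")
})

test_that("bound-allele counts are non-increasing as thresholds rise", {
  set.seed(9)
  pep <- randomPeptides(1)
  mats <- lapply(1:4, function(i)
    ScoringMatrix(paste0("A", i), matrix(runif(180, -2, 2), 9, 20), 0))
  counts <- vapply(c(-10, 0, 2, 10), function(thr) {
    shifted <- lapply(mats, function(m)
      ScoringMatrix(m@allele, m@weights, thr))
    promiscuousBinders(pep, shifted, 1L)$n_alleles_bound
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("arm aggregation computes neoepitope and promiscuity flags", {
  peps <- randomPeptides(5)
  yes <- propertyPredictor(function(p) TRUE, "ctl", "stub_yes")
  no <- propertyPredictor(function(p) FALSE, "bcell", "stub_no")

  all_pos <- classifyArms(peps, list(ctl = yes, hla1 = yes))
  expect_true(all(all_pos$is_neoepitope))
  expect_true(all(all_pos$is_promiscuous))

  mixed <- classifyArms(peps, list(ctl = yes, bcell = no))
  expect_true(all(mixed$is_neoepitope))
  expect_false(any(mixed$is_promiscuous))

  none <- classifyArms(peps, list(bcell = no))
  expect_false(any(none$is_neoepitope))
  expect_false(any(none$is_promiscuous))

  expect_error(classifyArms(peps, list()), "configuration error")

  # deterministic: identical inputs give identical profiles
  expect_identical(classifyArms(peps, list(ctl = yes, bcell = no)), mixed)
})

test_that("a predictor failure is recorded and the run continues", {
  peps <- c("ACDEFGHIK", "CCDEFGHIK", "DCDEFGHIK")
  flaky <- function(p) {
    if (substr(p, 1, 1) == "C") stop("boom")
    list(positive = TRUE, n_alleles_bound = 1L)
  }
  got <- classifyArms(peps, list(ctl = flaky))
  errs <- attr(got, "errors")
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$peptide, "CCDEFGHIK")
  expect_identical(got$is_neoepitope, c(TRUE, FALSE, TRUE))
})

test_that("epitope mapping reports all exact occurrences incl. overlaps", {
  expect_equal(mapValidatedEpitopes("MAWTE", c(e = "MAWTE")),
               data.frame(id = "e", start = 1L, end = 5L))
  hits <- mapValidatedEpitopes("AAA", c(e1 = "AA"))
  expect_equal(hits$start, c(1L, 2L))
  expect_equal(hits$end, c(2L, 3L))

  # planted construction: epitopes of mixed lengths at recorded offsets
  set.seed(13)
  antigen <- paste(sample(AA20, 600, replace = TRUE), collapse = "")
  starts <- sample(1:580, 100, replace = TRUE)
  lens <- sample(6:15, 100, replace = TRUE)
  eps <- setNames(substring(antigen, starts, pmin(starts + lens - 1L, 600)),
                  sprintf("e%03d", 1:100))
  hits <- mapValidatedEpitopes(antigen, eps)
  # every planted occurrence is found at its planting position
  for (i in seq_along(eps)) {
    h <- hits[hits$id == names(eps)[i], ]
    expect_true(starts[i] %in% h$start)
  }
  # and every reported hit is a true exact occurrence (naive check)
  expect_true(all(substring(antigen, hits$start, hits$end) ==
                    unname(eps[hits$id])))
  # agrees with a naive nested scan for a few epitopes
  for (id in sample(names(eps), 5)) {
    pat <- eps[[id]]
    naive <- which(vapply(seq_len(600 - nchar(pat) + 1L), function(s)
      substr(antigen, s, s + nchar(pat) - 1L) == pat, logical(1)))
    expect_equal(hits$start[hits$id == id], naive)
  }
})

test_that("percentile thresholds call the intended top fraction", {
  set.seed(15)
  m <- ScoringMatrix("Q", matrix(runif(180, -2, 2), 9, 20), 0)
  ref <- randomPeptides(200)
  m2 <- percentileThreshold(m, ref, top_frac = 0.1)
  scores <- vapply(ref, scorePeptide, numeric(1), matrix = m2)
  expect_true(abs(sum(scores >= binderThreshold(m2)) - 20L) <= 2L)
})
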
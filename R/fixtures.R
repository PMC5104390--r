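SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
TISSUE_POOL <- c("lung", "breast", "large_intestine", "skin", "haematopoietic")

#' Specification for the synthetic-data generator
#'
#' Collects the knobs of the fixture generator: cohort shape, coding
#' sequence lengths, the mutation class mix (mirroring the dominance of
#' missense events in somatic profiles, with frameshifts split evenly
#' between insertions and deletions), decoy-proteome size, the fraction of
#' neopeptides deliberately planted into a self source, and the allele
#' panel. Generation is a pure function of (seed, spec): identical inputs
#' give identical fixtures.
#'
#' @param seed Integer seed; every generator op derives its RNG state from
#'   it.
#' @param n_genes Number of genes/transcripts.
#' @param cds_length_range Min/max CDS length in codons (incl. start and
#'   stop).
#' @param n_cell_lines Number of cell lines in the cohort.
#' @param n_mutations Number of mutation records to generate.
#' @param mutation_class_mix Named probabilities over
#'   \code{c("missense", "frameshift", "inframe_ins", "inframe_del")};
#'   must sum to 1.
#' @param n_self_proteins Decoy proteins per self source.
#' @param self_protein_length Min/max decoy protein length (residues).
#' @param planted_self_fraction Fraction of neopeptides embedded verbatim
#'   into a self source (in [0, 1]).
#' @param n_alleles Number of scoring matrices in the allele panel.
#' @param planted_binder_fraction Approximate fraction of peptides that
#'   score at or above each allele's threshold (thresholds are calibrated
#'   as score quantiles at generation time; 0 means no peptide passes).
#' @return A list of class \code{"fixture_spec"}.
#' @export
fixtureSpec <- function(seed = 1L, n_genes = 3L, cds_length_range = c(40L, 80L),
                        n_cell_lines = 5L, n_mutations = 30L,
                        mutation_class_mix = c(missense = 0.6, frameshift = 0.2,
                                               inframe_ins = 0.1,
                                               inframe_del = 0.1),
                        n_self_proteins = 20L,
                        self_protein_length = c(80L, 200L),
                        planted_self_fraction = 0.1, n_alleles = 5L,
                        planted_binder_fraction = 0.3) {
  stopifnot(abs(sum(mutation_class_mix) - 1) < 1e-9,
            all(names(mutation_class_mix) %in%
                  c("missense", "frameshift", "inframe_ins", "inframe_del")),
            planted_self_fraction >= 0, planted_self_fraction <= 1,
            planted_binder_fraction >= 0, planted_binder_fraction <= 1,
            cds_length_range[1] >= 12L,
            cds_length_range[2] >= cds_length_range[1])
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 cds_length_range = as.integer(cds_length_range),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_mutations = as.integer(n_mutations),
                 mutation_class_mix = mutation_class_mix,
                 n_self_proteins = as.integer(n_self_proteins),
                 self_protein_length = as.integer(self_protein_length),
                 planted_self_fraction = planted_self_fraction,
                 n_alleles = as.integer(n_alleles),
                 planted_binder_fraction = planted_binder_fraction),
            class = "fixture_spec")
}

#' Generate reference transcripts
#'
#' Random coding sequences: ATG start, sense codons inside, one stop codon
#' at the end, lengths drawn from \code{cds_length_range}. Every result
#' satisfies the \linkS4class{Transcript} validity contract.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @return List of \linkS4class{Transcript} named by gene id.
#' @export
makeTranscripts <- function(spec) {
  withr::with_seed(spec$seed + 101L, {
    out <- lapply(seq_len(spec$n_genes), function(i) {
      n_codons <- sample(spec$cds_length_range[1]:spec$cds_length_range[2], 1L)
      body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
      cdna <- paste0("ATG", paste(body, collapse = ""),
                     sample(STOP_CODONS, 1L))
      Transcript(paste0("G", i), paste0("T", i), cdna)
    })
    names(out) <- vapply(out, geneId, character(1))
    out
  })
}

# ---- independent naive oracle paths -------------------------------------
# These re-derive translation, masks and scores through routes disjoint
# from the production code (seqinr translation, pairwise alignment,
# double-loop scoring) and exist so generated fixtures carry ground truth.

#' Naive oracle: translate a CDS via seqinr
#'
#' Independent re-translation used for fixture ground truth: codon
#' translation is delegated to \code{seqinr::translate}, then cut at the
#' first stop, with the same flag semantics as \code{\link{translateCds}}.
#'
#' @param cdna Nucleotide string.
#' @return List with \code{protein} and \code{flags}.
#' @export
naiveTranslate <- function(cdna) {
  if (substr(cdna, 1, 3) != "ATG")
    return(list(protein = "", flags = "start_lost"))
  aa <- seqinr::translate(seqinr::s2c(cdna))
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    first <- stop_at[1]
    flags <- if (first < length(aa) || nchar(cdna) %% 3L != 0L)
      "new_stop_gained" else character()
    list(protein = paste(aa[seq_len(first - 1L)], collapse = ""),
         flags = flags)
  } else {
    list(protein = paste(aa, collapse = ""), flags = "no_stop_found")
  }
}

#' Naive oracle: altered mask by terminal-trim re-derivation
#'
#' Independent (vectorized, codepoint-based) re-derivation of the
#' altered-residue definition for in-frame events: compare wild type and
#' mutant position by position from the N-terminus and from the C-terminus
#' inward; the unmatched middle segment of the mutant is altered. This is
#' the ground-truth mask attached to generated mutation records.
#'
#' @param wt,mut Wild-type and mutant protein strings.
#' @return Logical mask along \code{mut}.
#' @export
naiveTrimMask <- function(wt, mut) {
  mutc <- utf8ToInt(mut)
  wtc <- utf8ToInt(wt)
  lm <- length(mutc); lw <- length(wtc); lmin <- min(lm, lw)
  if (lm == 0L) return(logical())
  if (lmin == 0L) return(rep(TRUE, lm))
  p <- sum(cumprod(wtc[seq_len(lmin)] == mutc[seq_len(lmin)]))
  s <- sum(cumprod(rev(wtc)[seq_len(lmin)] == rev(mutc)[seq_len(lmin)]))
  s <- min(s, lmin - p)
  mask <- rep(FALSE, lm)
  if (lm - s >= p + 1L) mask[(p + 1L):(lm - s)] <- TRUE
  mask
}

#' Naive oracle: altered mask via global pairwise alignment
#'
#' A global edit-distance-style alignment
#' (\code{Biostrings::pairwiseAlignment}, unit match/mismatch/gap scores)
#' of mutant against wild type; mutant positions that are inserted (gap in
#' wild type) or aligned with a mismatch are altered. Optimal gap
#' placement is ambiguous inside repeats, so alignment masks are a
#' consistency check against the definitional terminal-trim mask (altered
#' positions contained in the trimmed middle segment, never more of them),
#' not an exact-equality oracle.
#'
#' @param wt,mut Wild-type and mutant protein strings.
#' @return Logical mask along \code{mut}.
#' @export
naiveAlignMask <- function(wt, mut) {
  if (!nchar(mut)) return(logical())
  if (!nchar(wt)) return(rep(TRUE, nchar(mut)))
  sub_mat <- matrix(-1, 26, 26,
                    dimnames = list(LETTERS, LETTERS))
  diag(sub_mat) <- 1
  al <- Biostrings::pairwiseAlignment(pattern = mut, subject = wt,
                                      type = "global",
                                      substitutionMatrix = sub_mat,
                                      gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  mask <- logical(nchar(mut))
  mi <- 0L
  for (col in seq_along(p)) {
    if (p[col] == "-") next
    mi <- mi + 1L
    mask[mi] <- (s[col] == "-") || (p[col] != s[col])
  }
  mask
}

#' Naive oracle: double-loop matrix score
#'
#' @param peptide A 9-mer.
#' @param matrix A \linkS4class{ScoringMatrix}.
#' @return Numeric score, computed position by position with explicit
#'   column search (independent of the vectorized production scorer).
#' @export
naiveScorePeptide <- function(peptide, matrix) {
  res <- strsplit(peptide, "")[[1]]
  total <- 0
  for (i in seq_along(res)) {
    j <- which(colnames(matrix@weights) == res[i])
    if (!length(j)) stop("unknown residue ", res[i])
    total <- total + matrix@weights[i, j]
  }
  unname(total)
}

# Apply an edit by character-vector splicing (independent of applyEdit's
# substring concatenation).
naiveApplyEdit <- function(cdna, record) {
  v <- strsplit(cdna, "")[[1]]
  switch(record$kind,
    substitution = { v[record$position] <- record$alt_nt; v },
    insertion = append(v, strsplit(record$alt_nt, "")[[1]],
                       after = record$position),
    deletion = v[-(record$position:record$end)]) |>
    paste(collapse = "")
}

#' Generate mutation records with independent ground truth
#'
#' Draws \code{n_mutations} records over the transcripts and cohort of
#' \code{spec}, class-balanced per \code{mutation_class_mix}
#' (missense events are resampled until non-synonymous; in-frame
#' insertions/deletions are resampled if they create a premature stop, so
#' in-frame fixtures stay length-variant only). Every record is valid
#' against its transcript and round-trips through the mutation-table
#' dialect. The returned truth is computed by the naive oracle paths
#' (\code{\link{naiveTranslate}}, \code{\link{naiveTrimMask}}), never by
#' the production mutant builder.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param transcripts List of \linkS4class{Transcript} from
#'   \code{\link{makeTranscripts}}.
#' @return List with \code{records} (mutation-record data.frame) and
#'   \code{truth} (per record: \code{protein}, \code{mask},
#'   \code{flags}, \code{silent}).
#' @export
makeMutations <- function(spec, transcripts) {
  mix <- spec$mutation_class_mix
  withr::with_seed(spec$seed + 202L, {
    cl <- paste0("CL", seq_len(spec$n_cell_lines))
    tissue_of <- stats::setNames(
      TISSUE_POOL[(seq_len(spec$n_cell_lines) - 1L) %% length(TISSUE_POOL) + 1L],
      cl)
    rows <- vector("list", spec$n_mutations)
    truth <- vector("list", spec$n_mutations)
    for (r in seq_len(spec$n_mutations)) {
      tx <- transcripts[[sample(length(transcripts), 1L)]]
      L <- nchar(cdnaSeq(tx))
      cls <- sample(names(mix), 1L, prob = mix)
      if (cls == "frameshift")
        cls <- sample(c("frameshift_ins", "frameshift_del"), 1L)
      rec <- NULL
      for (try in 1:50) {
        cand <- switch(cls,
          missense = {
            pos <- sample(4:(L - 3L), 1L)
            ref <- substr(cdnaSeq(tx), pos, pos)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
            list(cdna_change = sprintf("c.%d%s>%s", pos, ref, alt),
                 position = pos, end = NA_integer_, ref_nt = ref,
                 alt_nt = alt, kind = "substitution")
          },
          frameshift_ins = {
            pos <- sample(3:(L - 4L), 1L)
            ins <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1L),
                                replace = TRUE), collapse = "")
            list(cdna_change = sprintf("c.%d_%dins%s", pos, pos + 1L, ins),
                 position = pos, end = pos + 1L, ref_nt = NA_character_,
                 alt_nt = ins, kind = "insertion")
          },
          inframe_ins = {
            pos <- sample(3:(L - 4L), 1L)
            ins <- paste(sample(c("A", "C", "G", "T"), 3L * sample(1:2, 1L),
                                replace = TRUE), collapse = "")
            list(cdna_change = sprintf("c.%d_%dins%s", pos, pos + 1L, ins),
                 position = pos, end = pos + 1L, ref_nt = NA_character_,
                 alt_nt = ins, kind = "insertion")
          },
          frameshift_del = {
            len <- sample(1:2, 1L)
            pos <- sample(4:(L - 3L - len), 1L)
            list(cdna_change = if (len == 1L) sprintf("c.%ddel", pos)
                 else sprintf("c.%d_%ddel", pos, pos + len - 1L),
                 position = pos, end = pos + len - 1L,
                 ref_nt = NA_character_, alt_nt = NA_character_,
                 kind = "deletion")
          },
          inframe_del = {
            len <- 3L * sample(1:2, 1L)
            pos <- sample(4:(L - 3L - len), 1L)
            list(cdna_change = sprintf("c.%d_%ddel", pos, pos + len - 1L),
                 position = pos, end = pos + len - 1L,
                 ref_nt = NA_character_, alt_nt = NA_character_,
                 kind = "deletion")
          })
        cand_rec <- c(list(gene_id = geneId(tx),
                           transcript_id = transcriptId(tx)), cand,
                      list(mclass = cls))
        tr <- naiveTranslate(naiveApplyEdit(cdnaSeq(tx), cand_rec))
        ok <- switch(cls,
          missense = tr$protein != proteinSeq(tx) &&
            nchar(tr$protein) == nchar(proteinSeq(tx)),
          inframe_ins = , inframe_del =
            !("new_stop_gained" %in% tr$flags) && nzchar(tr$protein),
          TRUE)
        if (ok) { rec <- cand_rec; break }
      }
      if (is.null(rec)) stop("could not draw a valid ", cls, " record")
      sm <- sample(cl, 1L)
      rows[[r]] <- data.frame(
        gene_id = rec$gene_id, transcript_id = rec$transcript_id,
        cdna_change = rec$cdna_change, position = rec$position,
        end = rec$end, ref_nt = rec$ref_nt, alt_nt = rec$alt_nt,
        kind = rec$kind, mclass = rec$mclass, sample = sm,
        tissue = unname(tissue_of[sm]), stringsAsFactors = FALSE)
      tr <- naiveTranslate(naiveApplyEdit(cdnaSeq(tx), rec))
      wt <- proteinSeq(tx)
      silent <- identical(tr$protein, wt)
      mask <- if (silent || !nzchar(tr$protein)) {
        rep(FALSE, nchar(tr$protein))
      } else if (rec$mclass %in% c("frameshift_ins", "frameshift_del")) {
        first_nt <- if (rec$kind == "insertion") rec$position + 1L
                    else rec$position
        fc <- (first_nt - 1L) %/% 3L + 1L
        m <- rep(FALSE, nchar(tr$protein))
        if (fc <= length(m)) m[fc:length(m)] <- TRUE
        m
      } else {
        naiveTrimMask(wt, tr$protein)
      }
      truth[[r]] <- list(protein = tr$protein, mask = mask,
                         flags = tr$flags, silent = silent)
    }
    list(records = do.call(rbind, rows), truth = truth)
  })
}

randomProtein <- function(len) {
  paste(sample(AA_ALPHABET_20, len, replace = TRUE), collapse = "")
}

#' Generate a decoy self proteome with recorded peptide planting
#'
#' Builds \code{n_self_proteins} random-composition decoy proteins, then
#' embeds a recorded subset of the supplied neopeptides verbatim (exactly
#' \code{round(planted_fraction * length(neopeptides))} of them, inserted
#' at random positions). The construction is verified by a naive substring
#' scan: the set of neopeptides occurring anywhere in the source equals
#' the planting record exactly (decoys or junctions that collide with an
#' unplanted neopeptide are redrawn), so a filter stage built from this
#' source must eliminate precisely the planted peptides.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param neopeptides Character vector of 9-mers eligible for planting.
#' @param label Source label (also seeds the per-source RNG stream, so
#'   different stages get different decoys).
#' @param planted_fraction Fraction to plant (default
#'   \code{spec$planted_self_fraction}).
#' @return List with \code{sequences} (named character vector),
#'   \code{label}, and \code{planted} (the planting record).
#' @export
makeSelfProteome <- function(spec, neopeptides = character(), label = "self",
                             planted_fraction = spec$planted_self_fraction) {
  seed <- spec$seed + 303L +
    sum(utf8ToInt(label)) %% 1000L
  withr::with_seed(seed, {
    n_plant <- round(planted_fraction * length(neopeptides))
    planted <- if (n_plant > 0L) sample(neopeptides, n_plant) else character()
    other <- setdiff(neopeptides, planted)
    occursIn <- function(peps, seqs) {
      if (!length(peps)) return(logical())
      vapply(peps, function(p) any(grepl(p, seqs, fixed = TRUE)), logical(1))
    }
    for (attempt in 1:500) {
      lens <- sample(spec$self_protein_length[1]:spec$self_protein_length[2],
                     spec$n_self_proteins, replace = TRUE)
      seqs <- vapply(lens, randomProtein, character(1))
      if (length(planted)) {
        # all insertion points are chosen on the original decoy and applied
        # at once, so a later insertion can never split an earlier peptide
        at <- sample(spec$n_self_proteins, length(planted), replace = TRUE)
        for (d in unique(at)) {
          s <- seqs[d]
          mine <- planted[at == d]
          cuts <- sort(sample(0:nchar(s), length(mine), replace = TRUE))
          pieces <- substring(s, c(1L, cuts + 1L), c(cuts, nchar(s)))
          seqs[d] <- paste0(paste0(pieces[seq_along(mine)], mine,
                                   collapse = ""),
                            pieces[length(mine) + 1L])
        }
      }
      # junction windows around an inserted peptide can complete one of its
      # overlapping sibling windows by chance (~1/20 per boundary), so
      # collision-free decoys may need many redraws
      ok <- all(occursIn(planted, seqs)) && !any(occursIn(other, seqs))
      if (ok) break
      if (attempt == 500L) stop("could not build a collision-free proteome")
    }
    names(seqs) <- sprintf("%s_p%03d", label, seq_along(seqs))
    list(sequences = seqs, label = label, planted = sort(planted))
  })
}

#' Generate an allele panel and expression matrix with truth calls
#'
#' Scoring matrices get uniform random weights; each allele's threshold is
#' calibrated at generation time as the score quantile putting roughly
#' \code{planted_binder_fraction} of the supplied peptides at or above it
#' (0 yields a threshold above every achievable score). Truth binder calls
#' are recorded with the naive double-loop scorer, independently of the
#' production scorer. Expression values are drawn uniformly on the
#' log-scale range [2, 15] typical of microarray summaries.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param peptides Character vector of 9-mers used for threshold
#'   calibration and truth calls.
#' @return List with \code{matrices} (list of
#'   \linkS4class{ScoringMatrix}), \code{expression} (gene x cell-line
#'   matrix), and \code{truth_calls} (data.frame peptide, allele, score,
#'   bound).
#' @export
makeMatricesAndExpression <- function(spec, peptides) {
  if (spec$n_alleles < 1L) stop("n_alleles must be >= 1")
  withr::with_seed(spec$seed + 404L, {
    mats <- list()
    calls <- list()
    for (a in seq_len(spec$n_alleles)) {
      allele <- sprintf("HLA-X%02d", a)
      w <- matrix(stats::runif(180, -2, 2), 9, 20,
                  dimnames = list(NULL, AA_ALPHABET_20))
      m0 <- ScoringMatrix(allele, w, 0)
      scores <- vapply(peptides, function(p) naiveScorePeptide(p, m0),
                       numeric(1))
      thr <- if (spec$planted_binder_fraction == 0 || !length(peptides))
        (if (length(scores)) max(scores) else 0) + 1
      else stats::quantile(scores, 1 - spec$planted_binder_fraction,
                           names = FALSE)
      mats[[allele]] <- ScoringMatrix(allele, w, thr)
      if (length(peptides))
        calls[[allele]] <- data.frame(
          peptide = peptides, allele = allele, score = unname(scores),
          bound = unname(scores) >= thr, stringsAsFactors = FALSE)
    }
    expr <- matrix(round(stats::runif(spec$n_genes * spec$n_cell_lines,
                                      2, 15), 2),
                   nrow = spec$n_genes,
                   dimnames = list(paste0("G", seq_len(spec$n_genes)),
                                   paste0("CL", seq_len(spec$n_cell_lines))))
    list(matrices = mats, expression = expr,
         truth_calls = if (length(calls)) do.call(rbind, c(calls,
             list(make.row.names = FALSE)))
           else data.frame(peptide = character(), allele = character(),
                           score = numeric(), bound = logical()))
  })
}

#' Write a complete, immediately runnable fixture bundle
#'
#' Generates transcripts, mutations, the four-stage self-filter sources
#' (reference protein = the wild-type antigens themselves; reference
#' proteome = wild types plus decoys; population antigen variants =
#' singly-substituted wild types; population proteomes = decoys), an
#' allele panel, an expression matrix and a YAML run configuration, and
#' writes them all as plain-text files under \code{dir}.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the config list (paths filled in).
#' @export
writeFixtureBundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txs <- makeTranscripts(spec)
  mut <- makeMutations(spec, txs)

  cdna <- vapply(txs, cdnaSeq, character(1))
  names(cdna) <- vapply(txs, function(t)
    paste(geneId(t), transcriptId(t), sep = "|"), character(1))
  writeFasta(cdna, file.path(dir, "transcripts.fa"))
  writeMutationTable(mut$records, file.path(dir, "mutations.tsv"))

  # neopeptides for planting, via the truth masks (not the production path)
  peps <- character()
  for (r in seq_len(nrow(mut$records))) {
    t <- mut$truth[[r]]
    if (t$silent || !any(t$mask)) next
    cums <- cumsum(c(0L, as.integer(t$mask)))
    L <- nchar(t$protein)
    if (L < 9L) next
    starts <- seq_len(L - 8L)
    keep <- (cums[starts + 9L] - cums[starts]) > 0L
    peps <- c(peps, substring(t$protein, starts[keep], starts[keep] + 8L))
  }
  peps <- sort(unique(peps))

  wt <- vapply(txs, proteinSeq, character(1))
  names(wt) <- vapply(txs, function(t)
    paste(geneId(t), transcriptId(t), sep = "|"), character(1))
  writeFasta(wt, file.path(dir, "stage1_reference_protein.fa"))

  src2 <- makeSelfProteome(spec, peps, label = "reference_proteome")
  writeFasta(c(wt, src2$sequences), file.path(dir,
             "stage2_reference_proteome.fa"))
  remaining <- setdiff(peps, src2$planted)
  src3 <- makeSelfProteome(spec, remaining, label = "kgenomes_antigen_variants")
  writeFasta(src3$sequences, file.path(dir,
             "stage3_kgenomes_antigen_variants.fa"))
  remaining <- setdiff(remaining, src3$planted)
  src4 <- makeSelfProteome(spec, remaining, label = "kgenomes_proteomes")
  writeFasta(src4$sequences, file.path(dir, "stage4_kgenomes_proteomes.fa"))

  mx <- makeMatricesAndExpression(spec, peps)
  writeScoringMatrices(mx$matrices, file.path(dir, "matrices.tsv"))
  expr_df <- data.frame(gene = rownames(mx$expression), mx$expression,
                        stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg <- list(
    mode = "cohort", k = 9L,
    transcripts = file.path(dir, "transcripts.fa"),
    mutations = file.path(dir, "mutations.tsv"),
    self_stages = list(
      reference_protein = file.path(dir, "stage1_reference_protein.fa"),
      reference_proteome = file.path(dir, "stage2_reference_proteome.fa"),
      kgenomes_antigen_variants =
        file.path(dir, "stage3_kgenomes_antigen_variants.fa"),
      kgenomes_proteomes = file.path(dir, "stage4_kgenomes_proteomes.fa")),
    matrices = file.path(dir, "matrices.tsv"),
    expression = file.path(dir, "expression.tsv"),
    out_dir = file.path(dir, "reports"),
    min_ratio = 2, min_fD = 20L, freq = 0.10, min_alleles = 1L,
    seed = spec$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(cfg)
}
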
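#' Translate a coding sequence codon by codon
#'
#' Standard genetic code translation from position 1 of \code{cdna},
#' stopping at the first stop codon. Flags describe the anomalies a mutant
#' CDS can show: \code{start_lost} when the sequence does not begin with
#' ATG (an empty protein is returned), \code{new_stop_gained} when the
#' first stop codon is not the last complete codon of the input (a
#' premature stop, typical of frameshifts), and \code{no_stop_found} when
#' no stop codon occurs before the end (all complete codons are translated;
#' a trailing 1--2 nt remainder is ignored).
#'
#' @param cdna Nucleotide string (uppercase A/C/G/T), length >= 3.
#' @return List with elements \code{protein} (string, no stop symbol) and
#'   \code{flags} (character vector).
#' @examples
#' translateCds("ATGGCTTGGTAA")  # list(protein = "MAW", flags = character())
#' @export
translateCds <- function(cdna) {
  if (nchar(cdna) < 3L) stop("cdna shorter than one codon")
  if (grepl("[^ACGT]", cdna))
    stop("cdna contains non-ACGT characters")
  if (substr(cdna, 1L, 3L) != "ATG")
    return(list(protein = "", flags = "start_lost"))
  n_codon <- nchar(cdna) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cdna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")
  flags <- character()
  if (length(stop_at)) {
    first <- stop_at[1L]
    if (first < n_codon || nchar(cdna) %% 3L != 0L)
      flags <- "new_stop_gained"
    protein <- paste(aa[seq_len(first - 1L)], collapse = "")
  } else {
    flags <- "no_stop_found"
    protein <- paste(aa, collapse = "")
  }
  list(protein = protein, flags = flags)
}

#' Apply one cDNA edit to a reference transcript
#'
#' Substitutions replace one nucleotide (the record's \code{ref_nt} must
#' match the transcript at that position, otherwise a reference-mismatch
#' error reports expected vs found); insertions insert \code{alt_nt} after
#' \code{position}; deletions remove the inclusive range
#' \code{[position, end]}. Coordinates are 1-based on the coding sequence.
#'
#' @param transcript A \linkS4class{Transcript}.
#' @param record One-row mutation-record data.frame (see
#'   \code{\link{readMutationTable}}).
#' @return The mutated cDNA string.
#' @examples
#' tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
#' rec <- data.frame(gene_id = "G1", transcript_id = "T1",
#'                   cdna_change = "c.4G>T", position = 4L, end = NA,
#'                   ref_nt = "G", alt_nt = "T", kind = "substitution",
#'                   mclass = "missense", sample = "CL1", tissue = "lung")
#' applyEdit(tx, rec)  # "ATGTCTTGGTAA"
#' @export
applyEdit <- function(transcript, record) {
  cdna <- transcript@cdna
  L <- nchar(cdna)
  pos <- record$position[1]
  if (is.na(pos) || pos < 1L || pos > L)
    stop("edit position ", pos, " out of range for ", transcript@transcript_id,
         " (CDS length ", L, ")")
  switch(record$kind[1],
    substitution = {
      found <- substr(cdna, pos, pos)
      if (found != record$ref_nt[1])
        stop("reference mismatch at c.", pos, " of ",
             transcript@transcript_id, ": expected ", record$ref_nt[1],
             ", found ", found)
      paste0(substr(cdna, 1L, pos - 1L), record$alt_nt[1],
             substr(cdna, pos + 1L, L))
    },
    insertion = {
      paste0(substr(cdna, 1L, pos), record$alt_nt[1],
             substr(cdna, pos + 1L, L))
    },
    deletion = {
      end <- record$end[1]
      if (is.na(end) || end < pos || end > L)
        stop("deletion range c.", pos, "_", end, " out of range for ",
             transcript@transcript_id)
      paste0(substr(cdna, 1L, pos - 1L), substr(cdna, end + 1L, L))
    },
    stop("unknown edit kind: ", record$kind[1]))
}

# Longest common prefix / suffix trim of two character vectors, with the
# suffix capped so prefix + suffix never exceeds the shorter sequence.
# Returns the altered index range of the mutant (possibly empty).
trimAlteredRange <- function(wt, mut) {
  lw <- length(wt); lm <- length(mut); lmin <- min(lw, lm)
  p <- 0L
  while (p < lmin && wt[p + 1L] == mut[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < lmin - p && wt[lw - s] == mut[lm - s]) s <- s + 1L
  if (lm - s >= p + 1L) seq.int(p + 1L, lm - s) else integer()
}

#' Build a mutant protein from a transcript and a mutation record
#'
#' Applies the edit, re-translates, and computes the altered-residue mask.
#' For missense and in-frame events the mask is derived by trimming the
#' longest matching N-terminal and C-terminal runs against the wild-type
#' protein: the unmatched middle segment of the mutant (including inserted
#' residues) is marked altered. For frameshifts, every residue from the
#' first position whose codon overlaps the edit through the new C-terminus
#' is marked altered. An edit whose mutant protein equals the wild type is
#' returned with \code{isSilent(x) == TRUE} and must be excluded from
#' peptide extraction.
#'
#' A pure in-frame deletion leaves no unmatched mutant residue, and a
#' frameshift that immediately creates a stop codon truncates the protein
#' without introducing new residues; both yield an all-false mask (and, in
#' turn, no neopeptides).
#'
#' @param transcript A \linkS4class{Transcript}.
#' @param record One-row mutation-record data.frame.
#' @return A \linkS4class{MutantProtein}.
#' @examples
#' tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
#' rec <- data.frame(gene_id = "G1", transcript_id = "T1",
#'                   cdna_change = "c.4G>T", position = 4L, end = NA,
#'                   ref_nt = "G", alt_nt = "T", kind = "substitution",
#'                   mclass = "missense", sample = "CL1", tissue = "lung")
#' mp <- buildMutant(tx, rec)
#' mutantSeq(mp)      # "MSW"
#' alteredMask(mp)    # FALSE TRUE FALSE
#' @export
buildMutant <- function(transcript, record) {
  mut_cdna <- applyEdit(transcript, record)
  tr <- translateCds(mut_cdna)
  wt <- transcript@protein
  mut <- tr$protein
  # A premature stop is only "new" relative to the reference terminal stop:
  # a substitution that recreates the terminal stop at the same codon keeps
  # the flag from translateCds only if the stop moved.
  flags <- tr$flags
  silent <- identical(mut, wt)
  lm <- nchar(mut)
  frameshift <- record$mclass[1] %in% c("frameshift_ins", "frameshift_del")
  if (silent || lm == 0L) {
    mask <- rep(FALSE, lm)
  } else if (frameshift) {
    first_nt <- if (record$kind[1] == "insertion") record$position[1] + 1L
                else record$position[1]
    first_codon <- (first_nt - 1L) %/% 3L + 1L
    mask <- rep(FALSE, lm)
    if (first_codon <= lm) mask[first_codon:lm] <- TRUE
  } else {
    wtc <- strsplit(wt, "")[[1]]
    mutc <- strsplit(mut, "")[[1]]
    mask <- rep(FALSE, lm)
    mask[trimAlteredRange(wtc, mutc)] <- TRUE
  }
  new("MutantProtein", record = record[1, , drop = FALSE], sequence = mut,
      altered = mask, flags = flags, silent = silent)
}

#' FASTA header for a mutant protein
#'
#' Encodes provenance as \code{gene|transcript|sample|edit}, the header
#' convention of exported mutant proteomes.
#'
#' @param mutant A \linkS4class{MutantProtein}.
#' @return A single string.
#' @export
mutantHeader <- function(mutant) {
  r <- mutant@record
  paste(r$gene_id[1], r$transcript_id[1], r$sample[1], r$cdna_change[1],
        sep = "|")
}
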
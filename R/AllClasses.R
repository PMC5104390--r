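#' @import methods
#' @importFrom Biostrings DNAString AAString translate GENETIC_CODE
NULL

# 20-letter amino-acid alphabet used everywhere; column order of scoring
# matrices is fixed to this string.
AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

MUTATION_CLASSES <- c("missense", "frameshift_ins", "frameshift_del",
                      "inframe_ins", "inframe_del")
EDIT_KINDS <- c("substitution", "insertion", "deletion")
TRANSLATION_FLAGS <- c("new_stop_gained", "no_stop_found", "start_lost")

#' Transcript: a reference coding sequence and its protein
#'
#' Holds one gene's coding sequence (cDNA, from the A of the ATG through the
#' stop codon) together with the protein it encodes. Validity enforces the
#' contract the rest of the pipeline relies on: length a multiple of three,
#' ATG start, terminal stop codon, no internal stop, and translation
#' consistency between \code{cdna} and \code{protein}.
#'
#' @slot gene_id Gene symbol.
#' @slot transcript_id Transcript accession the cDNA coordinates refer to.
#' @slot cdna Coding nucleotide sequence (uppercase A/C/G/T).
#' @slot protein Encoded protein (20-letter alphabet, no stop symbol).
#'
#' @export
setClass("Transcript",
  representation(gene_id = "character", transcript_id = "character",
                 cdna = "character", protein = "character"))

setValidity("Transcript", function(object) {
  msg <- character()
  cdna <- object@cdna
  if (length(cdna) != 1L || !nzchar(cdna))
    return("cdna must be a single non-empty string")
  if (grepl("[^ACGT]", cdna))
    msg <- c(msg, "cdna contains non-ACGT characters")
  if (nchar(cdna) %% 3L != 0L)
    msg <- c(msg, "cdna length is not a multiple of 3")
  if (substr(cdna, 1L, 3L) != "ATG")
    msg <- c(msg, "cdna does not begin with ATG")
  if (length(msg) == 0L) {
    tr <- translateCds(cdna)
    if (!"new_stop_gained" %in% tr$flags && "no_stop_found" %in% tr$flags)
      msg <- c(msg, "cdna does not end with a stop codon")
    if (nchar(tr$protein) != nchar(cdna) / 3L - 1L)
      msg <- c(msg, "cdna contains an internal stop codon")
    if (tr$protein != object@protein)
      msg <- c(msg, sprintf("protein does not match translated cdna ('%s' vs '%s')",
                            object@protein, tr$protein))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Transcript
#'
#' @param gene_id Gene symbol.
#' @param transcript_id Transcript accession.
#' @param cdna Coding sequence (ATG..stop). Uppercased on input.
#' @param protein Optional protein sequence; derived from \code{cdna} when
#'   omitted, validated against it when given.
#' @return A \linkS4class{Transcript}.
#' @examples
#' tx <- Transcript("G1", "T1", "ATGGCTTGGTAA")
#' proteinSeq(tx)  # "MAW"
#' @export
Transcript <- function(gene_id, transcript_id, cdna, protein = NULL) {
  cdna <- toupper(gsub("\\s", "", cdna))
  if (is.null(protein)) protein <- translateCds(cdna)$protein
  new("Transcript", gene_id = as.character(gene_id),
      transcript_id = as.character(transcript_id),
      cdna = cdna, protein = toupper(protein))
}

#' @describeIn Transcript gene symbol
#' @param x,object A \code{Transcript}.
#' @export
geneId <- function(x) x@gene_id

#' @describeIn Transcript transcript accession
#' @export
transcriptId <- function(x) x@transcript_id

#' @describeIn Transcript coding sequence
#' @export
cdnaSeq <- function(x) x@cdna

#' @describeIn Transcript protein sequence
#' @export
proteinSeq <- function(x) x@protein

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript %s (%s): %d nt CDS -> %d aa\n",
              object@transcript_id, object@gene_id,
              nchar(object@cdna), nchar(object@protein)))
})

#' MutantProtein: a translated mutant sequence with altered-residue mask
#'
#' Result of applying one somatic mutation record to a reference transcript
#' and re-translating. The altered mask marks, per residue of the mutant
#' protein, whether it differs from the wild type (for in-frame events, the
#' unmatched middle segment after trimming matching N- and C-terminal runs;
#' for frameshifts, everything from the first codon overlapping the edit to
#' the new C-terminus). Protein-silent edits are flagged \code{silent} and
#' excluded from peptide extraction downstream.
#'
#' @slot record One-row data.frame: the mutation record that produced this
#'   mutant (columns as returned by \code{\link{readMutationTable}}).
#' @slot sequence Mutant protein sequence (no stop symbol).
#' @slot altered Logical vector, one element per residue of \code{sequence}.
#' @slot flags Character subset of
#'   \code{c("new_stop_gained", "no_stop_found", "start_lost")}.
#' @slot silent Single logical; \code{TRUE} when the mutant protein equals
#'   the wild type.
#' @export
setClass("MutantProtein",
  representation(record = "data.frame", sequence = "character",
                 altered = "logical", flags = "character",
                 silent = "logical"))

setValidity("MutantProtein", function(object) {
  msg <- character()
  if (length(object@altered) != nchar(object@sequence))
    msg <- c(msg, "altered mask length differs from sequence length")
  if (grepl("\\*", object@sequence))
    msg <- c(msg, "mutant sequence contains a stop symbol")
  if (!all(object@flags %in% TRANSLATION_FLAGS))
    msg <- c(msg, "unknown translation flag")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MutantProtein", function(object) {
  cat(sprintf("MutantProtein %s %s [%s]: %d aa, %d altered%s%s\n",
              object@record$gene_id[1], object@record$cdna_change[1],
              object@record$sample[1], nchar(object@sequence),
              sum(object@altered),
              if (object@silent) ", silent" else "",
              if (length(object@flags))
                paste0(", flags: ", paste(object@flags, collapse = ",")) else ""))
})

#' @describeIn MutantProtein mutant protein sequence
#' @param x A \code{MutantProtein}.
#' @export
mutantSeq <- function(x) x@sequence

#' @describeIn MutantProtein logical altered-residue mask
#' @export
alteredMask <- function(x) x@altered

#' @describeIn MutantProtein translation flags
#' @export
translationFlags <- function(x) x@flags

#' @describeIn MutantProtein is the edit protein-silent?
#' @export
isSilent <- function(x) x@silent

#' PeptideIndex: exact k-mer membership over a self proteome
#'
#' Stores the set of distinct length-\code{k} substrings of one or more
#' "self" protein sequences, supporting exact-membership queries. A peptide
#' is considered self when it occurs verbatim anywhere in the indexed
#' sequences. Built by streaming over sequences; memory scales with the
#' number of distinct k-mers.
#'
#' @slot k Window length (default 9 throughout the pipeline).
#' @slot label Source label, e.g. \code{"reference_proteome"}.
#' @slot kmers Sorted character vector of distinct k-mers.
#' @slot n_sequences Number of sequences indexed.
#' @slot n_short Number of sequences shorter than \code{k} (contribute no
#'   k-mers; counted as a warning statistic).
#' @export
setClass("PeptideIndex",
  representation(k = "integer", label = "character", kmers = "character",
                 n_sequences = "integer", n_short = "integer"))

setMethod("show", "PeptideIndex", function(object) {
  cat(sprintf("PeptideIndex '%s': %d distinct %d-mers from %d sequences\n",
              object@label, length(object@kmers), object@k,
              object@n_sequences))
})

#' @describeIn PeptideIndex window length
#' @param x A \code{PeptideIndex}.
#' @export
kmerSize <- function(x) x@k

#' @describeIn PeptideIndex source label
#' @export
indexLabel <- function(x) x@label

#' @describeIn PeptideIndex number of distinct k-mers
#' @export
nKmers <- function(x) length(x@kmers)

#' @describeIn PeptideIndex vectorized exact-membership query
#' @param peptides Character vector of peptides of length \code{kmerSize(x)}.
#' @export
containsPeptide <- function(x, peptides) {
  if (any(nchar(peptides) != x@k))
    stop("peptide length differs from index k = ", x@k)
  peptides %in% x@kmers
}

#' ScoringMatrix: position-specific scoring matrix for one HLA allele
#'
#' A 9 position x 20 residue additive weight matrix with an absolute binder
#' threshold: a peptide whose summed per-position weights reach the
#' threshold is called a binder for this allele (quantitative-matrix
#' convention, weights on a log scale).
#'
#' @slot allele Allele name.
#' @slot weights Numeric 9 x 20 matrix; columns named by the residues
#'   \code{ACDEFGHIKLMNPQRSTVWY}.
#' @slot threshold Score at or above which a peptide is a binder.
#' @export
setClass("ScoringMatrix",
  representation(allele = "character", weights = "matrix",
                 threshold = "numeric"))

setValidity("ScoringMatrix", function(object) {
  msg <- character()
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != 9L || ncol(w) != 20L)
    msg <- c(msg, "weights must be a numeric 9 x 20 matrix")
  else {
    if (!identical(colnames(w), AA_ALPHABET_20))
      msg <- c(msg, "weight columns must be named ACDEFGHIKLMNPQRSTVWY")
    if (any(!is.finite(w)))
      msg <- c(msg, "weights must all be finite")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoringMatrix
#'
#' @param allele Allele name.
#' @param weights Numeric 9 x 20 matrix (columns in residue order
#'   \code{ACDEFGHIKLMNPQRSTVWY}; names are set if missing).
#' @param threshold Absolute binder threshold.
#' @return A \linkS4class{ScoringMatrix}.
#' @export
ScoringMatrix <- function(allele, weights, threshold) {
  weights <- as.matrix(weights)
  if (is.null(colnames(weights)) && ncol(weights) == 20L)
    colnames(weights) <- AA_ALPHABET_20
  rownames(weights) <- NULL
  new("ScoringMatrix", allele = as.character(allele), weights = weights,
      threshold = as.numeric(threshold))
}

setMethod("show", "ScoringMatrix", function(object) {
  cat(sprintf("ScoringMatrix %s: 9 x 20 weights, threshold %g\n",
              object@allele, object@threshold))
})

#' @describeIn ScoringMatrix allele name
#' @param x A \code{ScoringMatrix}.
#' @export
alleleName <- function(x) x@allele

#' @describeIn ScoringMatrix binder threshold
#' @export
binderThreshold <- function(x) x@threshold
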
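#' Enumerate overlapping k-mer windows of a protein
#'
#' @param protein Amino-acid string.
#' @param k Window length (default 9, the shared binding-core length of
#'   HLA class I and class II).
#' @return data.frame with columns \code{start} (1-based residue index)
#'   and \code{peptide}; \code{max(0, L - k + 1)} rows in left-to-right
#'   order.
#' @examples
#' peptideWindows("MAWTEYLKQ")        # one window
#' nrow(peptideWindows(strrep("A", 20)))  # 12
#' @export
peptideWindows <- function(protein, k = 9L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  L <- nchar(protein)
  if (L < k)
    return(data.frame(start = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  starts <- seq_len(L - k + 1L)
  data.frame(start = starts,
             peptide = substring(protein, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Extract neopeptides from a mutant protein
#'
#' Returns the k-mer windows of the mutant protein that cover at least one
#' altered residue, with provenance (gene, sample, tissue) attached.
#' Windows containing an ambiguous residue \code{X} are dropped and
#' counted in \code{attr(, "n_dropped_x")}: both self-filtering and matrix
#' scoring are undefined for \code{X}. Silent mutants are rejected.
#'
#' @param mutant A \linkS4class{MutantProtein}.
#' @param k Window length (default 9).
#' @return data.frame with columns \code{sequence}, \code{gene_id},
#'   \code{window_start}, \code{samples}, \code{tissues}.
#' @export
extractNeopeptides <- function(mutant, k = 9L) {
  if (isSilent(mutant))
    stop("silent mutant: no altered residues to extract from")
  k <- as.integer(k)
  prot <- mutantSeq(mutant)
  mask <- alteredMask(mutant)
  L <- nchar(prot)
  empty <- data.frame(sequence = character(), gene_id = character(),
                      window_start = integer(), samples = character(),
                      tissues = character(), stringsAsFactors = FALSE)
  attr(empty, "n_dropped_x") <- 0L
  if (L < k || !any(mask)) return(empty)
  # window s covers residues s..s+k-1; keep windows with >= 1 altered
  cums <- cumsum(c(0L, as.integer(mask)))
  starts <- seq_len(L - k + 1L)
  covered <- (cums[starts + k] - cums[starts]) > 0L
  starts <- starts[covered]
  if (!length(starts)) return(empty)
  seqs <- substring(prot, starts, starts + k - 1L)
  has_x <- grepl("X", seqs, fixed = TRUE)
  if (all(has_x)) {
    attr(empty, "n_dropped_x") <- sum(has_x)
    return(empty)
  }
  rec <- mutant@record
  out <- data.frame(sequence = seqs[!has_x], gene_id = rec$gene_id[1],
                    window_start = starts[!has_x], samples = rec$sample[1],
                    tissues = rec$tissue[1], stringsAsFactors = FALSE)
  attr(out, "n_dropped_x") <- sum(has_x)
  out
}

#' De-duplicate neopeptides, merging provenance
#'
#' Collapses repeated sequences either within each antigen
#' (\code{scope = "antigen"}, the default, one row per (gene, sequence))
#' or across the whole cohort (\code{scope = "cohort"}, one row per
#' sequence). Sample and tissue sets are merged as sorted unions
#' (comma-separated), the smallest \code{window_start} is kept, and the
#' output is sorted lexicographically (gene then sequence in antigen
#' scope) so the operation is deterministic, idempotent and insensitive to
#' input order.
#'
#' @param peptides data.frame as from \code{\link{extractNeopeptides}}
#'   (rows from several mutants/samples may be concatenated).
#' @param scope \code{"antigen"} or \code{"cohort"}.
#' @return data.frame with columns \code{sequence}, \code{gene_id},
#'   \code{window_start}, \code{samples}, \code{tissues},
#'   \code{n_samples}.
#' @export
dedupeNeopeptides <- function(peptides, scope = c("antigen", "cohort")) {
  scope <- match.arg(scope)
  if (nrow(peptides) == 0L) {
    out <- peptides
    out$n_samples <- integer()
    return(out)
  }
  key <- if (scope == "antigen")
    paste(peptides$gene_id, peptides$sequence, sep = "\r")
  else peptides$sequence
  mergeSet <- function(x)
    paste(sort(unique(unlist(strsplit(x, ",", fixed = TRUE)))), collapse = ",")
  idx <- split(seq_len(nrow(peptides)), key)
  rows <- lapply(idx, function(i) {
    p <- peptides[i, , drop = FALSE]
    samples <- mergeSet(p$samples)
    data.frame(sequence = p$sequence[1],
               gene_id = if (scope == "antigen") p$gene_id[1]
                         else mergeSet(p$gene_id),
               window_start = min(p$window_start),
               samples = samples,
               tissues = mergeSet(p$tissues),
               n_samples = length(strsplit(samples, ",", fixed = TRUE)[[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- if (scope == "antigen") order(out$gene_id, out$sequence)
         else order(out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
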
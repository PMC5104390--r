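#' Build an exact k-mer membership index over a self proteome
#'
#' Streams over the sequences, accumulating the set of distinct length-k
#' substrings; peak memory scales with the number of distinct k-mers, not
#' the input size. Sequences shorter than \code{k} contribute nothing and
#' are counted in the \code{n_short} slot.
#'
#' @param sequences Named character vector (or list) of protein sequences,
#'   e.g. from \code{\link{readFasta}}.
#' @param k Window length (default 9).
#' @param label Source label recorded in the index (e.g.
#'   \code{"reference_proteome"}).
#' @return A \linkS4class{PeptideIndex}.
#' @examples
#' idx <- buildPeptideIndex(c(p1 = "ACDEFGHIKL"), label = "demo")
#' nKmers(idx)                       # 2
#' containsPeptide(idx, "CDEFGHIKL") # TRUE
#' @export
buildPeptideIndex <- function(sequences, k = 9L, label = "self") {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sequences <- as.character(sequences)
  env <- new.env(hash = TRUE, parent = emptyenv())
  n_short <- 0L
  for (s in sequences) {
    L <- nchar(s)
    if (L < k) { n_short <- n_short + 1L; next }
    starts <- seq_len(L - k + 1L)
    for (km in unique(substring(s, starts, starts + k - 1L)))
      assign(km, TRUE, envir = env)
  }
  if (n_short > 0L)
    warning(n_short, " sequence(s) shorter than k = ", k,
            " contribute no k-mers")
  new("PeptideIndex", k = k, label = as.character(label),
      kmers = sort(ls(env, sorted = FALSE)),
      n_sequences = length(sequences), n_short = n_short)
}

#' Screen neopeptides through an ordered cascade of self filters
#'
#' Applies the stages in the given order (canonically: reference protein,
#' reference proteome, population variants of the same antigen, population
#' proteomes). A peptide is eliminated at the first stage whose index
#' contains it; later stages are not consulted (so the survival flags are
#' monotone: once false, false thereafter). Survivors of stage i are the
#' input of stage i+1, and per-stage surviving counts are attached as
#' \code{attr(, "stage_counts")}.
#'
#' @param peptides data.frame with a \code{sequence} column (e.g. from
#'   \code{\link{dedupeNeopeptides}}).
#' @param stages List of \linkS4class{PeptideIndex}, in cascade order,
#'   all sharing the same k.
#' @return \code{peptides} with one logical \code{survives_<label>}
#'   column per stage, an \code{eliminated_at} column (stage label or
#'   \code{NA} for survivors), and a \code{survives} column (\code{TRUE}
#'   iff no stage contains the peptide).
#' @export
filterCascade <- function(peptides, stages) {
  if (!length(stages)) stop("configuration error: no filter stages given")
  ks <- vapply(stages, kmerSize, integer(1))
  if (length(unique(ks)) != 1L)
    stop("configuration error: stages disagree on k: ",
         paste(unique(ks), collapse = ", "))
  labels <- vapply(stages, indexLabel, character(1))
  if (anyDuplicated(labels))
    stop("configuration error: duplicate stage labels")
  n <- nrow(peptides)
  if (n > 0L && any(nchar(peptides$sequence) != ks[1]))
    stop("configuration error: peptide length differs from stage k = ", ks[1])
  out <- peptides
  alive <- rep(TRUE, n)
  eliminated_at <- rep(NA_character_, n)
  counts <- integer(length(stages))
  for (i in seq_along(stages)) {
    hit <- alive
    if (any(alive))
      hit[alive] <- containsPeptide(stages[[i]], peptides$sequence[alive])
    eliminated_at[alive & hit] <- labels[i]
    alive <- alive & !hit
    out[[paste0("survives_", labels[i])]] <- alive
    counts[i] <- sum(alive)
  }
  out$eliminated_at <- eliminated_at
  out$survives <- alive
  attr(out, "stage_counts") <- data.frame(
    stage = c("total", labels), surviving = c(n, counts),
    stringsAsFactors = FALSE)
  out
}

#' Per-gene surviving counts across the filter cascade
#'
#' Summarizes a \code{\link{filterCascade}} result per gene: the total
#' number of distinct 9-mers and the number surviving each stage, in
#' cascade order (counts are non-increasing left to right).
#'
#' @param filtered data.frame returned by \code{\link{filterCascade}}
#'   (must contain \code{gene_id}).
#' @return data.frame with columns \code{gene_id}, \code{total_kmer},
#'   then \code{after_<label>} per stage, sorted by descending total.
#' @export
stageCounts <- function(filtered) {
  surv_cols <- grep("^survives_", names(filtered), value = TRUE)
  genes <- sort(unique(filtered$gene_id))
  if (!length(genes)) {
    out <- data.frame(gene_id = character(), total_kmer = integer(),
                      stringsAsFactors = FALSE)
    for (cl in sub("^survives_", "after_", surv_cols)) out[[cl]] <- integer()
    return(out)
  }
  rows <- lapply(genes, function(g) {
    f <- filtered[filtered$gene_id == g, , drop = FALSE]
    counts <- vapply(surv_cols, function(cl) sum(f[[cl]]), integer(1))
    cbind(data.frame(gene_id = g, total_kmer = nrow(f),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            counts, sub("^survives_", "after_", surv_cols)))))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_kmer, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reactivity screen of a whole antigen
#'
#' Labels every k-mer window of an antigen self or non-self against each
#' filter stage, with the same short-circuit cascade semantics as
#' \code{\link{filterCascade}} (equivalent to enumerating all windows and
#' filtering them without any mutation masking). This is the standalone
#' screen for removing cross-reactive peptides from a user-supplied
#' antigen.
#'
#' @param antigen Amino-acid string, length >= k.
#' @param stages List of \linkS4class{PeptideIndex} in cascade order.
#' @param k Window length (default 9).
#' @param antigen_id Optional id recorded in the report.
#' @return Per-window data.frame: \code{gene_id}, \code{window_start},
#'   \code{sequence}, per-stage survival flags, \code{eliminated_at},
#'   \code{survives}.
#' @export
crossReactivityScreen <- function(antigen, stages, k = 9L,
                                  antigen_id = "antigen") {
  if (nchar(antigen) < k)
    stop("antigen shorter than k = ", k)
  win <- peptideWindows(antigen, k)
  peps <- data.frame(gene_id = antigen_id, window_start = win$start,
                     sequence = win$peptide, stringsAsFactors = FALSE)
  filterCascade(peps, stages)
}
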
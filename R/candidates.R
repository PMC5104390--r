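# Half-up decimal rounding. base::round() rounds half to even, which does
# not reproduce published ratio tables (e.g. 58/8 = 7.25 must print 7.3).
roundHalfUp <- function(x, decimals = 1L) {
  f <- 10^decimals
  ifelse(is.infinite(x), x, floor(x * f + 0.5) / f)
}

#' Cancer-association ratio f_D / f_P
#'
#' The per-gene ratio of deleterious (cancer-associated) variant count
#' \code{f_D} to polymorphism/neutral variant count \code{f_P}, rounded
#' half-up to \code{decimals} places. \code{f_P == 0} gives \code{Inf};
#' both counts zero is an undefined input and an error.
#'
#' @param f_D,f_P Non-negative integer vectors (recycled).
#' @param decimals Decimal places (default 1, matching published tables).
#' @return Numeric vector of ratios.
#' @examples
#' associationRatio(1353, 7)   # 193.3
#' associationRatio(134, 52)   # 2.6
#' associationRatio(5, 0)      # Inf
#' @export
associationRatio <- function(f_D, f_P, decimals = 1L) {
  if (any(f_D < 0) || any(f_P < 0)) stop("counts must be non-negative")
  both0 <- f_D == 0 & f_P == 0
  if (any(both0))
    stop("undefined input: f_D and f_P both zero")
  roundHalfUp(ifelse(f_P == 0, Inf, f_D / f_P), decimals)
}

#' Select vaccine-candidate genes by the variant-association rule
#'
#' Keeps genes with \code{ratio >= min_ratio} and \code{f_D >= min_fD}
#' (defaults 2 and 20, the published criterion for highly cancer-sensitive
#' proteins), ordered by descending ratio, ties broken by descending
#' \code{f_D} then gene id.
#'
#' @param stats data.frame with columns \code{gene_id}, \code{f_D},
#'   \code{f_P} (a \code{ratio} column is recomputed if absent).
#' @param min_ratio Minimum association ratio.
#' @param min_fD Minimum deleterious-variant count.
#' @return Character vector of selected gene ids.
#' @export
selectCanProVar <- function(stats, min_ratio = 2, min_fD = 20L) {
  ratio <- associationRatio(stats$f_D, stats$f_P)
  keep <- ratio >= min_ratio & stats$f_D >= min_fD
  sel <- stats[keep, , drop = FALSE]
  ratio <- ratio[keep]
  sel$gene_id[order(-ratio, -sel$f_D, sel$gene_id)]
}

#' Select genes mutated in at least a fraction of the cohort
#'
#' The threshold is \code{floor(frac * cohort_size)} distinct mutated
#' samples (10\% of a 905-cell-line cohort gives 90). A gene mutated
#' several times in the same sample counts that sample once.
#'
#' @param mutation_samples Named list: gene id -> character vector of
#'   sample ids carrying a mutation in that gene.
#' @param cohort_size Total number of samples in the cohort.
#' @param frac Required fraction (default 0.10).
#' @return Character vector of selected gene ids, by descending distinct
#'   sample count (ties by gene id); the threshold used is attached as
#'   \code{attr(, "threshold")}.
#' @export
selectByFrequency <- function(mutation_samples, cohort_size, frac = 0.10) {
  if (cohort_size < 1L) stop("cohort_size must be >= 1")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  threshold <- floor(frac * cohort_size)
  counts <- vapply(mutation_samples, function(s) length(unique(s)),
                   integer(1))
  keep <- counts >= threshold
  genes <- names(counts)[keep]
  out <- genes[order(-counts[keep], genes)]
  attr(out, "threshold") <- threshold
  out
}

#' Bin gene expression by cell-line counts above cutoffs
#'
#' For each gene and cutoff, counts the cell lines whose expression is at
#' or above the cutoff (default cutoffs 3, 7, 9, 12; values at or above 9
#' are conventionally called highly expressed). Genes requested but absent
#' from the matrix get an all-NA row.
#'
#' @param expr Numeric matrix, genes in rows (rownames), cell lines in
#'   columns.
#' @param genes Genes to report (default: all rows of \code{expr}).
#' @param cutoffs Strictly increasing numeric vector.
#' @return data.frame: \code{gene_id} plus one \code{ge_<cutoff>} count
#'   column per cutoff.
#' @examples
#' m <- matrix(c(2, 9, 12), 1, dimnames = list("G1", NULL))
#' expressionBins(m)  # counts 2, 2, 2, 1
#' @export
expressionBins <- function(expr, genes = rownames(expr),
                           cutoffs = c(3, 7, 9, 12)) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  counts <- matrix(NA_integer_, nrow = length(genes),
                   ncol = length(cutoffs),
                   dimnames = list(genes, paste0("ge_", cutoffs)))
  present <- genes %in% rownames(expr)
  for (j in seq_along(cutoffs))
    counts[present, j] <- as.integer(
      rowSums(expr[genes[present], , drop = FALSE] >= cutoffs[j],
              na.rm = TRUE))
  out <- data.frame(gene_id = genes, counts, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Merge the two candidate-selection rules with provenance
#'
#' Union of the association-rule and frequency-rule gene lists, recording
#' which rule(s) selected each gene.
#'
#' @param canprovar_genes Character vector from
#'   \code{\link{selectCanProVar}}.
#' @param frequency_genes Character vector from
#'   \code{\link{selectByFrequency}}.
#' @return data.frame with columns \code{gene_id} and \code{selected_by}
#'   (\code{"canprovar_rule"}, \code{"frequency_rule"} or both,
#'   comma-separated), in the order canprovar list then new frequency
#'   genes.
#' @export
mergeCandidates <- function(canprovar_genes, frequency_genes) {
  genes <- c(canprovar_genes, setdiff(frequency_genes, canprovar_genes))
  by <- vapply(genes, function(g) paste(
    c("canprovar_rule"[g %in% canprovar_genes],
      "frequency_rule"[g %in% frequency_genes]), collapse = ","),
    character(1))
  data.frame(gene_id = genes, selected_by = unname(by),
             stringsAsFactors = FALSE)
}

#' Bundled CanProVar-derived vaccine-target statistics
#'
#' The published per-gene deleterious (\code{f_D}) and neutral
#' (\code{f_P}) variant counts, association ratio and protein-family
#' annotation for the 34 cancer-sensitive vaccine targets, shipped with
#' the package.
#'
#' @return data.frame with columns \code{target}, \code{f_D}, \code{f_P},
#'   \code{ratio}, \code{family}.
#' @export
canProVarTargets <- function() {
  path <- system.file("extdata", "canprovar_vaccine_targets.tsv",
                      package = "cancertope", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
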
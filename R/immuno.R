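#' Score a peptide against a position-specific scoring matrix
#'
#' Additive scoring: the sum over positions 1..9 of the weight of the
#' residue observed at that position.
#'
#' @param peptide A 9-residue peptide (20-letter alphabet; ambiguous
#'   residues are an error and are dropped upstream).
#' @param matrix A \linkS4class{ScoringMatrix}.
#' @return A single numeric score.
#' @export
scorePeptide <- function(peptide, matrix) {
  res <- strsplit(peptide, "")[[1]]
  if (length(res) != nrow(matrix@weights))
    stop("peptide length ", length(res), " does not match matrix positions ",
         nrow(matrix@weights))
  idx <- match(res, colnames(matrix@weights))
  if (anyNA(idx))
    stop("unknown residue(s) in peptide: ",
         paste(res[is.na(idx)], collapse = ","))
  sum(matrix@weights[cbind(seq_along(res), idx)])
}

#' Call a peptide's HLA-binding promiscuity over an allele panel
#'
#' Scores the peptide against every matrix; an allele is bound when the
#' score reaches that allele's threshold. The call is positive when the
#' peptide binds at least \code{min_alleles} alleles (1 = any binder;
#' higher values demand promiscuous binding across the panel).
#'
#' @param peptide A 9-residue peptide.
#' @param matrices Non-empty list of \linkS4class{ScoringMatrix}.
#' @param min_alleles Minimum bound-allele count for a positive call.
#' @param arm Immune-arm label recorded in the call (default
#'   \code{"hla1"}).
#' @return An epitope call: list with \code{peptide}, \code{arm},
#'   \code{positive}, \code{n_alleles_bound}, \code{predictor_id}.
#' @export
promiscuousBinders <- function(peptide, matrices, min_alleles = 1L,
                               arm = "hla1") {
  if (!length(matrices))
    stop("configuration error: empty matrix list")
  if (min_alleles < 1L) stop("min_alleles must be >= 1")
  scores <- vapply(matrices, function(m) scorePeptide(peptide, m),
                   numeric(1))
  thr <- vapply(matrices, binderThreshold, numeric(1))
  n <- sum(scores >= thr)
  list(peptide = peptide, arm = arm, positive = n >= min_alleles,
       n_alleles_bound = as.integer(n), predictor_id = "matrix_scorer")
}

#' Predictor constructors for the immune-arm interface
#'
#' An arm predictor is any deterministic function mapping a 9-mer to an
#' epitope call (list with at least \code{positive} and
#' \code{n_alleles_bound}). \code{matrixPredictor} wraps the built-in
#' matrix scorer over an allele panel; \code{propertyPredictor} wraps a
#' plain boolean function of the peptide (the adapter shape used for
#' external CTL/B-cell tools, which have no allele structure).
#'
#' @param matrices List of \linkS4class{ScoringMatrix}.
#' @param min_alleles Minimum bound alleles for a positive call.
#' @param arm Arm label (\code{"hla1"}, \code{"ctl"}, \code{"hla2"},
#'   \code{"bcell"}).
#' @param predictor_id Identifier recorded in each call.
#' @return A function \code{peptide -> epitope call}.
#' @export
matrixPredictor <- function(matrices, min_alleles = 1L, arm = "hla1",
                            predictor_id = "matrix_scorer") {
  force(matrices); force(min_alleles); force(arm); force(predictor_id)
  function(peptide) {
    call <- promiscuousBinders(peptide, matrices, min_alleles, arm)
    call$predictor_id <- predictor_id
    call
  }
}

#' @rdname matrixPredictor
#' @param is_positive Function \code{peptide -> logical(1)}.
#' @export
propertyPredictor <- function(is_positive, arm, predictor_id = "property") {
  force(is_positive); force(arm); force(predictor_id)
  function(peptide) {
    list(peptide = peptide, arm = arm,
         positive = isTRUE(is_positive(peptide)), n_alleles_bound = 0L,
         predictor_id = predictor_id)
  }
}

#' Classify peptides across the configured immune arms
#'
#' Runs every configured arm predictor on every peptide and aggregates the
#' calls: a peptide positive in at least one arm is a neoepitope; one
#' positive in every configured arm is a promiscuous epitope (able to
#' engage all arms of the immune system). A predictor failure on a peptide
#' is recorded (see \code{attr(, "errors")}) and treated as a negative
#' call for that arm; the run continues.
#'
#' @param peptides Character vector of 9-mers, or a data.frame with a
#'   \code{sequence} column.
#' @param predictors Named list of arm predictors (names are the arm
#'   labels); at least one required.
#' @return data.frame with one row per peptide: \code{peptide}, per arm
#'   \code{<arm>_positive} and \code{<arm>_n_alleles}, then
#'   \code{is_neoepitope} and \code{is_promiscuous}. Failures, if any, in
#'   \code{attr(, "errors")} (peptide, arm, message).
#' @export
classifyArms <- function(peptides, predictors) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (!length(predictors) || is.null(names(predictors)) ||
      any(!nzchar(names(predictors))))
    stop("configuration error: predictors must be a non-empty named list")
  arms <- names(predictors)
  n <- length(peptides)
  pos <- matrix(FALSE, n, length(arms), dimnames = list(NULL, arms))
  nall <- matrix(0L, n, length(arms), dimnames = list(NULL, arms))
  errs <- list()
  for (j in seq_along(arms)) {
    pred <- predictors[[j]]
    for (i in seq_len(n)) {
      call <- tryCatch(pred(peptides[i]), error = function(e)
        structure(conditionMessage(e), class = "arm_error"))
      if (inherits(call, "arm_error")) {
        errs[[length(errs) + 1L]] <- data.frame(
          peptide = peptides[i], arm = arms[j],
          message = unclass(call), stringsAsFactors = FALSE)
      } else {
        pos[i, j] <- isTRUE(call$positive)
        nall[i, j] <- as.integer(call$n_alleles_bound %||% 0L)
      }
    }
  }
  out <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  for (j in seq_along(arms)) {
    out[[paste0(arms[j], "_positive")]] <- pos[, j]
    out[[paste0(arms[j], "_n_alleles")]] <- nall[, j]
  }
  out$is_neoepitope <- rowSums(pos) >= 1L
  out$is_promiscuous <- rowSums(pos) == length(arms)
  if (length(errs)) attr(out, "errors") <- do.call(rbind, errs)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map experimentally validated epitopes onto an antigen
#'
#' Reports every exact occurrence (overlapping and repeated occurrences
#' included) of every epitope in the antigen with 1-based inclusive
#' coordinates. The search groups epitopes by length and matches all
#' antigen windows of that length by hashed set lookup, so the cost is
#' linear-ish in antigen length per distinct epitope length (comfortably
#' handles 10^4 epitopes against a 10^4-residue antigen).
#'
#' @param antigen Non-empty amino-acid string.
#' @param epitopes Named character vector (names = epitope ids) or a
#'   data.frame with columns \code{id}, \code{sequence}.
#' @return data.frame with columns \code{id}, \code{start}, \code{end},
#'   sorted by id then start.
#' @examples
#' mapValidatedEpitopes("AAA", c(e1 = "AA"))  # hits (1,2) and (2,3)
#' @export
mapValidatedEpitopes <- function(antigen, epitopes) {
  if (!nzchar(antigen)) stop("antigen must be non-empty")
  if (is.data.frame(epitopes))
    epitopes <- stats::setNames(epitopes$sequence, epitopes$id)
  if (any(!nzchar(epitopes))) stop("epitope sequences must be non-empty")
  L <- nchar(antigen)
  hits <- list()
  for (len in sort(unique(nchar(epitopes)))) {
    if (len > L) next
    eps <- epitopes[nchar(epitopes) == len]
    starts <- seq_len(L - len + 1L)
    windows <- substring(antigen, starts, starts + len - 1L)
    # every (epitope id, window) pair with identical sequence
    by_seq <- split(names(eps), eps)
    m <- by_seq[windows]
    found <- which(!vapply(m, is.null, logical(1)))
    for (s in found) {
      ids <- m[[s]]
      hits[[length(hits) + 1L]] <- data.frame(
        id = ids, start = starts[s], end = starts[s] + len - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile-based binder threshold for a scoring matrix
#'
#' For users with real quantitative matrices: sets the allele threshold so
#' that the top \code{top_frac} of a reference peptide set would be called
#' binders.
#'
#' @param matrix A \linkS4class{ScoringMatrix}.
#' @param reference_peptides Character vector of 9-mers.
#' @param top_frac Fraction of the reference set to call positive.
#' @return The matrix with its threshold replaced.
#' @export
percentileThreshold <- function(matrix, reference_peptides, top_frac = 0.04) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  scores <- vapply(reference_peptides, function(p) scorePeptide(p, matrix),
                   numeric(1))
  ScoringMatrix(matrix@allele, matrix@weights,
                stats::quantile(scores, 1 - top_frac, names = FALSE,
                                type = 7))
}
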
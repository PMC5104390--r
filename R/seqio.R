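#' Read a FASTA file with pipeline-grade validation
#'
#' Thin validating wrapper around \code{Biostrings::readBStringSet}. On top
#' of plain parsing it enforces the contracts the pipeline relies on:
#' records are uppercased and whitespace-stripped, record order is
#' preserved, duplicate ids are rejected, a sequence line before the first
#' header is a parse error naming the offending line, and alphabet rules
#' are applied (\code{"dna"}: A/C/G/T only, with an explicit message for U
#' so RNA input fails loudly; \code{"protein"}: a terminal stop symbol
#' \code{*} is stripped with a warning, an internal one is an error).
#'
#' @param path Path to an uncompressed FASTA file.
#' @param alphabet \code{"protein"} or \code{"dna"}.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), f)
#' readFasta(f, "dna")
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L) return(stats::setNames(character(), character()))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: sequence before first header at line ", first,
         " of ", path)
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(trimws(sub("^>", "", lines[hdr])))]
  if (length(empty_hdr))
    stop("malformed FASTA: empty header at line ", empty_hdr[1L], " of ", path)

  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids

  if (alphabet == "dna") {
    if (any(grepl("U", seqs, fixed = TRUE)))
      stop("FASTA contains U: RNA input is not accepted, provide DNA")
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad))
      stop("non-ACGT characters in record(s): ",
           paste(ids[bad], collapse = ", "))
  } else {
    internal <- regexpr("\\*", sub("\\*$", "", seqs)) > 0L
    if (any(internal))
      stop("internal stop symbol '*' in record(s): ",
           paste(ids[internal], collapse = ", "))
    if (any(endsWith(seqs, "*"))) {
      warning("stripped terminal stop symbol '*' from ",
              sum(endsWith(seqs, "*")), " record(s)")
      seqs <- sub("\\*$", "", seqs)
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

MUTATION_TABLE_COLS <- c("gene", "transcript", "cdna_change", "class",
                         "sample", "tissue")

# Parse one cdna_change string. Grammar:
#   c.<pos><ref>><alt> | c.<start>_<end>ins<seq> | c.<start>_<end>del |
#   c.<pos>del
# Returns a list(position, end, ref_nt, alt_nt, kind) or NULL on failure.
parseCdnaChange <- function(s) {
  m <- regmatches(s, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", s))[[1]]
  if (length(m))
    return(list(position = as.integer(m[2]), end = NA_integer_,
                ref_nt = m[3], alt_nt = m[4], kind = "substitution"))
  m <- regmatches(s, regexec("^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (end != start + 1L) return(NULL)  # ins is anchored between pos, pos+1
    return(list(position = start, end = end, ref_nt = NA_character_,
                alt_nt = m[4], kind = "insertion"))
  }
  m <- regmatches(s, regexec("^c\\.([0-9]+)_([0-9]+)del$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (end < start) return(NULL)
    return(list(position = start, end = end, ref_nt = NA_character_,
                alt_nt = NA_character_, kind = "deletion"))
  }
  m <- regmatches(s, regexec("^c\\.([0-9]+)del$", s))[[1]]
  if (length(m))
    return(list(position = as.integer(m[2]), end = as.integer(m[2]),
                ref_nt = NA_character_, alt_nt = NA_character_,
                kind = "deletion"))
  NULL
}

# Is the declared mutation class consistent with the parsed edit?
classConsistent <- function(mclass, edit) {
  switch(edit$kind,
    substitution = mclass == "missense",
    insertion = {
      len <- nchar(edit$alt_nt)
      if (len %% 3L == 0L) mclass == "inframe_ins" else mclass == "frameshift_ins"
    },
    deletion = {
      len <- edit$end - edit$position + 1L
      if (len %% 3L == 0L) mclass == "inframe_del" else mclass == "frameshift_del"
    })
}

#' Read a somatic mutation table
#'
#' Reads the minimal MAF-like dialect used throughout the pipeline: a
#' UTF-8 TSV with a header row and six required columns (\code{gene},
#' \code{transcript}, \code{cdna_change}, \code{class}, \code{sample},
#' \code{tissue}); \code{#}-prefixed comment lines are ignored. cDNA
#' coordinates are 1-based on the coding sequence starting at the A of the
#' ATG. Each \code{cdna_change} is parsed into position(s), reference and
#' alternate nucleotides and an edit kind, and checked for consistency with
#' the declared class (e.g. \code{class = missense} with a 2-nt insertion
#' is a row error, the in-frame classes require an edit length divisible by
#' three). Inconsistent or unparseable rows are reported per row, never
#' silently dropped.
#'
#' @param path Path to the TSV.
#' @param strict If \code{TRUE} (default) any row error aborts with a
#'   message listing the offending rows. If \code{FALSE}, valid rows are
#'   returned and the failures are attached as a data.frame in
#'   \code{attr(, "row_errors")}.
#' @return A data.frame of mutation records with columns \code{gene_id},
#'   \code{transcript_id}, \code{cdna_change}, \code{position}, \code{end},
#'   \code{ref_nt}, \code{alt_nt}, \code{kind}, \code{mclass},
#'   \code{sample}, \code{tissue}.
#' @export
readMutationTable <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MUTATION_TABLE_COLS, names(tab))
  if (length(missing_cols))
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  n <- nrow(tab)
  out <- data.frame(
    gene_id = as.character(tab$gene),
    transcript_id = as.character(tab$transcript),
    cdna_change = as.character(tab$cdna_change),
    position = rep(NA_integer_, n), end = rep(NA_integer_, n),
    ref_nt = rep(NA_character_, n), alt_nt = rep(NA_character_, n),
    kind = rep(NA_character_, n), mclass = as.character(tab$class),
    sample = as.character(tab$sample), tissue = as.character(tab$tissue),
    stringsAsFactors = FALSE)

  errors <- character(0); error_rows <- integer(0)
  for (i in seq_len(n)) {
    if (!out$mclass[i] %in% MUTATION_CLASSES) {
      errors <- c(errors, sprintf("row %d: unknown class '%s'", i, out$mclass[i]))
      error_rows <- c(error_rows, i); next
    }
    edit <- parseCdnaChange(out$cdna_change[i])
    if (is.null(edit)) {
      errors <- c(errors, sprintf("row %d: unparseable cdna_change '%s'",
                                  i, out$cdna_change[i]))
      error_rows <- c(error_rows, i); next
    }
    if (!classConsistent(out$mclass[i], edit)) {
      errors <- c(errors, sprintf(
        "row %d: class '%s' contradicts edit '%s'", i, out$mclass[i],
        out$cdna_change[i]))
      error_rows <- c(error_rows, i); next
    }
    out$position[i] <- edit$position; out$end[i] <- edit$end
    out$ref_nt[i] <- edit$ref_nt; out$alt_nt[i] <- edit$alt_nt
    out$kind[i] <- edit$kind
  }

  if (length(errors) && strict)
    stop("mutation table row error(s):\n  ", paste(errors, collapse = "\n  "))
  if (length(error_rows)) {
    err_df <- data.frame(row = error_rows, message = errors,
                         stringsAsFactors = FALSE)
    out <- out[-error_rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "row_errors") <- err_df
  }
  out
}

#' Write a mutation table in the pipeline dialect
#'
#' @param records Mutation-record data.frame as from
#'   \code{\link{readMutationTable}} (only the six dialect columns are
#'   written).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMutationTable <- function(records, path) {
  out <- data.frame(gene = records$gene_id, transcript = records$transcript_id,
                    cdna_change = records$cdna_change, class = records$mclass,
                    sample = records$sample, tissue = records$tissue,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position-specific scoring matrices
#'
#' Reads the scoring-matrix dialect: one block per allele, each block a
#' header line \code{ALLELE <name> THRESHOLD <float>} followed by exactly 9
#' rows of 20 tab-separated weights, residue column order
#' \code{ACDEFGHIKLMNPQRSTVWY}. Blank lines between blocks are ignored.
#'
#' @param path Path to the matrix TSV.
#' @return List of \linkS4class{ScoringMatrix}, one per allele block.
#' @export
readScoringMatrices <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  mats <- list()
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i],
                    regexec("^ALLELE\\s+(\\S+)\\s+THRESHOLD\\s+(\\S+)$",
                            lines[i]))[[1]]
    if (!length(m))
      stop("expected 'ALLELE <name> THRESHOLD <float>' header, got: ",
           lines[i])
    allele <- m[2]
    threshold <- suppressWarnings(as.numeric(m[3]))
    if (is.na(threshold)) stop("non-numeric threshold for allele ", allele)
    if (i + 9L > length(lines))
      stop("allele block '", allele, "' is missing weight rows (need 9)")
    rows <- strsplit(lines[(i + 1L):(i + 9L)], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != 20L)
    if (length(bad))
      stop("allele block '", allele, "': row ", bad[1L], " has ",
           lengths(rows)[bad[1L]], " columns, expected 20")
    w <- suppressWarnings(matrix(as.numeric(unlist(rows)), nrow = 9L,
                                 byrow = TRUE))
    if (any(is.na(w)))
      stop("allele block '", allele, "': non-numeric weight")
    colnames(w) <- AA_ALPHABET_20
    mats[[allele]] <- ScoringMatrix(allele, w, threshold)
    i <- i + 10L
  }
  mats
}

#' Write scoring matrices in the pipeline dialect
#'
#' @param matrices List of \linkS4class{ScoringMatrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeScoringMatrices <- function(matrices, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in matrices) {
    writeLines(sprintf("ALLELE %s THRESHOLD %.6g", m@allele, m@threshold), con)
    utils::write.table(m@weights, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a tabular report as TSV or JSON
#'
#' TSV output is round-trippable (\code{read.delim} of the file reproduces
#' the values); JSON output is an array with one object per record in
#' stable key order (the column order of \code{records}).
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
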
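configError <- function(...) {
  stop(structure(class = c("cancertope_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Build a run configuration
#'
#' Collects every input path and threshold of a screening run. Three modes
#' exist: \code{"cohort"} (mutation table + transcripts, full report
#' bundle including candidate statistics), \code{"partial"} (tumor input
#' screened against reference self stages only) and \code{"full"} (tumor
#' plus matched-normal input; the normal proteome becomes the first filter
#' stage). Mode-specific required inputs are validated up front;
#' violations signal a configuration error (condition class
#' \code{cancertope_config_error}).
#'
#' @param mode \code{"cohort"}, \code{"partial"} or \code{"full"}.
#' @param out_dir Report bundle directory.
#' @param self_stages Named list: stage label -> protein FASTA path, in
#'   cascade order.
#' @param transcripts cDNA FASTA (headers \code{gene|transcript}).
#' @param mutations Mutation table TSV.
#' @param tumor_proteins Tumor protein/proteome FASTA (partial/full modes;
#'   alternative to \code{mutations} + \code{transcripts}).
#' @param normal_proteins Matched-normal proteome FASTA (full mode).
#' @param matrices Scoring-matrix TSV (optional; enables the HLA arms).
#' @param expression Gene x cell-line expression TSV (optional).
#' @param canprovar_stats TSV with columns \code{gene_id}, \code{f_D},
#'   \code{f_P} (optional; cohort candidate selection).
#' @param k Peptide window length.
#' @param min_ratio,min_fD Association-rule thresholds.
#' @param freq Cohort mutation-frequency fraction.
#' @param min_alleles Bound-allele count for a positive HLA call.
#' @param cohort_size Cohort size for the frequency rule (default: number
#'   of distinct samples in the mutation table).
#' @param seed Seed recorded in the config (fixture generation only; the
#'   screening pipeline itself is deterministic).
#' @return A list of class \code{"cancertope_config"}.
#' @export
runConfig <- function(mode = c("cohort", "partial", "full"),
                      out_dir = "cancertope_reports",
                      self_stages = list(), transcripts = NULL,
                      mutations = NULL, tumor_proteins = NULL,
                      normal_proteins = NULL, matrices = NULL,
                      expression = NULL, canprovar_stats = NULL,
                      k = 9L, min_ratio = 2, min_fD = 20L, freq = 0.10,
                      min_alleles = 1L, cohort_size = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(list(
    mode = mode, out_dir = out_dir, self_stages = self_stages,
    transcripts = transcripts, mutations = mutations,
    tumor_proteins = tumor_proteins, normal_proteins = normal_proteins,
    matrices = matrices, expression = expression,
    canprovar_stats = canprovar_stats, k = as.integer(k),
    min_ratio = min_ratio, min_fD = min_fD, freq = freq,
    min_alleles = as.integer(min_alleles), cohort_size = cohort_size,
    seed = as.integer(seed)), class = "cancertope_config")
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  need <- function(field, why) {
    if (is.null(cfg[[field]]))
      configError("mode '", cfg$mode, "' requires '", field, "' (", why, ")")
  }
  if (!length(cfg$self_stages) && cfg$mode != "full")
    configError("at least one self-filter stage is required")
  if (cfg$mode == "cohort") {
    need("transcripts", "reference coding sequences")
    need("mutations", "somatic mutation table")
  } else {
    if (is.null(cfg$tumor_proteins) &&
        (is.null(cfg$mutations) || is.null(cfg$transcripts)))
      configError("tumor input required: either tumor_proteins or ",
                  "mutations + transcripts")
    if (cfg$mode == "full") need("normal_proteins", "matched normal proteome")
  }
  for (f in c("transcripts", "mutations", "tumor_proteins",
              "normal_proteins", "matrices", "expression",
              "canprovar_stats")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      configError("input file for '", f, "' does not exist: ", cfg[[f]])
  }
  for (s in names(cfg$self_stages))
    if (!file.exists(cfg$self_stages[[s]]))
      configError("self stage '", s, "' file does not exist: ",
                  cfg$self_stages[[s]])
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors \code{\link{runConfig}}'s arguments; unknown keys are
#' rejected. Relative paths are interpreted relative to the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A \code{"cancertope_config"} list.
#' @export
readRunConfig <- function(path, ...) {
  if (!file.exists(path)) configError("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    configError("unknown config key(s): ", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (f in c("transcripts", "mutations", "tumor_proteins",
              "normal_proteins", "matrices", "expression",
              "canprovar_stats", "out_dir"))
    vals[[f]] <- rel(vals[[f]])
  vals$self_stages <- lapply(vals$self_stages, rel)
  do.call(runConfig, vals)
}

# ---- shared pipeline pieces ---------------------------------------------

loadTranscripts <- function(path) {
  cdna <- readFasta(path, "dna")
  parts <- strsplit(names(cdna), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("transcript FASTA headers must be 'gene|transcript', got: ",
         names(cdna)[bad][1])
  txs <- Map(function(p, s) Transcript(p[1], p[2], s), parts, cdna)
  names(txs) <- vapply(txs, transcriptId, character(1))
  txs
}

loadStages <- function(stage_paths, k) {
  stages <- vector("list", length(stage_paths))
  for (i in seq_along(stage_paths)) {
    seqs <- readFasta(stage_paths[[i]], "protein")
    stages[[i]] <- suppressWarnings(
      buildPeptideIndex(seqs, k, label = names(stage_paths)[i]))
  }
  stages
}

# Extract, pool and dedupe neopeptides from a mutation table; returns the
# peptide table plus counters for the run log.
extractFromMutations <- function(cfg, log) {
  txs <- loadTranscripts(cfg$transcripts)
  records <- readMutationTable(cfg$mutations, strict = FALSE)
  row_errors <- attr(records, "row_errors")
  log$add("mutation_records_read",
          n = nrow(records) + NROW(row_errors),
          parse_errors = NROW(row_errors))
  if (!is.null(row_errors))
    for (i in seq_len(nrow(row_errors)))
      log$add("row_error", row = row_errors$row[i],
              message = row_errors$message[i])
  counters <- c(silent = 0L, dropped_x = 0L, unknown_transcript = 0L,
                build_errors = 0L)
  peps <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    tx <- txs[[rec$transcript_id]]
    if (is.null(tx)) {
      counters["unknown_transcript"] <- counters["unknown_transcript"] + 1L
      log$add("row_error", row = i,
              message = paste0("unknown transcript ", rec$transcript_id))
      next
    }
    mp <- tryCatch(buildMutant(tx, rec), error = function(e) e)
    if (inherits(mp, "error")) {
      counters["build_errors"] <- counters["build_errors"] + 1L
      log$add("row_error", row = i, message = conditionMessage(mp))
      next
    }
    if (isSilent(mp)) {
      counters["silent"] <- counters["silent"] + 1L
      next
    }
    p <- extractNeopeptides(mp, cfg$k)
    counters["dropped_x"] <- counters["dropped_x"] + attr(p, "n_dropped_x")
    peps[[length(peps) + 1L]] <- p
  }
  log$add("extraction_done", silent_dropped = counters[["silent"]],
          x_windows_dropped = counters[["dropped_x"]],
          unknown_transcript = counters[["unknown_transcript"]],
          build_errors = counters[["build_errors"]])
  if (!length(peps))
    warning("mutation table produced no usable neopeptides")
  pooled <- if (length(peps)) do.call(rbind, peps)
            else extractNeopeptidesEmpty()
  list(peptides = dedupeNeopeptides(pooled, "antigen"), records = records)
}

extractNeopeptidesEmpty <- function() {
  data.frame(sequence = character(), gene_id = character(),
             window_start = integer(), samples = character(),
             tissues = character(), stringsAsFactors = FALSE)
}

# All windows of every tumor protein (single-sequence screening path).
windowsFromProteins <- function(path, k) {
  prot <- readFasta(path, "protein")
  out <- lapply(seq_along(prot), function(i) {
    w <- peptideWindows(prot[[i]], k)
    if (!nrow(w)) return(NULL)
    data.frame(sequence = w$peptide, gene_id = names(prot)[i],
               window_start = w$start, samples = "tumor",
               tissues = "tumor", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- extractNeopeptidesEmpty()
  dedupeNeopeptides(out, "antigen")
}

tissueSummary <- function(filtered) {
  surv <- filtered[filtered$survives, , drop = FALSE]
  if (!nrow(surv))
    return(data.frame(gene_id = character(), tissue = character(),
                      n_neopeptides = integer(), stringsAsFactors = FALSE))
  long <- do.call(rbind, lapply(seq_len(nrow(surv)), function(i)
    data.frame(gene_id = surv$gene_id[i],
               tissue = strsplit(surv$tissues[i], ",", fixed = TRUE)[[1]],
               sequence = surv$sequence[i], stringsAsFactors = FALSE)))
  agg <- stats::aggregate(sequence ~ gene_id + tissue, long,
                          function(s) length(unique(s)))
  names(agg)[3] <- "n_neopeptides"
  agg <- agg[order(agg$gene_id, agg$tissue), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-gene, per-arm positivity summary
#'
#' For each gene and immune arm: the number of positive peptides and the
#' number of distinct cell lines those peptides were observed in
#' (accounting in the style of per-arm cohort supplements).
#'
#' @param profiles Output of \code{\link{classifyArms}}.
#' @param peptides The peptide table the profiles were computed from
#'   (must carry \code{sequence}, \code{gene_id}, \code{samples}).
#' @return data.frame: \code{gene_id}, \code{arm},
#'   \code{n_positive_peptides}, \code{n_cell_lines}.
#' @export
armSummary <- function(profiles, peptides) {
  arm_cols <- grep("_positive$", names(profiles), value = TRUE)
  arms <- sub("_positive$", "", arm_cols)
  m <- merge(peptides, profiles, by.x = "sequence", by.y = "peptide")
  rows <- list()
  for (g in sort(unique(m$gene_id))) {
    mg <- m[m$gene_id == g, , drop = FALSE]
    for (j in seq_along(arms)) {
      pos <- mg[mg[[arm_cols[j]]], , drop = FALSE]
      cls <- unique(unlist(strsplit(pos$samples, ",", fixed = TRUE)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, arm = arms[j], n_positive_peptides = nrow(pos),
        n_cell_lines = length(cls), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), arm = character(),
                      n_positive_peptides = integer(),
                      n_cell_lines = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

makeLogger <- function() {
  events <- list()
  list(add = function(event, ...) {
    events[[length(events) + 1L]] <<- c(list(event = event), list(...))
  },
  write = function(path) {
    lines <- vapply(events, function(e)
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)),
      character(1))
    writeLines(lines, path)
  })
}

emptyProfiles <- function() {
  data.frame(peptide = character(), is_neoepitope = logical(),
             is_promiscuous = logical(), stringsAsFactors = FALSE)
}

# Shared screening core: peptides -> cascade -> reports. Used by all
# three modes so that identical inputs produce byte-identical bundles.
runScreen <- function(cfg, peptides, stages, log, extra = list()) {
  filtered <- filterCascade(peptides, stages)
  counts <- stageCounts(filtered)
  sc <- attr(filtered, "stage_counts")
  log$add("filter_cascade", stages = sc$stage, surviving = sc$surviving)

  survivors <- filtered[filtered$survives, , drop = FALSE]
  profiles <- emptyProfiles()
  arm_sum <- NULL
  if (!is.null(cfg$matrices) && nrow(survivors)) {
    mats <- readScoringMatrices(cfg$matrices)
    predictors <- list(hla1 = matrixPredictor(mats, cfg$min_alleles, "hla1"))
    profiles <- classifyArms(survivors$sequence, predictors)
    errs <- attr(profiles, "errors")
    if (!is.null(errs))
      for (i in seq_len(nrow(errs)))
        log$add("predictor_error", peptide = errs$peptide[i],
                arm = errs$arm[i], message = errs$message[i])
    arm_sum <- armSummary(profiles, survivors)
    log$add("immuno", n_neoepitopes = sum(profiles$is_neoepitope),
            n_promiscuous = sum(profiles$is_promiscuous))
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    neopeptides = file.path(cfg$out_dir, "neopeptides.tsv"),
    filter_counts = file.path(cfg$out_dir, "filter_counts.tsv"),
    profiles = file.path(cfg$out_dir, "profiles.tsv"),
    run_log = file.path(cfg$out_dir, "run_log.jsonl"))
  writeReport(filtered, paths$neopeptides)
  writeReport(counts, paths$filter_counts)
  writeReport(profiles, paths$profiles)

  out <- c(list(neopeptides = filtered, filter_counts = counts,
                profiles = profiles, arm_summary = arm_sum), extra)
  for (nm in names(extra)) {
    paths[[nm]] <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    writeReport(extra[[nm]], paths[[nm]])
  }
  log$write(paths$run_log)
  out$paths <- paths
  invisible(out)
}

#' Run the cohort database build
#'
#' End-to-end cohort mode: read the mutation table and reference
#' transcripts, build and translate every mutant, extract and pool
#' neopeptides per gene, screen them through the self-filter cascade,
#' classify surviving peptides across the configured immune arms, and
#' compute candidate-gene statistics (association rule if a stats table is
#' configured, cohort mutation-frequency rule from the mutation table,
#' expression bins if an expression matrix is configured). Row-level
#' input errors are logged with context and skipped; only configuration
#' errors abort. All outputs are deterministic for fixed inputs.
#'
#' @param config A \code{"cancertope_config"} (mode \code{"cohort"}).
#' @return Invisibly, the report bundle: data.frames plus output paths.
#' @export
runCohort <- function(config) {
  validateConfig(config)
  log <- makeLogger()
  ex <- extractFromMutations(config, log)
  stages <- loadStages(config$self_stages, config$k)

  extra <- list(tissue_summary = NULL, candidates = NULL,
                expression_bins = NULL)
  # frequency rule over the mutation table
  recs <- ex$records
  cohort_size <- config$cohort_size %||%
    length(unique(recs$sample))
  freq_genes <- character()
  if (nrow(recs) && cohort_size >= 1L) {
    by_gene <- split(recs$sample, recs$gene_id)
    freq_genes <- selectByFrequency(by_gene, cohort_size, config$freq)
    log$add("frequency_rule", cohort_size = cohort_size,
            threshold = attr(freq_genes, "threshold"),
            n_selected = length(freq_genes))
  }
  cp_genes <- character()
  stats_df <- NULL
  if (!is.null(config$canprovar_stats)) {
    stats_df <- utils::read.delim(config$canprovar_stats,
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
    if ("target" %in% names(stats_df) && !"gene_id" %in% names(stats_df))
      names(stats_df)[names(stats_df) == "target"] <- "gene_id"
    cp_genes <- selectCanProVar(stats_df, config$min_ratio, config$min_fD)
    log$add("canprovar_rule", n_selected = length(cp_genes))
  }
  cand <- mergeCandidates(cp_genes, freq_genes)
  n_samp <- vapply(cand$gene_id, function(g)
    length(unique(recs$sample[recs$gene_id == g])), integer(1))
  cand$mutated_samples <- unname(n_samp)
  if (!is.null(stats_df)) {
    m <- match(cand$gene_id, stats_df$gene_id)
    cand$f_D <- stats_df$f_D[m]
    cand$f_P <- stats_df$f_P[m]
    cand$ratio <- NA_real_
    idx <- which(!is.na(m))
    if (length(idx))
      cand$ratio[idx] <- associationRatio(cand$f_D[idx], cand$f_P[idx])
  }
  extra$candidates <- cand

  if (!is.null(config$expression)) {
    expr_df <- utils::read.delim(config$expression, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    expr <- as.matrix(expr_df[, -1, drop = FALSE])
    rownames(expr) <- expr_df[[1]]
    genes <- sort(unique(c(rownames(expr), cand$gene_id)))
    extra$expression_bins <- expressionBins(expr, genes)
  }

  out <- runScreenWithTissues(config, ex$peptides, stages, log, extra)
  invisible(out)
}

runScreenWithTissues <- function(cfg, peptides, stages, log, extra = list()) {
  filtered <- filterCascade(peptides, stages)
  extra$tissue_summary <- tissueSummary(filtered)
  extra <- Filter(Negate(is.null), extra)
  runScreen(cfg, peptides, stages, log, extra)
}

#' Run the partially personalized screen
#'
#' Screens tumor-derived peptides against the reference self stages only
#' (no matched normal). When a mutation table and transcripts are
#' configured, only mutation-overlapping windows are considered (the
#' neopeptide-extraction path); when a tumor protein FASTA is given, all
#' of its windows are screened (the single-sequence cross-reactivity
#' path).
#'
#' @param config A \code{"cancertope_config"} (mode \code{"partial"} or
#'   \code{"full"}).
#' @return Invisibly, the report bundle.
#' @export
runPartial <- function(config) {
  validateConfig(config)
  log <- makeLogger()
  peptides <- if (!is.null(config$mutations) && !is.null(config$transcripts))
    extractFromMutations(config, log)$peptides
  else windowsFromProteins(config$tumor_proteins, config$k)
  stages <- loadStages(config$self_stages, config$k)
  invisible(runScreen(config, peptides, stages, log))
}

#' Run the fully personalized screen
#'
#' Like \code{\link{runPartial}}, but the matched-normal proteome is
#' compiled into a peptide index placed first in the cascade, so peptides
#' present anywhere in the patient's healthy proteome are eliminated
#' before any reference stage. A normal input containing no k-mers
#' contributes no stage, making the run identical to the partially
#' personalized screen.
#'
#' @param config A \code{"cancertope_config"} (mode \code{"full"}).
#' @return Invisibly, the report bundle.
#' @export
runFull <- function(config) {
  validateConfig(config)
  if (is.null(config$normal_proteins))
    configError("full mode requires 'normal_proteins'")
  log <- makeLogger()
  peptides <- if (!is.null(config$mutations) && !is.null(config$transcripts))
    extractFromMutations(config, log)$peptides
  else windowsFromProteins(config$tumor_proteins, config$k)
  normal_seqs <- readFasta(config$normal_proteins, "protein")
  normal_idx <- suppressWarnings(
    buildPeptideIndex(normal_seqs, config$k, label = "personal_normal"))
  stages <- loadStages(config$self_stages, config$k)
  if (nKmers(normal_idx) > 0L) stages <- c(list(normal_idx), stages)
  invisible(runScreen(config, peptides, stages, log))
}
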
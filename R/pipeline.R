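#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> sequence -> process (quality filter, pair
#' and merge, demultiplex, UMI consensus, duplicate collapse) ->
#' annotate -> clone -> diversity -> span overlap -> proteome overlap
#' -> statistics, writing each stage's TSV plus a JSON log under
#' `outDir`. The run is idempotent under a fixed seed.
#'
#' @param config A YAML path or a list; see Details. Keys: `seed`,
#'   `out_dir`, `cohort` (arguments to [cohortConfig()]), `reads`
#'   (`error_rate`, `pcr_duplication`; set `simulate: false` to skip
#'   read-level simulation and use truth consensus records),
#'   `peptides` (`n_per_sample`, `decoy_fraction`), `diversity`
#'   (`n_resample`, `n_boot`), `min_sample_records` (samples holding
#'   fewer annotated records are excluded and logged).
#' @param outDir Output directory (overrides `config$out_dir`).
#' @param seed Seed (overrides `config$seed`).
#' @return Invisibly, a list of the main result tables.
#' @export
runPipeline <- function(config = list(), outDir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  outDir <- outDir %||% config$out_dir %||%
    stop("configuration error: no output directory given")
  seed <- seed %||% config$seed %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = seed)
  tsv <- function(df, name) {
    write.table(df, file.path(outDir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }

  cohort_args <- config$cohort %||% list(nPatients = 2L, nClones = 80L,
                                         sizeCap = 50)
  cfg <- do.call(cohortConfig, cohort_args)
  sim <- simulateCohort(cfg, seed = seed)
  log$simulate <- c(clones = nrow(sim$clones), molecules = nrow(sim$cells))
  writeGermlineFasta(sim$germline, file.path(outDir, "germline.fasta"))

  simulate_reads <- isTRUE((config$reads %||% list())$simulate %||% TRUE)
  if (simulate_reads) {
    rd_cfg <- config$reads %||% list()
    reads <- simulateReads(sim,
                           errorRate = rd_cfg$error_rate %||% 0.001,
                           pcrDuplication = rd_cfg$pcr_duplication %||% 3,
                           seed = seed + 1L)
    fq <- filterQuality(reads, qThreshold = rd_cfg$q_threshold %||% 20)
    log$filter_quality <- attr(fq, "stepLog")
    merged <- pairAndMerge(fq)
    log$pair_merge <- attr(merged, "stepLog")
    dmx <- demultiplex(merged)
    log$demultiplex <- dmx$log
    cons <- consensusFromReads(dmx$assigned,
                               maxError = rd_cfg$max_error %||% 0.1,
                               minReads = rd_cfg$min_reads %||% 2L)
    log$consensus <- attr(cons, "stepLog")
    # molecule -> sample metadata travels on the UMI (one molecule, one
    # sample); recover it from the read table
    mol <- sim$cells[match(
      reads$truth_uid[match(cons$umi, reads$umi)],
      sim$cells$molecule_id), ]
    cons$patient <- mol$patient
    cons$timepoint <- mol$timepoint
    coll <- collapseDuplicates(cons)
    log$collapse <- attr(coll, "stepLog")
  } else {
    coll <- truthRearrangements(sim)
    log$consensus <- c(input = nrow(coll), pass = nrow(coll))
  }

  ann <- if (simulate_reads)
    annotateRepertoire(coll, sim$germline)
  else {
    x <- coll
    attr(x, "stepLog") <- c(input = nrow(x), pass = nrow(x))
    x
  }
  log$annotate <- attr(ann, "stepLog")
  repr <- ann[ann$productive, , drop = FALSE]

  # sample-exclusion floor (a sample failing a minimum-record floor is
  # dropped and logged)
  floor_n <- config$min_sample_records %||% 0L
  if (floor_n > 0L) {
    key <- paste(repr$patient, repr$timepoint, repr$subset)
    sizes <- table(key)
    drop_keys <- names(sizes)[sizes < floor_n]
    log$excluded_samples <- drop_keys
    repr <- repr[!(key %in% drop_keys), , drop = FALSE]
  }

  repr <- assignCloneIds(repr)
  tsv(repr, "rearrangements")
  writeAirr(repr, file.path(outDir, "rearrangements_airr.tsv"))
  clones <- cloneSummary(repr)
  tsv(clones, "clones")

  div_cfg <- config$diversity %||% list()
  div <- diversityTable(repr, q = c(0, 1),
                        nResample = div_cfg$n_resample %||% 951L,
                        nBoot = div_cfg$n_boot %||% 200L,
                        seed = seed + 2L)
  tsv(div, "diversity")
  exp_tab <- expandedCloneTable(repr)
  tsv(exp_tab, "expanded_clones")

  spans <- computeSpans(repr)
  spans_sub <- computeSpans(repr, bySubset = TRUE)
  tsv(spans, "clone_spans")
  tsv(spanClassCounts(spans), "span_class_counts")
  tsv(spanClassCounts(spans_sub, "per-subset"), "span_class_counts_subset")

  pep_cfg <- config$peptides %||% list()
  peptides <- simulateSerumPeptides(
    sim, nPerSample = pep_cfg$n_per_sample %||% 50L,
    decoyFraction = pep_cfg$decoy_fraction %||% 0.05, seed = seed + 3L)
  tsv(peptides, "serum_peptides")
  prot_res <- list()
  for (pat in unique(repr$patient)) {
    prep <- repr[repr$patient == pat, , drop = FALSE]
    bdb <- translateBcr(prep, sim$germline)
    bdb$clone_id <- prep$clone_id
    pp <- peptides[peptides$patient == pat, , drop = FALSE]
    mm <- matchPeptides(pp$peptide_aa, bdb)
    att <- attributeSpecificPeptides(mm, prep, peptideMeta = pp)
    prot_res[[pat]] <- cbind(pp[, c("patient", "timepoint")], mm)
    tsvname <- paste0("peptide_attribution_", pat)
    if (nrow(att$attributions)) tsv(att$attributions, tsvname)
  }
  matches <- do.call(rbind, prot_res)
  rownames(matches) <- NULL
  tsv(matches, "peptide_matches")

  # statistics: memory-subset diversity across time points
  stats_out <- list()
  mem <- div[div$subset == "memory" & div$q == 0, , drop = FALSE]
  if (nrow(mem) > 0 && length(unique(mem$patient)) >= 2 &&
      all(table(mem$patient) == length(TIMEPOINTS))) {
    g <- split(mem$bootstrap_mean, factor(mem$timepoint, TIMEPOINTS))
    cr <- kwThenWilcoxon(g, pairs = list(c("B", "6M"), c("B", "12M"),
                                         c("6M", "12M")))
    stats_out$memory_q0 <- list(statistic = cr$statistic,
                                p_value = cr$p_value)
  }
  log$stats <- stats_out
  jsonlite::write_json(log, file.path(outDir, "pipeline_log.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(rearrangements = repr, clones = clones, diversity = div,
                 spans = spans, peptide_matches = matches, log = log))
}
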
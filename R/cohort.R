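#' Scenario configuration for the synthetic cohort generator
#'
#' Defaults emulate the shape of a longitudinal treatment-course study:
#' 8 patients sampled at baseline (B), 6 months (6M) and 12 months
#' (12M), four sorted B-cell subsets, power-law (Zipf-type) clone sizes,
#' uniform somatic hypermutation within clones, subset-dependent isotype
#' usage, a persistence-class distribution in which clones spanning more
#' than one time point split 2/12/26/60% across the
#' B+6M / B+12M / 6M+12M / B+6M+12M classes, and a 3-fold depletion of
#' clones from the memory compartment at 6M that is sustained at 12M.
#'
#' @param nPatients Number of patients.
#' @param nClones Clones per patient.
#' @param powerExponent Exponent of the clone-size power law
#'   (density proportional to size^-powerExponent).
#' @param sizeCap Upper truncation of the clone-size law.
#' @param memoryDepletion Fold reduction of memory-resident clones at 6M
#'   and 12M (1 = null scenario, no treatment effect).
#' @param depletionBias Exponent biasing depletion toward small clones
#'   (0 = size-independent).
#' @param persistenceProbs Named probability vector over the 7 time-point
#'   span classes (see `SPAN_CLASSES` order "B","6M","12M","B+6M",
#'   "B+12M","6M+12M","B+6M+12M"); must sum to 1.
#' @param shmRate Per-base somatic hypermutation rate applied per
#'   molecule relative to the clone founder sequence.
#' @param subsetBaseWeights Cohort-level mean subset composition.
#' @param subsetConcentration Dirichlet concentration for per-clone
#'   subset propensities.
#' @param junctionMean,junctionSd Mean/sd (nt) of the junction-length
#'   distribution, snapped to in-frame lengths in 21..72 nt.
#' @param nVFamilies,nJ,nAllelesPerFamily Germline database dimensions.
#' @return A list of class `ScenarioConfig`.
#' @export
cohortConfig <- function(nPatients = 8L,
                         nClones = 1500L,
                         powerExponent = 1.5,
                         sizeCap = 1000,
                         memoryDepletion = 3,
                         depletionBias = 0.5,
                         persistenceProbs = NULL,
                         shmRate = 0.02,
                         subsetBaseWeights = c(naive = 0.45, memory = 0.30,
                                               DN = 0.15, plasmablast = 0.10),
                         subsetConcentration = 2,
                         junctionMean = 45, junctionSd = 9,
                         nVFamilies = 5L, nJ = 6L, nAllelesPerFamily = 2L) {
  if (is.null(persistenceProbs)) {
    # half the clones are single-time-point; multi-time-point clones
    # follow the 2/12/26/60 split
    persistenceProbs <- c(rep(0.5 / 3, 3),
                          0.5 * c(0.02, 0.12, 0.26, 0.60))
    names(persistenceProbs) <- SPAN_CLASSES
  }
  if (is.null(names(persistenceProbs)))
    names(persistenceProbs) <- SPAN_CLASSES
  if (abs(sum(persistenceProbs) - 1) > 1e-8)
    stop("configuration error: persistenceProbs must sum to 1")
  if (!setequal(names(persistenceProbs), SPAN_CLASSES))
    stop("configuration error: persistenceProbs must cover the 7 span classes")
  if (abs(sum(subsetBaseWeights) - 1) > 1e-8)
    stop("configuration error: subsetBaseWeights must sum to 1")
  if (memoryDepletion < 1)
    stop("configuration error: memoryDepletion must be >= 1")
  structure(list(
    nPatients = as.integer(nPatients), nClones = as.integer(nClones),
    powerExponent = powerExponent, sizeCap = sizeCap,
    memoryDepletion = memoryDepletion, depletionBias = depletionBias,
    persistenceProbs = persistenceProbs[SPAN_CLASSES],
    shmRate = shmRate,
    subsetBaseWeights = subsetBaseWeights[SUBSETS],
    subsetConcentration = subsetConcentration,
    junctionMean = junctionMean, junctionSd = junctionSd,
    nVFamilies = as.integer(nVFamilies), nJ = as.integer(nJ),
    nAllelesPerFamily = as.integer(nAllelesPerFamily)),
    class = "ScenarioConfig")
}

# isotype usage templates keyed by a clone's dominant subset
ISOTYPE_TEMPLATES <- list(
  naive = c(IgM = 0.60, IgD = 0.30, IgG = 0.08, IgA = 0.02),
  memory = c(IgM = 0.15, IgD = 0.05, IgG = 0.55, IgA = 0.25),
  DN = c(IgM = 0.35, IgD = 0.05, IgG = 0.40, IgA = 0.20),
  plasmablast = c(IgM = 0.10, IgD = 0.02, IgG = 0.55, IgA = 0.33))

# inverse-CDF sample from a power law truncated to [1, cap]:
# density proportional to x^-exponent on that interval
rPowerLaw <- function(n, exponent, cap) {
  a <- exponent - 1
  u <- runif(n)
  (1 - u * (1 - cap^(-a)))^(-1 / a)
}

# CDF of the same truncated power law (for KS checks)
pPowerLaw <- function(q, exponent, cap) {
  a <- exponent - 1
  pmin(1, pmax(0, (1 - q^(-a)) / (1 - cap^(-a))))
}

spanOfClass <- function(class) strsplit(class, "+", fixed = TRUE)

#' Simulate a longitudinal B-cell repertoire cohort
#'
#' Draws ground-truth clones (germline assignment, junction, power-law
#' abundance, persistence class, subset propensities, isotype usage) and
#' realises per-sample molecule (cell) tables, including the
#' memory-compartment depletion effect at 6M/12M. Every clone has at
#' least one molecule at every time point of its persistence class, so
#' realised spans equal configured spans.
#'
#' @param config A [cohortConfig()] list.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `CohortSim` with elements `clones` (truth
#'   clone table), `cells` (one row per molecule), `germline`
#'   ([GermlineDb-class]) and `config`.
#' @export
simulateCohort <- function(config = cohortConfig(), seed = NULL) {
  stopifnot(inherits(config, "ScenarioConfig"))
  withSeed(seed, {
    db <- generateGermlineDb(config$nVFamilies, config$nJ,
                             config$nAllelesPerFamily)
    v_names <- names(vSegments(db)); j_names <- names(jSegments(db))
    v_widths <- setNames(Biostrings::width(vSegments(db)), v_names)
    v_seqs <- setNames(as.character(vSegments(db)), v_names)
    j_seqs <- setNames(as.character(jSegments(db)), j_names)
    jl_grid <- seq(21L, 72L, by = 3L)
    jl_w <- exp(-((jl_grid - config$junctionMean)^2) /
                  (2 * config$junctionSd^2))
    patients <- sprintf("P%02d", seq_len(config$nPatients))
    clone_rows <- vector("list", length(patients))
    cell_rows <- list()
    for (pi in seq_along(patients)) {
      pat <- patients[pi]
      n <- config$nClones
      v_call <- sample(v_names, n, replace = TRUE)
      j_call <- sample(j_names, n, replace = TRUE)
      jlen <- sample(jl_grid, n, replace = TRUE, prob = jl_w)
      insert <- vapply(jlen, function(L) randSenseCodons((L - 6L) / 3L),
                       character(1))
      founder <- paste0(v_seqs[v_call], insert, j_seqs[j_call])
      vlen <- v_widths[v_call]
      junction <- substr(founder, vlen - 2L, vlen - 3L + jlen)
      pclass <- sample(SPAN_CLASSES, n, replace = TRUE,
                       prob = config$persistenceProbs)
      lambda <- rPowerLaw(n, config$powerExponent, config$sizeCap)
      # per-clone subset propensities (Dirichlet, floored away from 0)
      alpha <- config$subsetConcentration * config$subsetBaseWeights
      g <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), nrow = n)
      w <- g / rowSums(g)
      w <- (w + 0.02) / (1 + 0.08)
      colnames(w) <- SUBSETS
      dominant <- SUBSETS[max.col(w, ties.method = "first")]
      # memory depletion: silence the memory compartment of a fraction
      # (1 - 1/d) of clones at 6M/12M, preferentially the small ones
      d <- config$memoryDepletion
      if (d > 1) {
        # calibrate silencing so the EXPECTED memory clone count drops
        # d-fold: weight by each clone's probability of showing >= 1
        # memory molecule at a time point (small clones are both more
        # likely silenced and less likely observed)
        w_mem <- w[, "memory"]
        q_pres <- 1 - (1 - w_mem) * exp(-pmax(lambda - 1, 0) * w_mem)
        base_p <- lambda^(-config$depletionBias)
        target <- 1 - 1 / d
        f <- function(cc) sum(q_pres * pmin(1, cc * base_p)) /
          sum(q_pres) - target
        cc <- stats::uniroot(f, c(0, 1e9), tol = 1e-10)$root
        p_sil <- pmin(1, cc * base_p)
        silenced <- runif(n) < p_sil
      } else silenced <- rep(FALSE, n)
      clone_uid <- sprintf("%s_T%04d", pat, seq_len(n))
      clone_rows[[pi]] <- data.frame(
        clone_uid = clone_uid, patient = pat, v_call = v_call,
        j_call = j_call, junction = junction, junction_length = jlen,
        sequence = founder, persistence_class = pclass, lambda = lambda,
        silenced_memory = silenced, dominant_subset = dominant,
        w, stringsAsFactors = FALSE)
      # realise molecules per (clone, time point in persistence class)
      tp_sets <- spanOfClass(pclass)
      acc <- list(clone = list(), tp = list(), sub = list(),
                  iso = list(), seq = list(), ci = list())
      for (ci in seq_len(n)) {
        iso_p <- ISOTYPE_TEMPLATES[[dominant[ci]]]
        for (tp in tp_sets[[ci]]) {
          n_mol <- 1L + rpois(1L, max(lambda[ci] - 1, 0))
          wt <- w[ci, ]
          if (silenced[ci] && tp != "B") wt["memory"] <- 0
          subs <- SUBSETS[sample.int(4L, n_mol, replace = TRUE,
                                     prob = wt)]
          isos <- ISOTYPES[sample.int(4L, n_mol, replace = TRUE,
                                      prob = iso_p)]
          if (config$shmRate > 0) {
            seqs <- vapply(seq_len(n_mol), function(k)
              mutateSeq(founder[ci], config$shmRate), character(1))
          } else seqs <- rep(founder[ci], n_mol)
          k <- length(acc$clone) + 1L
          acc$clone[[k]] <- rep(clone_uid[ci], n_mol)
          acc$tp[[k]] <- rep(tp, n_mol)
          acc$sub[[k]] <- subs
          acc$iso[[k]] <- isos
          acc$seq[[k]] <- seqs
          acc$ci[[k]] <- rep(ci, n_mol)
        }
      }
      seqs_all <- unlist(acc$seq)
      if (config$shmRate > 0 && length(seqs_all)) {
        # hypermutated variants carrying an in-frame stop are not part
        # of the expressed repertoire; redraw them (batch translation)
        ci_all <- unlist(acc$ci)
        for (try in 1:10) {
          bad <- which(grepl("*", translateNt(seqs_all), fixed = TRUE))
          if (!length(bad)) break
          seqs_all[bad] <- vapply(bad, function(k)
            mutateSeq(founder[ci_all[k]], config$shmRate), character(1))
        }
        bad <- grepl("*", translateNt(seqs_all), fixed = TRUE)
        if (any(bad)) seqs_all[bad] <- founder[ci_all[bad]]
      }
      cell_rows[[pi]] <- data.frame(
        patient = pat, clone_uid = unlist(acc$clone),
        timepoint = unlist(acc$tp), subset = unlist(acc$sub),
        isotype = unlist(acc$iso), sequence = seqs_all,
        stringsAsFactors = FALSE)
    }
    clones <- do.call(rbind, clone_rows)
    cells <- do.call(rbind, cell_rows)
    cells$molecule_id <- sprintf("M%07d", seq_len(nrow(cells)))
    rownames(clones) <- rownames(cells) <- NULL
    structure(list(clones = clones, cells = cells, germline = db,
                   config = config), class = "CohortSim")
  })
}

#' @export
print.CohortSim <- function(x, ...) {
  cat("CohortSim:", length(unique(x$clones$patient)), "patients,",
      nrow(x$clones), "true clones,", nrow(x$cells), "molecules\n")
  invisible(x)
}

#' Ground-truth rearrangement table from a simulated cohort
#'
#' Collapses the molecule table to unique consensus-level records: one
#' row per distinct nucleotide sequence within each
#' (patient, timepoint, subset, isotype) stratum, with `duplicate_count`
#' equal to the number of molecules (distinct UMIs) carrying it. This is
#' the table the sequencing + consensus pipeline recovers when the
#' per-base error rate is zero.
#'
#' @param sim A `CohortSim` from [simulateCohort()].
#' @return An AIRR-style data.frame with truth columns `truth_clone`.
#' @export
truthRearrangements <- function(sim) {
  stopifnot(inherits(sim, "CohortSim"))
  cells <- sim$cells
  key <- paste(cells$patient, cells$timepoint, cells$subset,
               cells$isotype, cells$sequence, sep = "\r")
  first <- !duplicated(key)
  cnt <- table(key)
  df <- cells[first, c("patient", "clone_uid", "timepoint", "subset",
                       "isotype", "sequence")]
  df$duplicate_count <- as.integer(cnt[key[first]])
  cl <- sim$clones[match(df$clone_uid, sim$clones$clone_uid), ]
  v_widths <- Biostrings::width(vSegments(sim$germline))
  names(v_widths) <- names(vSegments(sim$germline))
  vlen <- v_widths[cl$v_call]
  df$v_call <- cl$v_call
  df$j_call <- cl$j_call
  df$junction <- substr(df$sequence, vlen - 2L,
                        vlen - 3L + cl$junction_length)
  df$junction_length <- nchar(df$junction)
  df$junction_aa <- translateNt(df$junction)
  aa <- translateNt(df$sequence)
  df$productive <- !grepl("*", aa, fixed = TRUE) &
    df$junction_length %% 3L == 0L
  df$sequence_aa <- aa
  names(df)[names(df) == "clone_uid"] <- "truth_clone"
  df$sequence_id <- sprintf("S%07d", seq_len(nrow(df)))
  df$clone_id <- NA_character_
  rownames(df) <- NULL
  df[, c("sequence_id", "patient", "timepoint", "subset", "isotype",
         "sequence", "sequence_aa", "v_call", "j_call", "junction",
         "junction_aa", "junction_length", "productive",
         "duplicate_count", "clone_id", "truth_clone")]
}
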
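#' Simulate UMI-tagged paired-end amplicon reads
#'
#' Each molecule of the cohort's cell table yields one or more read
#' pairs sharing one unique molecular identifier (UMI). The amplicon is
#' the molecule's VDJ sequence followed by an 8-nt isotype
#' (constant-region) tag and an 8-nt subset barcode; mate 1 covers the
#' 5' part and mate 2 the reverse complement of the 3' part, with a
#' genuine overlap so pairs can be assembled. Sequencing errors are
#' uniform per-base substitutions applied independently to each mate.
#' UMIs are distinct across molecules.
#'
#' @param cells Molecule table from [simulateCohort()] (`sim$cells`) or
#'   a compatible data.frame with columns `molecule_id`, `sequence`,
#'   `subset`, `isotype`.
#' @param errorRate Per-base substitution probability in \[0, 0.05\].
#' @param pcrDuplication Mean read pairs per molecule (>= 1).
#' @param readFraction Fraction of the amplicon covered by each mate.
#' @param umiWidth UMI length in nt.
#' @param seed Integer seed.
#' @return data.frame with one row per read pair: `read_id`, `umi`,
#'   `truth_uid`, `mate1_seq`, `mate1_qual`, `mate2_seq`, `mate2_qual`.
#' @export
simulateReads <- function(cells, errorRate = 0.001, pcrDuplication = 3,
                          readFraction = 0.6, umiWidth = 12L, seed = NULL) {
  if (inherits(cells, "CohortSim")) cells <- cells$cells
  if (errorRate < 0 || errorRate > 0.05)
    stop("configuration error: errorRate must be in [0, 0.05]")
  if (pcrDuplication < 1)
    stop("configuration error: pcrDuplication must be >= 1")
  withSeed(seed, {
    n_mol <- nrow(cells)
    umis <- encodeDnaIndex(seq_len(n_mol), umiWidth)
    amplicon <- paste0(cells$sequence,
                       ISOTYPE_TAGS[cells$isotype],
                       SUBSET_BARCODES[cells$subset])
    copies <- 1L + rpois(n_mol, pcrDuplication - 1)
    mol_of_read <- rep(seq_len(n_mol), copies)
    la <- nchar(amplicon)[mol_of_read]
    w <- ceiling(readFraction * la)
    amp <- amplicon[mol_of_read]
    mate1 <- substr(amp, 1L, w)
    mate2 <- revComp(substr(amp, la - w + 1L, la))
    if (errorRate > 0) {
      mate1 <- vapply(mate1, mutateSeq, character(1),
                      rate = errorRate, USE.NAMES = FALSE)
      mate2 <- vapply(mate2, mutateSeq, character(1),
                      rate = errorRate, USE.NAMES = FALSE)
    }
    qual <- function(widths) vapply(widths, function(L)
      phredToString(sample(30:40, L, replace = TRUE)), character(1))
    data.frame(
      read_id = sprintf("R%08d", seq_along(mol_of_read)),
      umi = umis[mol_of_read],
      truth_uid = cells$molecule_id[mol_of_read] %||%
        as.character(mol_of_read),
      mate1_seq = mate1, mate1_qual = qual(nchar(mate1)),
      mate2_seq = mate2, mate2_qual = qual(nchar(mate2)),
      stringsAsFactors = FALSE)
  })
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' The UMI is carried in the header comment (`UMI=...`), as produced by
#' UMI-extraction preprocessing.
#'
#' @param reads data.frame from [simulateReads()]
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
writeFastqPair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  hdr <- paste0(reads$read_id, " UMI=", reads$umi)
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("mate", m, "_seq")]])
    q <- Biostrings::PhredQuality(reads[[paste0("mate", m, "_qual")]])
    x <- Biostrings::QualityScaledDNAStringSet(s, q)
    names(x) <- hdr
    Biostrings::writeQualityScaledXStringSet(x, filepath = paths[m])
  }
  invisible(paths)
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2.
#' @return data.frame with the [simulateReads()] columns (minus truth).
#' @export
readFastqPair <- function(path1, path2) {
  rd <- function(p) {
    # the reader warns that header comments are dropped from metadata;
    # we parse them from the names ourselves
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    hdr <- names(x)
    data.frame(
      read_id = sub(" .*$", "", hdr),
      umi = ifelse(grepl("UMI=", hdr),
                   sub("^.*UMI=([ACGTN]+).*$", "\\1", hdr), NA_character_),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x)),
      stringsAsFactors = FALSE)
  }
  m1 <- rd(path1); m2 <- rd(path2)
  if (!identical(m1$read_id, m2$read_id))
    stop("input error: mate files are not index-aligned by read ID")
  data.frame(read_id = m1$read_id, umi = m1$umi,
             mate1_seq = m1$seq, mate1_qual = m1$qual,
             mate2_seq = m2$seq, mate2_qual = m2$qual,
             stringsAsFactors = FALSE)
}

#' Simulate an observed serum Ig peptide table
#'
#' Draws tryptic peptides from the translated clone sequences of a
#' simulated cohort, preferentially from large and plasmablast-leaning
#' clones (antibody-secreting cells dominate serum Ig), and mixes in a
#' configurable fraction of decoy peptides that match no repertoire
#' sequence.
#'
#' @param sim A `CohortSim`, or its `clones` table.
#' @param nPerSample Peptides emitted per (patient, time point).
#' @param decoyFraction Expected fraction of decoy peptides.
#' @param seed Integer seed.
#' @return data.frame with columns `peptide_aa`, `patient`, `timepoint`,
#'   `truth_clone` (NA for decoys), `is_decoy`.
#' @export
simulateSerumPeptides <- function(sim, nPerSample = 200L,
                                  decoyFraction = 0.05, seed = NULL) {
  clones <- if (inherits(sim, "CohortSim")) sim$clones else sim
  if (is.null(clones) || nrow(clones) == 0L)
    stop("nothing to digest: empty clone set")
  withSeed(seed, {
    AA <- strsplit("ACDEFGHIKLMNQSTVWY", "")[[1]]  # no P/R/K in decoys
    out <- list()
    for (pat in unique(clones$patient)) {
      cl <- clones[clones$patient == pat, ]
      aa_all <- translateNt(cl$sequence)
      aa_cat <- paste(aa_all, collapse = "|")
      digest_cache <- new.env(parent = emptyenv())
      weights <- cl$lambda * (0.25 + cl$plasmablast)
      for (tp in TIMEPOINTS) {
        present <- vapply(strsplit(cl$persistence_class, "+", fixed = TRUE),
                          function(s) tp %in% s, logical(1))
        if (!any(present)) next
        n_decoy <- rbinom(1L, nPerSample, decoyFraction)
        n_real <- nPerSample - n_decoy
        pick <- sample(which(present), n_real, replace = TRUE,
                       prob = weights[present])
        peps <- vapply(pick, function(i) {
          key <- cl$clone_uid[i]
          frags <- if (!is.null(digest_cache[[key]])) digest_cache[[key]]
          else digest_cache[[key]] <- unique(
            trypticDigest(aa_all[i], maxMissed = 2L, minLength = 6L))
          if (length(frags) == 0L) NA_character_ else sample(frags, 1L)
        }, character(1))
        keep <- !is.na(peps)
        real <- data.frame(peptide_aa = peps[keep], patient = pat,
                           timepoint = tp,
                           truth_clone = cl$clone_uid[pick][keep],
                           is_decoy = FALSE, stringsAsFactors = FALSE)
        decoys <- character(0)
        while (length(decoys) < n_decoy) {
          cand <- paste(sample(AA, sample(8:14, 1L), replace = TRUE),
                        collapse = "")
          if (!grepl(cand, aa_cat, fixed = TRUE)) decoys <- c(decoys, cand)
        }
        dec <- if (n_decoy > 0L) data.frame(
          peptide_aa = decoys, patient = pat, timepoint = tp,
          truth_clone = NA_character_, is_decoy = TRUE,
          stringsAsFactors = FALSE) else NULL
        out[[length(out) + 1L]] <- rbind(real, dec)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
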
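#' Translate productive rearrangements and map CDR intervals
#'
#' Translates each productive record in the V reading frame and maps
#' its CDR amino-acid intervals: CDR1 and CDR2 come from the germline V
#' annotation (the V segment occupies the sequence prefix), CDR3 from
#' the junction. Intervals are 0-based half-open.
#'
#' @param rearrangements Productive, annotated records with `sequence`,
#'   `v_call`, `junction_length` (and `v_shift` if non-zero offsets
#'   were allowed).
#' @param db The [GermlineDb-class] used for annotation.
#' @return data.frame `sequence_id`, `sequence_aa`, and a `cdr` list
#'   column of integer interval matrices (rows CDR1, CDR2, CDR3).
#' @export
translateBcr <- function(rearrangements, db) {
  df <- rearrangements(rearrangements)
  if (!is.null(df$productive) && !all(df$productive))
    stop("translateBcr requires productive records only")
  vshift <- df$v_shift %||% rep(0L, nrow(df))
  L <- nchar(df$sequence)
  keep_len <- 3L * ((L - vshift) %/% 3L)
  aa <- translateNt(substr(df$sequence, vshift + 1L, vshift + keep_len))
  if (any(grepl("*", aa, fixed = TRUE)))
    stop("consistency error: internal stop codon in productive record ",
         df$sequence_id[grepl("*", aa, fixed = TRUE)][1])
  v_widths <- setNames(Biostrings::width(vSegments(db)),
                       names(vSegments(db)))
  cdr_db <- cdrRegions(db)
  cdr <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vc <- df$v_call[i]
    giv <- cdr_db[[vc]]
    giv <- giv[rownames(giv) %in% c("CDR1", "CDR2"), , drop = FALSE]
    # CDR3: junction interval; starts on the conserved cysteine, the
    # last codon of V
    cdr3_start <- as.integer(v_widths[vc] / 3L - 1L)
    cdr3 <- matrix(c(cdr3_start, cdr3_start + df$junction_length[i] %/% 3L),
                   ncol = 2, dimnames = list("CDR3", c("start", "end")))
    cdr[[i]] <- rbind(giv, cdr3)
  }
  out <- data.frame(sequence_id = df$sequence_id, sequence_aa = aa,
                    stringsAsFactors = FALSE)
  out$cdr <- cdr
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except when the next residue is P, and
#' emits every fragment with at most `maxMissed` internal missed
#' cleavages and length at least `minLength`. Fragments are returned
#' in positional order (0-missed fragments first); the concatenation of
#' the 0-missed fragments (before the length filter) reconstitutes the
#' input.
#'
#' @param aaSequence One amino-acid sequence.
#' @param maxMissed Maximum missed cleavages (default 2).
#' @param minLength Minimum peptide length (default 6).
#' @return Character vector of peptides (possibly with duplicates).
#' @examples
#' trypticDigest("AAARPAAK", 0, 1)  # proline blocks the R-P site
#' @export
trypticDigest <- function(aaSequence, maxMissed = 2L, minLength = 6L) {
  stopifnot(length(aaSequence) == 1L, nchar(aaSequence) > 0L)
  chars <- strsplit(aaSequence, "")[[1]]
  L <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < L & chars[pmin(sites + 1L, L)] != "P"]
  starts <- c(1L, sites + 1L)
  ends <- c(sites, L)
  out <- character(0)
  for (m in 0:maxMissed) {
    n_frag <- length(starts) - m
    if (n_frag < 1L) break
    for (k in seq_len(n_frag)) {
      s <- starts[k]; e <- ends[k + m]
      if (e - s + 1L >= minLength)
        out <- c(out, substr(aaSequence, s, e))
    }
  }
  out
}

.isTrypticBoundary <- function(aa, pos, len) {
  # N-term: sequence start, or preceded by K/R with no following P
  L <- nchar(aa)
  nterm <- pos == 1L ||
    (substr(aa, pos - 1L, pos - 1L) %in% c("K", "R") &&
       substr(aa, pos, pos) != "P")
  e <- pos + len - 1L
  cterm <- e == L ||
    (substr(aa, e, e) %in% c("K", "R") &&
       substr(aa, e + 1L, e + 1L) != "P")
  nterm && cterm
}

#' Match observed peptides against a translated BCR database
#'
#' A match is an exact amino-acid substring occurrence with
#' tryptic-consistent boundaries (configurable). A peptide is specific
#' when it matches exactly one distinct BCR sequence (amino-acid
#' distinct by default; clone-distinct via `uniqueLevel`) and overlaps
#' a single CDR interval by at least `minCdrOverlap` residues.
#'
#' @param peptides Character vector of observed peptide sequences.
#' @param bcrDb Output of [translateBcr()]; a `clone_id` column is
#'   required for `uniqueLevel = "clone"`.
#' @param requireTryptic Require tryptic-consistent match boundaries.
#' @param uniqueLevel Count distinct matches at the `"sequence"`
#'   (amino-acid) or `"clone"` level.
#' @param minCdrOverlap Minimum residues inside one CDR (default 3).
#' @return data.frame per peptide: `peptide_aa`, `n_distinct_matches`,
#'   `matched_sequence_ids` (`;`-collapsed), `cdr_overlap_aa`,
#'   `is_specific`, `valid`.
#' @export
matchPeptides <- function(peptides, bcrDb, requireTryptic = TRUE,
                          uniqueLevel = c("sequence", "clone"),
                          minCdrOverlap = 3L) {
  uniqueLevel <- match.arg(uniqueLevel)
  aa_vec <- bcrDb$sequence_aa
  res <- vector("list", length(peptides))
  for (pi in seq_along(peptides)) {
    pep <- peptides[pi]
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep)) {
      warning("skipping peptide with non-standard characters: ", pep)
      res[[pi]] <- data.frame(peptide_aa = pep, n_distinct_matches = 0L,
                              matched_sequence_ids = "",
                              cdr_overlap_aa = 0L, is_specific = FALSE,
                              valid = FALSE, stringsAsFactors = FALSE)
      next
    }
    plen <- nchar(pep)
    hit_rows <- integer(0)
    best_overlap <- 0L
    cand <- grep(pep, aa_vec, fixed = TRUE)
    for (ri in cand) {
      aa <- aa_vec[ri]
      pos <- gregexpr(pep, aa, fixed = TRUE)[[1]]
      pos <- pos[pos > 0L]
      if (requireTryptic)
        pos <- pos[vapply(pos, .isTrypticBoundary, logical(1),
                          aa = aa, len = plen)]
      if (length(pos) == 0L) next
      hit_rows <- c(hit_rows, ri)
      iv <- bcrDb$cdr[[ri]]
      for (p in pos) {
        ps <- p - 1L; pe <- ps + plen  # 0-based half-open
        ovl <- pmax(0L, pmin(pe, iv[, "end"]) - pmax(ps, iv[, "start"]))
        if (length(ovl) && max(ovl) > best_overlap)
          best_overlap <- max(ovl)
      }
    }
    units <- if (uniqueLevel == "sequence") aa_vec[hit_rows]
             else bcrDb$clone_id[hit_rows]
    n_distinct <- length(unique(units))
    res[[pi]] <- data.frame(
      peptide_aa = pep, n_distinct_matches = n_distinct,
      matched_sequence_ids = paste(bcrDb$sequence_id[hit_rows],
                                   collapse = ";"),
      cdr_overlap_aa = best_overlap,
      is_specific = n_distinct == 1L && best_overlap >= minCdrOverlap,
      valid = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Attribute specific peptides to time points, isotypes and subsets
#'
#' For each specific peptide, collects the time points, isotypes and
#' subsets of every rearrangement record carrying a matched sequence (a
#' peptide attributes to several time points when the clone persists),
#' plus per-(patient, peptide-library time point) specific-peptide
#' counts.
#'
#' @param matches Output of [matchPeptides()]; only specific rows are
#'   used.
#' @param rearrangements The rearrangement table the BCR database came
#'   from.
#' @param peptideMeta Optional data.frame aligned with `matches` rows
#'   carrying `patient` and `timepoint` of the peptide library.
#' @return list with `attributions` (one row per specific peptide) and
#'   `counts` (specific peptides per patient/time point, when
#'   `peptideMeta` is given).
#' @export
attributeSpecificPeptides <- function(matches, rearrangements,
                                      peptideMeta = NULL) {
  df <- rearrangements(rearrangements)
  spec <- which(matches$is_specific)
  rows <- lapply(spec, function(mi) {
    ids <- strsplit(matches$matched_sequence_ids[mi], ";")[[1]]
    ri <- match(ids, df$sequence_id)
    if (anyNA(ri))
      stop("referential integrity error: matched sequence id absent ",
           "from rearrangement table: ", ids[is.na(ri)][1])
    span <- function(vals, universe) paste(
      universe[universe %in% vals], collapse = "+")
    data.frame(
      peptide_aa = matches$peptide_aa[mi],
      patient = if (!is.null(peptideMeta)) peptideMeta$patient[mi]
                else unique(df$patient[ri])[1],
      peptide_timepoint = if (!is.null(peptideMeta))
        peptideMeta$timepoint[mi] else NA_character_,
      attributed_timepoints = span(df$timepoint[ri], TIMEPOINTS),
      attributed_isotypes = span(df$isotype[ri], ISOTYPES),
      attributed_subsets = span(df$subset[ri], SUBSETS),
      cdr_overlap_aa = matches$cdr_overlap_aa[mi],
      stringsAsFactors = FALSE)
  })
  attributions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide_aa = character(0), patient = character(0),
               peptide_timepoint = character(0),
               attributed_timepoints = character(0),
               attributed_isotypes = character(0),
               attributed_subsets = character(0),
               cdr_overlap_aa = integer(0))
  rownames(attributions) <- NULL
  counts <- NULL
  if (!is.null(peptideMeta) && nrow(attributions) > 0) {
    counts <- as.data.frame(table(
      patient = attributions$patient,
      timepoint = factor(attributions$peptide_timepoint,
                         levels = TIMEPOINTS)),
      stringsAsFactors = FALSE)
    names(counts)[names(counts) == "Freq"] <- "n_specific"
  }
  list(attributions = attributions, counts = counts)
}
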
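#' Assign V and J germline segments and junction boundaries
#'
#' A banded, gap-free semi-global assignment suitable for amplicons
#' whose reads start at the V segment 5' end: each V segment is scored
#' by Hamming identity against the sequence prefix (at codon-aligned
#' offsets up to `maxShift`), each J segment against the suffix. The
#' junction runs from the conserved cysteine codon ending the V segment
#' to the conserved tryptophan codon starting the J segment. Records
#' with best identity below `identityFloor` for either segment, or with
#' an impossible junction, are flagged unannotatable. Ties are broken
#' toward the lexicographically smaller segment name and flagged.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param db A [GermlineDb-class].
#' @param identityFloor Minimum segment identity (default 0.7).
#' @param maxShift Maximum codon-aligned 5' offset of the V segment.
#' @return data.frame with `v_call`, `j_call`, `v_identity`,
#'   `j_identity`, `v_shift`, `junction`, `junction_aa`,
#'   `junction_length`, `annotatable`, `call_tie`.
#' @export
assignGermline <- function(sequences, db, identityFloor = 0.7,
                           maxShift = 0L) {
  if (length(db) == 0L) stop("germline_db is empty")
  n <- length(sequences)
  L <- nchar(sequences)
  vset <- vSegments(db); jset <- jSegments(db)
  scoreEnd <- function(segs, side) {
    # best (identity, name) per sequence for one end of the read; the
    # fragment matrix is built once per (width, shift), then every
    # segment of that width is scored against it vectorised
    best_id <- rep(-1, n)
    best_nm <- rep(NA_character_, n)
    best_w <- rep(NA_integer_, n)
    best_sh <- rep(0L, n)
    tie <- rep(FALSE, n)
    widths <- Biostrings::width(segs)
    shifts <- if (side == "prefix") seq(0L, maxShift, by = 3L) else 0L
    for (w in sort(unique(widths))) {
      refs <- as.character(segs[widths == w])
      ref_m <- vapply(strsplit(refs, ""), identity, character(w))
      for (sh in shifts) {
        okl <- which(L >= w + sh)
        if (!length(okl)) next
        frag <- if (side == "prefix")
          substr(sequences[okl], sh + 1L, sh + w)
        else substr(sequences[okl], L[okl] - w + 1L, L[okl])
        fm <- vapply(strsplit(frag, ""), identity, character(w))
        if (is.null(dim(fm))) fm <- matrix(fm, nrow = w)
        for (si in seq_along(refs)) {
          ident <- 1 - colSums(fm != ref_m[, si]) / w
          nm <- names(refs)[si]
          better <- ident > best_id[okl] + 1e-12
          equal <- !better & abs(ident - best_id[okl]) <= 1e-12
          ib <- okl[better]
          if (length(ib)) {
            best_id[ib] <- ident[better]; best_nm[ib] <- nm
            best_w[ib] <- w; best_sh[ib] <- sh; tie[ib] <- FALSE
          }
          ie <- okl[equal]
          if (length(ie)) {
            tie[ie] <- TRUE
            swap <- ie[nm < best_nm[ie]]
            if (length(swap)) {
              best_nm[swap] <- nm; best_w[swap] <- w; best_sh[swap] <- sh
            }
          }
        }
      }
    }
    list(id = best_id, nm = best_nm, w = best_w, sh = best_sh, tie = tie)
  }
  v <- scoreEnd(vset, "prefix")
  j <- scoreEnd(jset, "suffix")
  j_start <- L - j$w + 1L
  jx_start <- v$sh + v$w - 2L
  jx_end <- j_start + 2L
  annotatable <- !is.na(v$nm) & !is.na(j$nm) &
    v$id >= identityFloor & j$id >= identityFloor &
    jx_end >= jx_start + 5L
  junction <- rep(NA_character_, n)
  junction[annotatable] <- substr(sequences[annotatable],
                                  jx_start[annotatable],
                                  jx_end[annotatable])
  jlen <- ifelse(is.na(junction), NA_integer_, nchar(junction))
  jaa <- rep(NA_character_, n)
  tr_ok <- !is.na(junction) & jlen %% 3L == 0L
  if (any(tr_ok)) jaa[tr_ok] <- translateNt(junction[tr_ok])
  data.frame(
    v_call = ifelse(annotatable, v$nm, NA_character_),
    j_call = ifelse(annotatable, j$nm, NA_character_),
    v_identity = v$id, j_identity = j$id, v_shift = v$sh,
    junction = junction, junction_aa = jaa, junction_length = jlen,
    annotatable = annotatable, call_tie = v$tie | j$tie,
    stringsAsFactors = FALSE)
}

#' Determine rearrangement productivity
#'
#' A record is productive when its junction is in frame (length
#' divisible by 3) and the translation of the V-framed coding region
#' contains no stop codon.
#'
#' @param sequences Nucleotide sequences.
#' @param junctionLength Junction lengths (nt).
#' @param vShift 5' offset of the V segment (reading frame anchor).
#' @return Logical vector.
#' @export
checkProductivity <- function(sequences, junctionLength, vShift = 0L) {
  n <- length(sequences)
  if (length(vShift) == 1L) vShift <- rep(vShift, n)
  L <- nchar(sequences)
  keep_len <- 3L * ((L - vShift) %/% 3L)
  coding <- substr(sequences, vShift + 1L, vShift + keep_len)
  aa <- translateNt(coding)
  inframe <- !is.na(junctionLength) & junctionLength %% 3L == 0L
  inframe & !grepl("*", aa, fixed = TRUE)
}

#' Annotate a consensus-sequence table against a germline database
#'
#' Runs [assignGermline()] and [checkProductivity()] over a table of
#' consensus sequences and returns an AIRR-style rearrangement table.
#' Unannotatable records are excluded (and counted in the `stepLog`
#' attribute).
#'
#' @param consensuses data.frame with a `sequence` column plus any
#'   metadata columns (patient, timepoint, subset, isotype,
#'   duplicate_count...).
#' @param db A [GermlineDb-class].
#' @inheritParams assignGermline
#' @return AIRR-style data.frame with annotation columns and
#'   `sequence_id`.
#' @export
annotateRepertoire <- function(consensuses, db, identityFloor = 0.7,
                               maxShift = 0L) {
  ann <- assignGermline(consensuses$sequence, db, identityFloor, maxShift)
  out <- cbind(consensuses[, setdiff(names(consensuses),
                                     names(ann)), drop = FALSE], ann)
  out$productive <- FALSE
  ok <- out$annotatable
  out$productive[ok] <- checkProductivity(out$sequence[ok],
                                          out$junction_length[ok],
                                          out$v_shift[ok])
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  if (is.null(res$sequence_id))
    res$sequence_id <- sprintf("S%07d", seq_len(nrow(res)))
  if (is.null(res$clone_id)) res$clone_id <- NA_character_
  attr(res, "stepLog") <- c(input = nrow(consensuses), pass = nrow(res),
                            unannotatable = sum(!ok))
  res
}

# AIRR columns written in canonical order when present
AIRR_COLUMNS <- c("sequence_id", "sequence", "v_call", "j_call",
                  "junction", "junction_aa", "junction_length",
                  "productive", "duplicate_count", "clone_id",
                  "patient", "timepoint", "subset", "isotype")

#' Read / write AIRR Rearrangement TSV
#'
#' Tab-separated, UTF-8, header row, AIRR v1 column names; `productive`
#' is serialised as `T`/`F`. Extra columns are preserved opaquely, and
#' `writeAirr` followed by `readAirr` is the identity on supported
#' columns.
#'
#' @param path TSV path.
#' @return `readAirr`: data.frame of rearrangements.
#' @export
readAirr <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = NA,
                   check.names = FALSE, na.strings = "")
  required <- c("sequence_id", "v_call", "j_call", "junction",
                "duplicate_count")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if ("productive" %in% names(df) && !is.logical(df$productive))
    df$productive <- df$productive %in% c("T", "TRUE", "true")
  for (col in c("duplicate_count", "junction_length"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  df
}

#' @rdname readAirr
#' @param records Rearrangement data.frame or [Repertoire-class].
#' @export
writeAirr <- function(records, path) {
  df <- rearrangements(records)
  lead <- intersect(AIRR_COLUMNS, names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  if ("productive" %in% names(df) && is.logical(df$productive))
    df$productive <- ifelse(df$productive, "T", "F")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
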
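#' Time-point span of every clone
#'
#' A clone's span is the exact set of time points at which it has at
#' least one member sequence; it is also its exclusive class (a clone
#' of class B+6M has no sequence at 12M). With `bySubset = TRUE` a span
#' is computed per (clone, subset): a clone may occupy different
#' classes in different subsets.
#'
#' @param rearrangements Clone-assigned table.
#' @param bySubset Compute spans per subset instead of overall.
#' @return data.frame `clone_id`, `patient` (, `subset`), `span` — the
#'   span class in canonical `"B+6M+12M"` notation.
#' @export
computeSpans <- function(rearrangements, bySubset = FALSE) {
  df <- rearrangements(rearrangements)
  df <- df[!is.na(df$clone_id), , drop = FALSE]
  if (any(is.na(df$timepoint) | df$timepoint == ""))
    stop("data error: record without timepoint: ",
         df$sequence_id[which(is.na(df$timepoint) | df$timepoint == "")[1]])
  bad_tp <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad_tp))
    stop("data error: unknown timepoint label(s): ",
         paste(bad_tp, collapse = ", "))
  keycols <- if (bySubset) c("clone_id", "subset") else "clone_id"
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  spans <- vapply(split(df$timepoint, key), function(tps)
    paste(TIMEPOINTS[TIMEPOINTS %in% tps], collapse = "+"), character(1))
  parts <- strsplit(names(spans), "\r", fixed = TRUE)
  out <- data.frame(
    clone_id = vapply(parts, `[`, character(1), 1),
    stringsAsFactors = FALSE)
  if (bySubset) out$subset <- vapply(parts, `[`, character(1), 2)
  out$patient <- df$patient[match(out$clone_id, df$clone_id)]
  out$span <- unname(spans)
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clone counts per exclusive span class
#'
#' Counts clones in each of the 7 exclusive time-point classes, per
#' patient (and per subset when `level = "per-subset"`). Classes are
#' mutually exclusive and exhaustive, so counts sum to the number of
#' clones (per subset, a clone is counted once in every subset it
#' appears in).
#'
#' @param spans Output of [computeSpans()] (with `bySubset = TRUE` for
#'   the per-subset level).
#' @param level `"all-subsets"` or `"per-subset"`.
#' @return data.frame in long form: `patient` (, `subset`), `span`,
#'   `n_clones`.
#' @export
spanClassCounts <- function(spans, level = c("all-subsets", "per-subset")) {
  level <- match.arg(level)
  if (level == "per-subset" && is.null(spans$subset))
    stop("per-subset level needs spans computed with bySubset = TRUE")
  grp <- if (level == "per-subset") list(patient = spans$patient,
                                         subset = spans$subset)
         else list(patient = spans$patient)
  tab <- table(c(grp, list(span = factor(spans$span,
                                         levels = SPAN_CLASSES))))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n_clones"
  out$span <- as.character(out$span)
  out
}

#' Span-class proportions per patient
#'
#' Fractions of clones per exclusive class. By default the denominator
#' is the clones spanning at least two time points (the four multi-
#' time-point classes), matching how overlap percentages are usually
#' quoted; `denominator = "all"` uses all clones including
#' single-time-point ones.
#'
#' @param spans Output of [computeSpans()].
#' @param denominator `"multi"` (default) or `"all"`.
#' @return data.frame `patient`, `span`, `n_clones`, `proportion`;
#'   proportions sum to 1 per patient.
#' @export
overlapProportions <- function(spans, denominator = c("multi", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(spans) == 0L)
    stop("overlap proportions undefined: zero clones")
  counts <- spanClassCounts(spans, "all-subsets")
  classes <- if (denominator == "multi")
    SPAN_CLASSES[grepl("+", SPAN_CLASSES, fixed = TRUE)] else SPAN_CLASSES
  counts <- counts[counts$span %in% classes, , drop = FALSE]
  out <- do.call(rbind, lapply(split(counts, counts$patient), function(d) {
    tot <- sum(d$n_clones)
    d$proportion <- if (tot > 0) d$n_clones / tot else NA_real_
    d
  }))
  rownames(out) <- NULL
  out
}
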
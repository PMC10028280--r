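#' Hill-number diversity of order q
#'
#' \deqn{^qD = (\sum_i p_i^q)^{1/(1-q)}}{qD = (sum p_i^q)^(1/(1-q))}
#' with the q = 1 limit \eqn{\exp(-\sum_i p_i \ln p_i)} (exponential
#' Shannon entropy). q = 0 is clone richness.
#'
#' @param abundances Positive abundance vector (normalised internally).
#' @param q Diversity order (scalar or vector).
#' @return Numeric diversity value(s).
#' @examples
#' hillNumber(rep(1, 10), 0)   # 10
#' hillNumber(c(0.9, 0.1), 1)  # exp(Shannon) ~ 1.384
#' @export
hillNumber <- function(abundances, q) {
  abundances <- abundances[!is.na(abundances) & abundances > 0]
  if (length(abundances) == 0L)
    stop("diversity undefined: empty abundance vector")
  p <- abundances / sum(abundances)
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-8) exp(-sum(p * log(p)))
    else sum(p^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' Per-sample clonal abundance
#'
#' Clone abundance is the summed `duplicate_count` (copy number) of the
#' clone's member records — copies approximate cell counts.
#'
#' @param rearrangements Clone-assigned table.
#' @return Named numeric vector of clone abundances.
#' @export
clonalAbundance <- function(rearrangements) {
  df <- rearrangements(rearrangements)
  df <- df[!is.na(df$clone_id), , drop = FALSE]
  w <- df$duplicate_count %||% rep(1L, nrow(df))
  ab <- rowsum(as.numeric(w), df$clone_id)
  setNames(ab[, 1], rownames(ab))
}

#' Bootstrap Hill diversity for one sample
#'
#' Each repetition draws `nResample` sequence records with replacement,
#' weighted by `duplicate_count`, recomputes clone abundances from the
#' draw, and evaluates the Hill number. Samples holding fewer records
#' than `nResample` copies are resampled with replacement anyway and
#' flagged.
#'
#' @param rearrangements Clone-assigned records of one sample.
#' @param q Diversity order(s).
#' @param nResample Sequences drawn per repetition (default 951).
#' @param nBoot Repetitions (default 200).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return data.frame with one row per q: `q`, `point_estimate`,
#'   `bootstrap_mean`, `bootstrap_sd`, `n_boot`, `n_resample`,
#'   `undersampled`.
#' @export
bootstrapDiversity <- function(rearrangements, q = c(0, 1),
                               nResample = 951L, nBoot = 200L,
                               seed = NULL) {
  df <- rearrangements(rearrangements)
  df <- df[!is.na(df$clone_id), , drop = FALSE]
  if (nrow(df) == 0L) stop("diversity undefined: no records")
  w <- as.numeric(df$duplicate_count %||% rep(1L, nrow(df)))
  point <- hillNumber(clonalAbundance(df), q)
  withSeed(seed, {
    boots <- matrix(NA_real_, nrow = nBoot, ncol = length(q))
    for (b in seq_len(nBoot)) {
      draw <- sample.int(nrow(df), nResample, replace = TRUE, prob = w)
      ab <- table(df$clone_id[draw])
      boots[b, ] <- hillNumber(as.numeric(ab), q)
    }
    data.frame(q = q, point_estimate = point,
               bootstrap_mean = colMeans(boots),
               bootstrap_sd = apply(boots, 2, sd),
               n_boot = nBoot, n_resample = nResample,
               undersampled = sum(w) < nResample)
  })
}

#' Bootstrap diversity across all samples of a repertoire
#'
#' @param rearrangements Clone-assigned table.
#' @param by Sample-defining columns.
#' @inheritParams bootstrapDiversity
#' @return data.frame: sample key columns plus the
#'   [bootstrapDiversity()] columns.
#' @export
diversityTable <- function(rearrangements, q = c(0, 1),
                           by = c("patient", "timepoint", "subset"),
                           nResample = 951L, nBoot = 200L, seed = NULL) {
  df <- rearrangements(rearrangements)
  by <- intersect(by, names(df))
  key <- do.call(paste, c(df[by], sep = "\r"))
  keys <- sort(unique(key))
  withSeed(seed, {
    out <- lapply(keys, function(k) {
      sub <- df[key == k, , drop = FALSE]
      if (all(is.na(sub$clone_id))) return(NULL)
      res <- bootstrapDiversity(sub, q, nResample, nBoot, seed = NULL)
      meta <- as.data.frame(as.list(setNames(
        strsplit(k, "\r", fixed = TRUE)[[1]], by)),
        stringsAsFactors = FALSE)
      cbind(meta[rep(1, nrow(res)), , drop = FALSE], res)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Percentage of expanded clones in a sample
#'
#' The percentage of clones whose number of member sequences strictly
#' exceeds `minSequences` (default 100: "more than 100 retrieved
#' sequences per clone").
#'
#' @param cloneSizes Integer vector of per-clone sequence counts.
#' @param minSequences Expansion threshold (strict inequality).
#' @return Percentage in \[0, 100\].
#' @examples
#' expandedCloneFraction(c(101, 5, 5, 5))  # 25
#' @export
expandedCloneFraction <- function(cloneSizes, minSequences = 100L) {
  if (length(cloneSizes) == 0L)
    stop("expanded-clone fraction undefined: zero clones")
  100 * sum(cloneSizes > minSequences) / length(cloneSizes)
}

#' Expanded-clone fractions per sample
#'
#' @param rearrangements Clone-assigned table.
#' @param by Sample-defining columns.
#' @param minSequences Expansion threshold.
#' @param weightBy Size measure: member sequence records
#'   (`"sequences"`) or summed copies (`"copies"`).
#' @return data.frame of per-sample percentages.
#' @export
expandedCloneTable <- function(rearrangements,
                               by = c("patient", "timepoint", "subset"),
                               minSequences = 100L,
                               weightBy = c("sequences", "copies")) {
  weightBy <- match.arg(weightBy)
  df <- rearrangements(rearrangements)
  df <- df[!is.na(df$clone_id), , drop = FALSE]
  by <- intersect(by, names(df))
  key <- do.call(paste, c(df[by], sep = "\r"))
  out <- lapply(sort(unique(key)), function(k) {
    sub <- df[key == k, , drop = FALSE]
    sizes <- if (weightBy == "sequences")
      as.vector(table(sub$clone_id))
    else as.vector(rowsum(as.numeric(
      sub$duplicate_count %||% rep(1L, nrow(sub))), sub$clone_id))
    meta <- as.data.frame(as.list(setNames(
      strsplit(k, "\r", fixed = TRUE)[[1]], by)),
      stringsAsFactors = FALSE)
    cbind(meta, data.frame(
      n_clones = length(unique(sub$clone_id)),
      expanded_pct = expandedCloneFraction(sizes, minSequences)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
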
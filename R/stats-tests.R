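#' Per-patient cohort counts for a cladribine treatment course
#'
#' Returns the bundled per-patient table of sorted B-cell numbers,
#' unique consensus sequences (>= 2 UMI representatives) and annotated
#' sequence yields for an eight-patient multiple-sclerosis cohort
#' treated with cladribine and sampled at baseline, 6 and 12 months.
#' Used as the worked example for [summarizeCohort()].
#'
#' @return data.frame with columns `patient`, `timepoint`,
#'   `sorted_cells`, `unique_sequences`, `annotated_sequences`.
#' @export
cohortCounts <- function() {
  path <- system.file("extdata", "cohort_counts.tsv",
                      package = "ClonoTrack", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$timepoint <- factor(df$timepoint, levels = TIMEPOINTS)
  df
}

#' Cohort summary table: mean and range per time point
#'
#' Arithmetic mean (rounded half-up to integer, the convention of
#' printed cohort tables) and (min, max) range of each count column,
#' per time point.
#'
#' @param samples data.frame with `timepoint` plus numeric count
#'   columns.
#' @return data.frame `timepoint`, `metric`, `mean`, `min`, `max`.
#' @examples
#' summarizeCohort(cohortCounts())
#' @export
summarizeCohort <- function(samples) {
  if (is.null(samples) || nrow(samples) == 0L) stop("empty cohort")
  metrics <- names(samples)[vapply(samples, is.numeric, logical(1))]
  tps <- if (is.factor(samples$timepoint)) levels(samples$timepoint)
         else unique(samples$timepoint)
  out <- list()
  for (tp in tps) {
    sub <- samples[samples$timepoint == tp, , drop = FALSE]
    for (m in metrics) {
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, metric = m,
        mean = roundHalfUp(mean(sub[[m]])),
        min = min(sub[[m]]), max = max(sub[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Friedman test with Dunn's multiple comparisons
#'
#' Omnibus Friedman chi-square on within-patient ranks of a complete
#' patients x conditions block design; when the omnibus p-value passes
#' `alpha`, Dunn's pairwise z-tests on mean ranks follow, with the
#' chosen p-value adjustment (Holm by default).
#'
#' @param mat Numeric matrix, rows = patients (blocks), columns =
#'   conditions (time points); complete, no missing cells.
#' @param alpha Gatekeeping level for the post hoc (default 0.05).
#' @param pAdjust `"holm"`, `"bonferroni"` or `"none"`.
#' @return list of class `ComparisonResult`: `method`, `statistic`,
#'   `p_value`, `posthoc` (data.frame or NULL), `adjust`.
#' @export
friedmanDunn <- function(mat, alpha = 0.05, pAdjust = "holm") {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing cell: patient ", bad[1], ", condition ", bad[2])
  }
  ft <- friedman.test(mat)
  stat <- unname(ft$statistic); pval <- ft$p.value
  if (is.nan(pval)) {
    # fully tied blocks: the tie-corrected statistic degenerates to 0/0;
    # there is no evidence against the null
    stat <- 0; pval <- 1
  }
  n <- nrow(mat); k <- ncol(mat)
  posthoc <- NULL
  if (pval < alpha) {
    ranks <- t(apply(mat, 1, rank))
    rbar <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(k, 2)
    z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
    p <- 2 * pnorm(-abs(z))
    cn <- colnames(mat) %||% as.character(seq_len(k))
    posthoc <- data.frame(
      group1 = cn[pairs[1, ]], group2 = cn[pairs[2, ]],
      z = unname(z), p_value = unname(p),
      p_adjusted = p.adjust(p, method = pAdjust),
      stringsAsFactors = FALSE)
  }
  structure(list(method = "friedman_dunn",
                 statistic = stat,
                 p_value = pval, posthoc = posthoc,
                 adjust = pAdjust, alpha = alpha),
            class = "ComparisonResult")
}

#' Kruskal-Wallis omnibus with gated paired Wilcoxon post hoc
#'
#' Kruskal-Wallis across the groups; when significant at `alpha`, the
#' stated pairs are compared with the Wilcoxon signed-rank test (the
#' paired test; exact p for n <= 25 without ties, normal approximation
#' above). The rank-sum (unpaired) variant is available via
#' `paired = FALSE`.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @param pairs Optional list of 2-element name vectors to compare post
#'   hoc; defaults to all pairs.
#' @param alpha Gatekeeping level.
#' @param paired Use the signed-rank (paired) test post hoc.
#' @param pAdjust p-value adjustment for the post hoc (default none,
#'   figure-asterisk style).
#' @return list of class `ComparisonResult`.
#' @export
kwThenWilcoxon <- function(groups, pairs = NULL, alpha = 0.05,
                           paired = TRUE, pAdjust = "none") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    stop("group with fewer than 2 observations: ",
         names(groups)[sizes < 2L][1])
  kw <- kruskal.test(groups)
  posthoc <- NULL
  if (kw$p.value < alpha) {
    if (is.null(pairs)) {
      cb <- utils::combn(names(groups), 2)
      pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
    }
    rows <- lapply(pairs, function(pr) {
      x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
      if (paired && length(x) <= 14) {
        sr <- .exactSignedRank(x, y)
      } else {
        wt <- suppressWarnings(wilcox.test(
          x, y, paired = paired,
          exact = if (paired) length(x) <= 25 else NULL))
        sr <- list(statistic = unname(wt$statistic),
                   p_value = wt$p.value)
      }
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = sr$statistic,
                 p_value = sr$p_value, stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
    posthoc$p_adjusted <- p.adjust(posthoc$p_value, method = pAdjust)
  }
  structure(list(method = if (paired) "kw_wilcoxon_signed_rank"
                          else "kw_wilcoxon_rank_sum",
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value, posthoc = posthoc,
                 adjust = pAdjust, alpha = alpha),
            class = "ComparisonResult")
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
# (valid with tied |differences|, where the classical exact tables are
# not); statistic V = sum of midranks of positive differences
.exactSignedRank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  p_le <- mean(sums <= v + 1e-9)
  p_ge <- mean(sums >= v - 1e-9)
  list(statistic = v, p_value = min(1, 2 * min(p_le, p_ge)))
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 4),
      ", omnibus p =", signif(x$p_value, 4), "\n")
  if (!is.null(x$posthoc)) {
    cat("post hoc (", x$adjust, " adjustment):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  } else cat("post hoc not performed (omnibus above alpha)\n")
  invisible(x)
}
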
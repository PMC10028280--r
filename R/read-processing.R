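#' Filter reads by mean base quality
#'
#' Retains read pairs whose mean Phred score is at or above the
#' threshold on both mates (single-sequence tables are filtered on
#' their one `qual` column). Order is preserved. The per-step counts
#' are attached as attribute `"stepLog"`.
#'
#' @param reads data.frame with either `mate1_qual`/`mate2_qual` or a
#'   single `qual` column (Phred+33 strings).
#' @param qThreshold Minimum mean Phred score (default 20).
#' @return The retained rows, with a `stepLog` attribute
#'   `c(input, pass, fail)`.
#' @export
filterQuality <- function(reads, qThreshold = 20) {
  stopifnot(qThreshold >= 0)
  if (all(c("mate1_qual", "mate2_qual") %in% names(reads))) {
    bad1 <- nchar(reads$mate1_qual) != nchar(reads$mate1_seq)
    bad2 <- nchar(reads$mate2_qual) != nchar(reads$mate2_seq)
    if (any(bad1 | bad2))
      stop("parse error: quality/sequence length mismatch at record ",
           which(bad1 | bad2)[1])
    keep <- meanPhred(reads$mate1_qual) >= qThreshold &
      meanPhred(reads$mate2_qual) >= qThreshold
  } else {
    if (any(nchar(reads$qual) != nchar(reads$seq)))
      stop("parse error: quality/sequence length mismatch at record ",
           which(nchar(reads$qual) != nchar(reads$seq))[1])
    keep <- meanPhred(reads$qual) >= qThreshold
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stepLog") <- c(input = nrow(reads), pass = sum(keep),
                            fail = sum(!keep))
  out
}

# best overlap assembly of one pair; returns merged seq/qual or NULL
.mergeOne <- function(s1, q1, s2rc, q2rc, minOverlap, maxMismatchRate) {
  x1 <- utf8ToInt(s1); x2 <- utf8ToInt(s2rc)
  p1 <- utf8ToInt(q1); p2 <- utf8ToInt(q2rc)
  L1 <- length(x1); L2 <- length(x2)
  if (min(L1, L2) < minOverlap) return(NULL)
  best <- NULL
  for (ov in seq(min(L1, L2), minOverlap)) {
    a <- x1[(L1 - ov + 1L):L1]
    b <- x2[1:ov]
    mm <- sum(a != b)
    if (mm <= maxMismatchRate * ov) { best <- ov; break }
  }
  if (is.null(best)) return(NULL)
  ov <- best
  head_len <- L1 - ov
  ov_i1 <- (head_len + 1L):L1
  ov_i2 <- 1:ov
  # overlap conflicts resolved toward the higher-quality base
  take2 <- p2[ov_i2] > p1[ov_i1]
  ov_seq <- x1[ov_i1]; ov_seq[take2] <- x2[ov_i2][take2]
  ov_q <- pmax(p1[ov_i1], p2[ov_i2])
  tail_i <- if (ov < L2) (ov + 1L):L2 else integer(0)
  list(seq = intToUtf8(c(x1[seq_len(head_len)], ov_seq, x2[tail_i])),
       qual = intToUtf8(c(p1[seq_len(head_len)], ov_q, p2[tail_i])))
}

#' Pair mates by read ID and assemble full-length amplicons
#'
#' Mates are matched by `read_id`; orphans are dropped and counted.
#' Assembly finds the longest 3' overlap between mate 1 and the reverse
#' complement of mate 2 whose mismatch rate is below `maxMismatchRate`;
#' conflicting overlap bases take the higher-quality call. Pairs with
#' no acceptable overlap are dropped and counted.
#'
#' @param mate1,mate2 data.frames with `read_id`, `seq`, `qual` (and
#'   optionally `umi`), or a single combined data.frame with
#'   `mate1_seq`/`mate2_seq` columns in place of `mate2`.
#' @param minOverlap Minimum acceptable overlap (nt).
#' @param maxMismatchRate Maximum mismatch fraction within the overlap.
#' @return data.frame of merged reads (`read_id`, `umi`, `seq`, `qual`)
#'   with a `stepLog` attribute counting orphans and failed merges.
#' @export
pairAndMerge <- function(mate1, mate2 = NULL, minOverlap = 10L,
                         maxMismatchRate = 0.1) {
  if (is.null(mate2)) {
    pairs <- mate1
  } else {
    common <- intersect(mate1$read_id, mate2$read_id)
    n_orphan <- (nrow(mate1) - length(common)) +
      (nrow(mate2) - length(common))
    i1 <- match(common, mate1$read_id); i2 <- match(common, mate2$read_id)
    pairs <- data.frame(read_id = common,
                        umi = mate1$umi[i1] %||% NA_character_,
                        mate1_seq = mate1$seq[i1],
                        mate1_qual = mate1$qual[i1],
                        mate2_seq = mate2$seq[i2],
                        mate2_qual = mate2$qual[i2],
                        stringsAsFactors = FALSE)
  }
  if (is.null(mate2)) n_orphan <- 0L
  s2rc <- revComp(pairs$mate2_seq)
  q2rc <- vapply(pairs$mate2_qual, function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  merged <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    merged[[i]] <- .mergeOne(pairs$mate1_seq[i], pairs$mate1_qual[i],
                             s2rc[i], q2rc[i], minOverlap, maxMismatchRate)
  }
  ok <- !vapply(merged, is.null, logical(1))
  out <- data.frame(
    read_id = pairs$read_id[ok],
    umi = (pairs$umi %||% rep(NA_character_, nrow(pairs)))[ok],
    seq = vapply(merged[ok], `[[`, character(1), "seq"),
    qual = vapply(merged[ok], `[[`, character(1), "qual"),
    stringsAsFactors = FALSE)
  attr(out, "stepLog") <- c(input = nrow(pairs) + n_orphan,
                            pass = sum(ok),
                            orphan = n_orphan, merge_fail = sum(!ok))
  out
}

#' Demultiplex merged reads by constant-region tags
#'
#' The amplicon 3' end carries an 8-nt isotype (constant-region) tag
#' followed by an 8-nt subset barcode. Both are looked up with a
#' configurable mismatch tolerance; reads whose best hit is ambiguous
#' or beyond tolerance go to the `undetermined` bin. Matching reads are
#' returned with the tags trimmed.
#'
#' @param reads data.frame with `seq` (and optionally `qual`) columns.
#' @param barcodes Named subset barcode table (default the package's
#'   `SUBSET_BARCODES`).
#' @param isotypeTags Named isotype tag table (default `ISOTYPE_TAGS`).
#' @param maxMismatch Mismatch tolerance per tag (default 1).
#' @return list with `assigned` (rows + `subset`, `isotype`, trimmed
#'   `seq`/`qual`), `undetermined` (unmodified rows) and `log`.
#' @export
demultiplex <- function(reads, barcodes = SUBSET_BARCODES,
                        isotypeTags = ISOTYPE_TAGS, maxMismatch = 1L) {
  if (anyDuplicated(barcodes) || anyDuplicated(isotypeTags))
    stop("configuration error: duplicate barcode definitions")
  bw <- unique(nchar(barcodes)); iw <- unique(nchar(isotypeTags))
  if (length(bw) != 1L || length(iw) != 1L)
    stop("configuration error: tags within a table must share one width")
  lookup <- function(words, table) {
    tbl_m <- vapply(strsplit(table, ""), identity,
                    character(nchar(table[1])))
    res_lab <- rep(NA_character_, length(words))
    wm <- vapply(strsplit(words, ""), identity,
                 character(nchar(table[1])))
    if (is.null(dim(wm))) wm <- matrix(wm, ncol = length(words))
    for (i in seq_along(words)) {
      d <- colSums(wm[, i] != tbl_m)
      hits <- which(d == min(d))
      if (min(d) <= maxMismatch && length(hits) == 1L)
        res_lab[i] <- names(table)[hits]
    }
    res_lab
  }
  L <- nchar(reads$seq)
  ok_len <- L >= bw + iw + 1L
  bc <- substr(reads$seq, L - bw + 1L, L)
  it <- substr(reads$seq, L - bw - iw + 1L, L - bw)
  subset <- isotype <- rep(NA_character_, nrow(reads))
  subset[ok_len] <- lookup(bc[ok_len], barcodes)
  isotype[ok_len] <- lookup(it[ok_len], isotypeTags)
  assigned_i <- !is.na(subset) & !is.na(isotype)
  assigned <- reads[assigned_i, , drop = FALSE]
  assigned$subset <- subset[assigned_i]
  assigned$isotype <- isotype[assigned_i]
  trim_to <- (L - bw - iw)[assigned_i]
  assigned$seq <- substr(assigned$seq, 1L, trim_to)
  if (!is.null(assigned$qual))
    assigned$qual <- substr(assigned$qual, 1L, trim_to)
  rownames(assigned) <- NULL
  undet <- reads[!assigned_i, , drop = FALSE]
  rownames(undet) <- NULL
  list(assigned = assigned, undetermined = undet,
       log = c(input = nrow(reads), pass = sum(assigned_i),
               undetermined = sum(!assigned_i)))
}

#' Build a position-wise majority consensus for one UMI group
#'
#' Members of discordant length are first restricted to the modal
#' length. The group is rejected when fewer than `minReads` members
#' remain or when the mean per-read mismatch rate against the consensus
#' exceeds `maxError`. Base ties are resolved by the higher summed
#' quality, then alphabetically, so the consensus is deterministic and
#' independent of read order.
#'
#' @param group data.frame with `seq` and `qual` for one UMI group.
#' @param maxError Maximum mean per-read mismatch rate (default 0.1).
#' @param minReads Minimum reads required (default 2).
#' @return list with `sequence`, `umiCountSupport`, `errorRate`,
#'   `rejected` (FALSE or a reason code string).
#' @export
buildConsensus <- function(group, maxError = 0.1, minReads = 2L) {
  if (nrow(group) == 0L) stop("empty UMI group")
  lens <- nchar(group$seq)
  modal <- as.integer(names(which.max(table(lens))))
  use <- which(lens == modal)
  if (length(use) < minReads)
    return(list(sequence = NA_character_, umiCountSupport = length(use),
                errorRate = NA_real_,
                rejected = if (length(use) < nrow(group))
                  "length_discordant" else "too_few_reads"))
  m <- vapply(strsplit(group$seq[use], ""), identity, character(modal))
  if (is.null(dim(m))) m <- matrix(m, nrow = modal)
  qm <- vapply(group$qual[use], function(q) utf8ToInt(q) - 33L,
               integer(modal), USE.NAMES = FALSE)
  if (is.null(dim(qm))) qm <- matrix(qm, nrow = modal)
  cons <- character(modal)
  for (p in seq_len(modal)) {
    bases <- m[p, ]
    u <- unique(bases)
    if (length(u) == 1L) { cons[p] <- u; next }
    cnt <- tabulate(match(bases, u))
    top <- u[cnt == max(cnt)]
    if (length(top) > 1L) {
      qsum <- vapply(top, function(b) sum(qm[p, bases == b]), numeric(1))
      top <- sort(top[qsum == max(qsum)])[1]
    }
    cons[p] <- top
  }
  consensus <- paste(cons, collapse = "")
  err <- mean(colSums(m != cons) / modal)
  if (err > maxError)
    return(list(sequence = NA_character_, umiCountSupport = length(use),
                errorRate = err, rejected = "error_rate"))
  list(sequence = consensus, umiCountSupport = length(use),
       errorRate = err, rejected = FALSE)
}

#' Build consensus sequences for all UMI groups of a sample
#'
#' Groups reads by UMI (subset/isotype labels are resolved by majority
#' within the group) and applies [buildConsensus()] to each.
#'
#' @param reads data.frame with `umi`, `seq`, `qual` and optionally
#'   `subset`, `isotype` columns.
#' @inheritParams buildConsensus
#' @return data.frame of consensus records (`umi`, `sequence`,
#'   `umi_count_support`, `subset`, `isotype`) with a `stepLog`
#'   attribute including per-reason rejection counts.
#' @export
consensusFromReads <- function(reads, maxError = 0.1, minReads = 2L) {
  groups <- split(seq_len(nrow(reads)), reads$umi)
  rows <- vector("list", length(groups))
  reasons <- character(0)
  majority <- function(x) names(which.max(table(x)))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    res <- buildConsensus(reads[idx, , drop = FALSE], maxError, minReads)
    if (!isFALSE(res$rejected)) {
      reasons <- c(reasons, res$rejected)
      next
    }
    rows[[gi]] <- data.frame(
      umi = names(groups)[gi], sequence = res$sequence,
      umi_count_support = res$umiCountSupport,
      subset = if (!is.null(reads$subset)) majority(reads$subset[idx])
               else NA_character_,
      isotype = if (!is.null(reads$isotype)) majority(reads$isotype[idx])
                else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(umi = character(0), sequence = character(0),
                      umi_count_support = integer(0),
                      subset = character(0), isotype = character(0))
  rownames(out) <- NULL
  lg <- c(input = length(groups), pass = nrow(out),
          fail = length(groups) - nrow(out))
  for (r in unique(reasons)) lg[paste0("fail_", r)] <- sum(reasons == r)
  attr(out, "stepLog") <- lg
  out
}

#' Collapse identical consensus sequences into copy counts
#'
#' Within each stratum (by default patient, time point, subset and
#' isotype, restricted to the columns present), records with identical
#' nucleotide sequence are collapsed into one, with `duplicate_count`
#' equal to the number of collapsed records — i.e. the number of
#' identical sequences observed under distinct UMIs.
#'
#' @param consensuses data.frame with a `sequence` column.
#' @param strata Columns defining the collapse stratum.
#' @return Collapsed data.frame with `duplicate_count`; the sum of
#'   `duplicate_count` equals the number of input records.
#' @export
collapseDuplicates <- function(consensuses,
                               strata = c("patient", "timepoint",
                                          "subset", "isotype")) {
  strata <- intersect(strata, names(consensuses))
  key <- do.call(paste, c(consensuses[c(strata, "sequence")], sep = "\r"))
  first <- !duplicated(key)
  cnt <- table(key)
  out <- consensuses[first, , drop = FALSE]
  out$duplicate_count <- as.integer(cnt[key[first]])
  rownames(out) <- NULL
  attr(out, "stepLog") <- c(input = nrow(consensuses), pass = nrow(out))
  out
}
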
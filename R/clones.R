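#' Partition rearrangements into clone-candidate groups
#'
#' Groups records by patient, V gene, J gene (allele suffixes stripped;
#' for ambiguous comma-separated calls the first listed gene is used
#' and flagged) and junction length — the first two parts of the clone
#' definition. Records lacking a V or J call are routed to an
#' "ungrouped" bin.
#'
#' @param rearrangements data.frame or [Repertoire-class] with
#'   `patient`, `v_call`, `j_call`, `junction`, `junction_length`.
#' @return list with `groups` (named list of row-index vectors),
#'   `ungrouped` (row indices) and `ambiguous_calls` (count).
#' @export
partitionRearrangements <- function(rearrangements) {
  df <- rearrangements(rearrangements)
  v_raw <- df$v_call; j_raw <- df$j_call
  ungrouped <- which(is.na(v_raw) | is.na(j_raw))
  ok <- setdiff(seq_len(nrow(df)), ungrouped)
  ambiguous <- grepl(",", v_raw[ok]) | grepl(",", j_raw[ok])
  v_gene <- geneOf(sub(",.*$", "", v_raw[ok]))
  j_gene <- geneOf(sub(",.*$", "", j_raw[ok]))
  key <- paste(df$patient[ok], v_gene, j_gene, df$junction_length[ok],
               sep = "|")
  groups <- split(ok, key)
  list(groups = groups, ungrouped = ungrouped,
       ambiguous_calls = sum(ambiguous))
}

#' Single-linkage CDR3 identity clustering within one group
#'
#' All junctions must share one length L. Sequences are linked when
#' their nucleotide identity (1 - mismatches/L) is at least
#' `minIdentity` (inclusive at the boundary); clusters are the
#' single-linkage closure of the link relation, computed by cutting a
#' single-linkage dendrogram on integer mismatch distances.
#'
#' @param junctions Character vector of equal-length junction
#'   sequences.
#' @param minIdentity Identity threshold (default 0.88).
#' @return Integer cluster labels (1-based, order-independent up to
#'   relabeling).
#' @export
clusterGroup <- function(junctions, minIdentity = 0.88) {
  n <- length(junctions)
  if (n == 0L) return(integer(0))
  L <- unique(nchar(junctions))
  if (length(L) != 1L)
    stop("all junctions in a group must share one length")
  if (L == 0L) {
    warning("zero-length junctions: each sequence its own clone")
    return(seq_len(n))
  }
  uj <- unique(junctions)
  if (length(uj) == 1L) return(rep(1L, n))
  mmax <- floor((1 - minIdentity) * L + 1e-9)
  d <- hammingMatrix(uj)
  hc <- hclust(as.dist(d), method = "single")
  lab_u <- cutree(hc, h = mmax + 0.5)
  unname(lab_u[match(junctions, uj)])
}

#' Assign clone identifiers across a repertoire
#'
#' Pools all time points and subsets within each patient, partitions by
#' (patient, V gene, J gene, junction length), clusters each group at
#' `minIdentity` CDR3 nucleotide identity, and writes deterministic
#' clone labels (`<patient>_C<number>`, numbered by sorted group key
#' and representative junction, so output is independent of record
#' order). Clone identifiers are never shared across patients.
#'
#' Records are expected to be productive and annotated; rows without
#' V/J calls keep `clone_id = NA`.
#'
#' @param rearrangements data.frame or [Repertoire-class].
#' @param minIdentity CDR3 identity threshold (default 0.88).
#' @return The input table with `clone_id` filled (a `Repertoire` input
#'   returns a `Repertoire`).
#' @export
assignCloneIds <- function(rearrangements, minIdentity = 0.88) {
  is_rep <- is(rearrangements, "Repertoire")
  df <- rearrangements(rearrangements)
  part <- partitionRearrangements(df)
  df$clone_id <- NA_character_
  # cluster every group, then label clusters in sorted-key order
  per_patient <- new.env(parent = emptyenv())
  keys <- sort(names(part$groups))
  for (key in keys) {
    idx <- part$groups[[key]]
    labs <- clusterGroup(df$junction[idx], minIdentity)
    pat <- df$patient[idx[1]]
    # deterministic cluster order: by smallest member junction
    reps <- vapply(split(df$junction[idx], labs), min, character(1))
    ord <- order(reps)
    relab <- match(labs, as.integer(names(reps)[ord]))
    base <- per_patient[[pat]] %||% 0L
    df$clone_id[idx] <- sprintf("%s_C%04d", pat, base + relab)
    per_patient[[pat]] <- base + length(reps)
  }
  attr(df, "ungrouped") <- length(part$ungrouped)
  if (is_rep) {
    rearrangements@rearrangements <- df
    rearrangements
  } else df
}

#' Summarise clones
#'
#' @param rearrangements Clone-assigned table from [assignCloneIds()].
#' @return data.frame with one row per clone: `clone_id`, `patient`,
#'   `v_gene`, `j_gene`, `junction_length`, `size_sequences`,
#'   `size_copies`, `samples_present`.
#' @export
cloneSummary <- function(rearrangements) {
  df <- rearrangements(rearrangements)
  df <- df[!is.na(df$clone_id), , drop = FALSE]
  sp <- split(seq_len(nrow(df)), df$clone_id)
  res <- lapply(names(sp), function(cid) {
    i <- sp[[cid]]
    data.frame(
      clone_id = cid, patient = df$patient[i[1]],
      v_gene = geneOf(sub(",.*$", "", df$v_call[i[1]])),
      j_gene = geneOf(sub(",.*$", "", df$j_call[i[1]])),
      junction_length = df$junction_length[i[1]],
      size_sequences = length(i),
      size_copies = sum(df$duplicate_count[i] %||% rep(1L, length(i))),
      samples_present = paste(sort(unique(
        paste(df$timepoint[i], df$subset[i], sep = ":"))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
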
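#' GermlineDb: a reference set of V and J germline segments
#'
#' Holds germline V and J nucleotide segments together with the
#' amino-acid coordinates of their complementarity-determining regions
#' (CDRs) on the translated segment. V segments end on the conserved
#' CDR3 cysteine codon; J segments begin on the conserved tryptophan
#' codon, so the junction between them is well defined.
#'
#' @slot segments A [Biostrings::DNAStringSet] of germline sequences,
#'   named by segment (allele-level names such as `"IGHV1-1*01"`).
#' @slot kind Character vector, `"V"` or `"J"`, one per segment.
#' @slot cdrAA Named list of integer matrices with columns `start`,
#'   `end`: 0-based half-open amino-acid intervals on the translated
#'   segment (CDR1, CDR2 and the CDR3-proximal cysteine for V segments;
#'   empty matrix for J segments).
#'
#' @aliases GermlineDb-class
#' @exportClass GermlineDb
setClass("GermlineDb",
  representation(
    segments = "DNAStringSet",
    kind = "character",
    cdrAA = "list"))

setValidity("GermlineDb", function(object) {
  msg <- character(0)
  n <- length(object@segments)
  if (n == 0L) msg <- c(msg, "no segments")
  if (length(object@kind) != n)
    msg <- c(msg, "kind length does not match segments")
  if (!all(object@kind %in% c("V", "J")))
    msg <- c(msg, "kind must be 'V' or 'J'")
  if (is.null(names(object@segments)) || anyDuplicated(names(object@segments)))
    msg <- c(msg, "segments must have unique names")
  af <- Biostrings::alphabetFrequency(object@segments, baseOnly = TRUE)
  if (n > 0 && any(af[, "other"] > 0))
    msg <- c(msg, "segment sequences must be over {A,C,G,T}")
  if (length(object@cdrAA) != n)
    msg <- c(msg, "cdrAA length does not match segments")
  for (i in seq_len(n)) {
    iv <- object@cdrAA[[i]]
    if (nrow(iv) == 0L) next
    aa_len <- Biostrings::width(object@segments)[i] %/% 3L
    if (any(iv[, "start"] >= iv[, "end"]) || any(iv[, "end"] > aa_len))
      msg <- c(msg, sprintf("CDR intervals out of range for segment %d", i))
    if (nrow(iv) > 1L && any(iv[-1L, "start"] < iv[-nrow(iv), "end"]))
      msg <- c(msg, sprintf("CDR intervals overlap for segment %d", i))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GermlineDb Number of segments
#' @param x,object A `GermlineDb`
#' @export
setMethod("length", "GermlineDb", function(x) length(x@segments))

#' @describeIn GermlineDb Compact display
#' @export
setMethod("show", "GermlineDb", function(object) {
  cat("GermlineDb with", sum(object@kind == "V"), "V and",
      sum(object@kind == "J"), "J segments\n")
  cat("  V widths:", paste(unique(Biostrings::width(
    object@segments[object@kind == "V"])), collapse = ","), "nt;",
    "J widths:", paste(unique(Biostrings::width(
      object@segments[object@kind == "J"])), collapse = ","), "nt\n")
})

#' Extract V or J segments from a GermlineDb
#'
#' @param db A `GermlineDb`
#' @return A named [Biostrings::DNAStringSet]
#' @export
vSegments <- function(db) db@segments[db@kind == "V"]

#' @rdname vSegments
#' @export
jSegments <- function(db) db@segments[db@kind == "J"]

#' @rdname vSegments
#' @export
cdrRegions <- function(db) db@cdrAA

#' Repertoire: an annotated rearrangement table with provenance
#'
#' A light S4 container around an AIRR-style rearrangement data.frame,
#' tracking which processing stages have run. Most analysis functions
#' accept either a `Repertoire` or a bare data.frame with the same
#' columns.
#'
#' @slot rearrangements data.frame of AIRR-style records (one row per
#'   unique consensus sequence per sample).
#' @slot processLog list of per-stage record counts.
#'
#' @aliases Repertoire-class
#' @exportClass Repertoire
setClass("Repertoire",
  representation(
    rearrangements = "data.frame",
    processLog = "list"))

setValidity("Repertoire", function(object) {
  req <- c("sequence_id", "patient", "timepoint", "subset")
  miss <- setdiff(req, names(object@rearrangements))
  if (length(miss))
    return(paste("missing rearrangement columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@rearrangements$sequence_id))
    return("sequence_id values must be unique")
  TRUE
})

#' Construct a Repertoire from a rearrangement table
#' @param rearrangements data.frame of rearrangement records
#' @param processLog optional list of per-stage counts
#' @return A `Repertoire`
#' @export
Repertoire <- function(rearrangements, processLog = list()) {
  new("Repertoire", rearrangements = rearrangements, processLog = processLog)
}

#' Access the rearrangement table of a Repertoire
#' @param x A `Repertoire` or data.frame (returned as is)
#' @return data.frame
#' @export
rearrangements <- function(x) {
  if (is(x, "Repertoire")) x@rearrangements else as.data.frame(x)
}

#' @describeIn Repertoire Number of rearrangement records
#' @param x,object A `Repertoire`
#' @export
setMethod("length", "Repertoire", function(x) nrow(x@rearrangements))

#' @describeIn Repertoire Compact display
#' @export
setMethod("show", "Repertoire", function(object) {
  df <- object@rearrangements
  cat("Repertoire:", nrow(df), "rearrangements,",
      length(unique(df$patient)), "patient(s)\n")
  if ("clone_id" %in% names(df) && any(!is.na(df$clone_id)))
    cat("  clones assigned:", length(unique(df$clone_id[!is.na(df$clone_id)])),
        "\n")
  else cat("  clones not yet assigned\n")
})
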
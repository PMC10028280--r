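#' Generate a toy germline V/J segment database
#'
#' Builds a reproducible set of artificial IGH V and J germline segments
#' for simulation and testing. V families are mutually distinguishable
#' (pairwise nucleotide identity below 90%); alleles within a family
#' differ by a handful of codon substitutions. Every V segment is
#' in-frame and stop-free and ends on the conserved CDR3 cysteine codon
#' (TGC); every J segment starts on the conserved tryptophan codon
#' (TGG), so junction boundaries are well defined by construction.
#'
#' @param nVFamilies Number of V families (>= 2).
#' @param nJ Number of J segments (>= 1).
#' @param nAllelesPerFamily Alleles per V family (default 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param vCodons,jCodons Segment lengths in codons.
#' @return A [GermlineDb-class] object.
#' @examples
#' db <- generateGermlineDb(5, 6, nAllelesPerFamily = 2, seed = 7)
#' length(db)  # 16 segments
#' @export
generateGermlineDb <- function(nVFamilies, nJ, nAllelesPerFamily = 1L,
                               seed = NULL, vCodons = 60L, jCodons = 16L) {
  if (!is.numeric(nVFamilies) || nVFamilies < 2)
    stop("configuration error: nVFamilies must be >= 2")
  if (!is.numeric(nJ) || nJ < 1)
    stop("configuration error: nJ must be >= 1")
  if (nAllelesPerFamily < 1)
    stop("configuration error: nAllelesPerFamily must be >= 1")
  withSeed(seed, {
    v_cdr <- cbind(start = c(24L, 44L, vCodons - 1L),
                   end = c(32L, 52L, vCodons))
    rownames(v_cdr) <- c("CDR1", "CDR2", "CDR3prox")
    fam_bases <- character(0)
    for (f in seq_len(nVFamilies)) {
      repeat {
        cand <- paste0(randSenseCodons(vCodons - 1L), "TGC")
        ok <- all(vapply(fam_bases, function(b)
          pairIdentity(cand, b) < 0.90, logical(1)))
        if (ok) break
      }
      fam_bases <- c(fam_bases, cand)
    }
    v_seqs <- character(0); v_names <- character(0)
    for (f in seq_len(nVFamilies)) {
      for (a in seq_len(nAllelesPerFamily)) {
        s <- fam_bases[f]
        if (a > 1L) {
          # allele = family base with a few codon substitutions away from
          # the conserved terminal cysteine
          n_sub <- 4L
          pos <- sample(seq_len(vCodons - 1L), n_sub)
          chars <- substring(s, 3 * (seq_len(vCodons) - 1) + 1,
                             3 * seq_len(vCodons))
          for (p in pos) chars[p] <- sample(
            setdiff(SENSE_CODONS, chars[p]), 1L)
          s <- paste(chars, collapse = "")
        }
        v_seqs <- c(v_seqs, s)
        v_names <- c(v_names, sprintf("IGHV%d-1*%02d", f, a))
      }
    }
    j_seqs <- character(0)
    for (j in seq_len(nJ)) {
      repeat {
        cand <- paste0("TGG", randSenseCodons(jCodons - 1L))
        ok <- all(vapply(j_seqs, function(b)
          pairIdentity(cand, b) < 0.90, logical(1)))
        if (ok) break
      }
      j_seqs <- c(j_seqs, cand)
    }
    j_names <- sprintf("IGHJ%d*01", seq_len(nJ))
    segs <- Biostrings::DNAStringSet(c(v_seqs, j_seqs))
    names(segs) <- c(v_names, j_names)
    empty <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    cdrs <- c(rep(list(v_cdr), length(v_seqs)),
              rep(list(empty), length(j_seqs)))
    names(cdrs) <- names(segs)
    new("GermlineDb", segments = segs,
        kind = c(rep("V", length(v_seqs)), rep("J", length(j_seqs))),
        cdrAA = cdrs)
  })
}

#' Write a GermlineDb to FASTA
#' @param db A [GermlineDb-class]
#' @param path Output FASTA path
#' @return `path`, invisibly
#' @export
writeGermlineFasta <- function(db, path) {
  Biostrings::writeXStringSet(db@segments, filepath = path)
  invisible(path)
}
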
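#' @import methods
#' @importFrom stats rpois runif rbinom rmultinom rgamma setNames aggregate
#'   friedman.test kruskal.test wilcox.test p.adjust pnorm as.dist hclust
#'   cutree sd quantile
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons, used wherever an in-frame, stop-free stretch is needed
SENSE_CODONS <- local({
  all <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
})

TIMEPOINTS <- c("B", "6M", "12M")
SUBSETS <- c("naive", "memory", "DN", "plasmablast")
ISOTYPES <- c("IgM", "IgD", "IgG", "IgA")

# the 7 possible non-empty time-point span classes, canonical order
SPAN_CLASSES <- c("B", "6M", "12M", "B+6M", "B+12M", "6M+12M", "B+6M+12M")

# constant-region tags: pairwise Hamming distance 8, so 1-mismatch
# correction is unambiguous
SUBSET_BARCODES <- c(
  naive = "AAAACCCC", memory = "CCCCGGGG",
  DN = "GGGGTTTT", plasmablast = "TTTTAAAA")
ISOTYPE_TAGS <- c(
  IgM = "ACACACAC", IgD = "GTGTGTGT", IgG = "CACACACA", IgA = "TGTGTGTG")

randDna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
    character(1))
}

randSenseCodons <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Round half away from zero to integer (printed-table convention)
#' @param x numeric vector
#' @return integer-valued numeric
#' @keywords internal
roundHalfUp <- function(x) floor(x + 0.5)

translateNt <- function(nt) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt), if.fuzzy.codon = "X"))
}

revComp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}

# per-read mean Phred scores from Phred+33 quality strings
meanPhred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

phredToString <- function(scores) {
  intToUtf8(pmin(scores, 93L) + 33L)
}

# Hamming mismatch count between equal-length strings and one reference
hammingToRef <- function(strings, ref) {
  m <- vapply(strsplit(strings, ""), identity,
              character(nchar(ref)))
  r <- strsplit(ref, "")[[1]]
  if (is.null(dim(m))) m <- matrix(m, nrow = length(r))
  colSums(m != r)
}

# pairwise Hamming mismatch matrix for equal-length strings
hammingMatrix <- function(strings) {
  x <- Biostrings::DNAStringSet(strings)
  as.matrix(Biostrings::stringDist(x, method = "hamming"))
}

# fraction identity between two sequences over their full (equal) length
pairIdentity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  1 - hammingToRef(a, b) / nchar(a)
}

# strip the allele suffix from a V/J call: IGHV3-2*02 -> IGHV3-2
geneOf <- function(call) sub("\\*.*$", "", call)

# encode integer i as a fixed-width DNA word (base-4 digits); distinct i
# give distinct words, which gives collision-free UMIs
encodeDnaIndex <- function(i, width) {
  vapply(i, function(k) {
    digits <- integer(width)
    for (p in seq_len(width)) {
      digits[p] <- k %% 4L
      k <- k %/% 4L
    }
    paste(DNA_BASES[digits + 1L], collapse = "")
  }, character(1))
}

# alternative bases for each base, for substitution draws
ALT_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))

# apply uniform per-base substitutions at rate `rate` to one sequence
mutateSeq <- function(seq, rate) {
  L <- nchar(seq)
  n_mut <- rbinom(1L, L, rate)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(L, n_mut)
  for (p in pos) {
    substr(seq, p, p) <- ALT_BASES[[substr(seq, p, p)]][sample.int(3L, 1L)]
  }
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
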
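mk_reads <- function(seqs, quals) {
  data.frame(read_id = sprintf("R%03d", seq_along(seqs)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

test_that("quality filter keeps reads by mean Phred with order preserved", {
  q30 <- strrep(rawToChar(as.raw(30 + 33)), 10)
  q10 <- strrep(rawToChar(as.raw(10 + 33)), 10)
  reads <- mk_reads(rep(strrep("A", 10), 4), c(q30, q30, q10, q30))
  all_pass <- filterQuality(mk_reads(rep(strrep("A", 10), 3), rep(q30, 3)), 20)
  expect_equal(nrow(all_pass), 3)
  none <- filterQuality(mk_reads(rep(strrep("A", 10), 3), rep(q10, 3)), 20)
  expect_equal(nrow(none), 0)
  # mixed set equals an independent per-read mean recomputation
  mixed_quals <- vapply(1:30, function(i)
    intToUtf8(sample(5:40, 12, replace = TRUE) + 33), character(1))
  mixed <- mk_reads(rep(strrep("C", 12), 30), mixed_quals)
  got <- filterQuality(mixed, 20)
  want <- vapply(mixed_quals, function(q)
    mean(utf8ToInt(q) - 33) >= 20, logical(1))
  expect_identical(got$read_id, mixed$read_id[want])
  expect_equal(unname(attr(got, "stepLog")["fail"]), sum(!want))
})

test_that("malformed records are reported with their index", {
  bad <- mk_reads(c("ACGT", "ACGT"), c("IIII", "III"))
  expect_error(filterQuality(bad), "record 2")
})

test_that("pairing drops orphans and zero-error merging recovers the molecule", {
  cells <- fix_sim$cells[1:20, ]
  reads <- simulateReads(cells, errorRate = 0, pcrDuplication = 1, seed = 21)
  m1 <- data.frame(read_id = reads$read_id, seq = reads$mate1_seq,
                   qual = reads$mate1_qual, umi = reads$umi)
  m2 <- data.frame(read_id = reads$read_id, seq = reads$mate2_seq,
                   qual = reads$mate2_qual)
  merged <- pairAndMerge(m1, m2)
  expect_equal(unname(attr(merged, "stepLog")["orphan"]), 0)
  expect_equal(nrow(merged), nrow(reads))
  # merged sequence equals the true amplicon (sequence + tags)
  truth <- paste0(cells$sequence,
                  ClonoTrack:::ISOTYPE_TAGS[cells$isotype],
                  ClonoTrack:::SUBSET_BARCODES[cells$subset])
  expect_identical(merged$seq,
                   truth[match(reads$truth_uid, cells$molecule_id)])

  # one orphan mate -> exactly one drop logged
  merged2 <- pairAndMerge(m1, m2[-3, ])
  expect_equal(unname(attr(merged2, "stepLog")["orphan"]), 1)
  expect_equal(nrow(merged2), nrow(reads) - 1)
})

test_that("demultiplexing resolves barcodes within tolerance and trims tags", {
  body <- strrep("ACGT", 30)
  mk <- function(iso, sub) paste0(body, iso, sub)
  bc <- ClonoTrack:::SUBSET_BARCODES
  it <- ClonoTrack:::ISOTYPE_TAGS
  reads <- data.frame(seq = c(
    mk(it[["IgG"]], bc[["memory"]]),
    mk(it[["IgM"]], sub("A", "C", bc[["naive"]])),       # 1 mismatch: ok
    mk(it[["IgA"]], sub("AAAA", "CCGG", bc[["naive"]]))  # beyond tolerance
  ), stringsAsFactors = FALSE)
  res <- demultiplex(reads, maxMismatch = 1)
  expect_equal(res$assigned$subset, c("memory", "naive"))
  expect_equal(res$assigned$isotype, c("IgG", "IgM"))
  expect_true(all(res$assigned$seq == body))
  expect_equal(nrow(res$undetermined), 1)
  expect_error(demultiplex(reads, barcodes = c(a = "AAAA", b = "AAAA")),
               "duplicate")
})

test_that("per-subset demultiplexed counts equal generator truth at zero error", {
  cells <- fix_sim$cells[1:60, ]
  reads <- simulateReads(cells, errorRate = 0, pcrDuplication = 1, seed = 22)
  merged <- pairAndMerge(data.frame(read_id = reads$read_id,
                                    seq = reads$mate1_seq,
                                    qual = reads$mate1_qual,
                                    umi = reads$umi),
                         data.frame(read_id = reads$read_id,
                                    seq = reads$mate2_seq,
                                    qual = reads$mate2_qual))
  res <- demultiplex(merged)
  got <- table(res$assigned$subset)
  want <- table(cells$subset)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
})

test_that("UMI consensus follows majority with documented rejections", {
  reads3 <- data.frame(seq = rep("ACGTACGTAC", 3),
                       qual = rep(strrep("I", 10), 3))
  r <- buildConsensus(reads3)
  expect_false(isTRUE(r$rejected != FALSE))
  expect_equal(r$sequence, "ACGTACGTAC")
  expect_equal(r$errorRate, 0)

  one <- buildConsensus(reads3[1, , drop = FALSE], minReads = 2)
  expect_equal(one$rejected, "too_few_reads")

  # 10 reads, one disagreeing base in one read: consensus = majority,
  # mean mismatch rate = (1/L)/10
  L <- 10
  seqs <- rep(strrep("A", L), 10)
  seqs[4] <- paste0("C", strrep("A", L - 1))
  g <- data.frame(seq = seqs, qual = rep(strrep("I", L), 10))
  r10 <- buildConsensus(g, maxError = 0.1)
  expect_equal(r10$sequence, strrep("A", L))
  expect_equal(r10$errorRate, (1 / L) / 10)
  expect_false(isTRUE(r10$rejected != FALSE))

  # beyond the error ceiling -> rejected
  noisy <- data.frame(seq = c("AAAA", "CCCC", "GGGG"),
                      qual = rep("IIII", 3))
  expect_equal(buildConsensus(noisy, maxError = 0.1)$rejected, "error_rate")
})

test_that("consensus is invariant to read order within a group", {
  set.seed(31)
  seqs <- c(rep("ACGTAACCGG", 4), "ACGTAACCGT")
  quals <- replicate(5, intToUtf8(sample(30:40, 10, TRUE) + 33))
  g <- data.frame(seq = seqs, qual = quals)
  ref <- buildConsensus(g)
  for (i in 1:5) {
    p <- sample(5)
    expect_identical(buildConsensus(g[p, ], maxError = 0.2)$sequence,
                     ref$sequence)
  }
})

test_that("duplicate collapsing conserves record counts within strata", {
  cons <- data.frame(
    patient = "P01", timepoint = "B",
    subset = c(rep("memory", 5), "naive", "naive"),
    isotype = "IgG",
    sequence = c(rep("AAAA", 5), "AAAA", "CCCC"),
    umi = sprintf("U%02d", 1:7), stringsAsFactors = FALSE)
  out <- collapseDuplicates(cons)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$duplicate_count), nrow(cons))
  expect_equal(out$duplicate_count[out$subset == "memory"], 5)
  # all distinct -> counts all 1
  dis <- within(cons, sequence <- sprintf("AC%05d", 1:7))
  expect_true(all(collapseDuplicates(dis)$duplicate_count == 1))
})

test_that("zero-error pipeline recovers the truth molecule set exactly", {
  cells <- fix_sim$cells[fix_sim$cells$patient == "P01" &
                           fix_sim$cells$timepoint == "B", ][1:80, ]
  reads <- simulateReads(cells, errorRate = 0, pcrDuplication = 4, seed = 23)
  fq <- filterQuality(reads)
  merged <- pairAndMerge(fq)
  dmx <- demultiplex(merged)
  cons <- consensusFromReads(dmx$assigned, minReads = 2)
  # duplication 4 virtually guarantees >= 2 reads per molecule here;
  # compare recovered molecule multiset against truth for kept UMIs
  truth_of_umi <- cells$sequence[match(
    reads$truth_uid[match(cons$umi, reads$umi)], cells$molecule_id)]
  expect_identical(cons$sequence, truth_of_umi)
  expect_identical(cons$subset, cells$subset[match(
    reads$truth_uid[match(cons$umi, reads$umi)], cells$molecule_id)])
})
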
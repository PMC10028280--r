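test_that("germline generation is deterministic and segments are distinguishable", {
  a <- generateGermlineDb(5, 6, nAllelesPerFamily = 2, seed = 7)
  b <- generateGermlineDb(5, 6, nAllelesPerFamily = 2, seed = 7)
  expect_equal(length(a), 16)
  expect_identical(as.character(a@segments), as.character(b@segments))
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  writeGermlineFasta(a, f1); writeGermlineFasta(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  small <- generateGermlineDb(2, 1, seed = 1)
  expect_equal(length(small), 3)
  vs <- as.character(vSegments(small))
  # distinct families stay below 90% identity (brute-force comparison)
  expect_lt(1 - oracle_mismatches(vs[1], vs[2]) / nchar(vs[1]), 0.90)

  expect_error(generateGermlineDb(1, 1, seed = 1), "configuration error")
})

test_that("V segments end on cysteine and J segments start on tryptophan", {
  vs <- vSegments(fix_db); js <- jSegments(fix_db)
  expect_true(all(substr(as.character(vs), Biostrings::width(vs) - 2,
                         Biostrings::width(vs)) %in% c("TGC", "TGT")))
  expect_true(all(substr(as.character(js), 1, 3) == "TGG"))
})

test_that("clone-size draws follow the configured truncated power law", {
  set.seed(5)
  x <- ClonoTrack:::rPowerLaw(2000, 1.5, 1000)
  ks <- suppressWarnings(stats::ks.test(
    x, function(q) ClonoTrack:::pPowerLaw(q, 1.5, 1000)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(x >= 1 & x <= 1000))
})

test_that("persistence classes are realised exactly and frequencies recover", {
  # degenerate distribution: every clone spans all three time points
  probs <- setNames(c(0, 0, 0, 0, 0, 0, 1),
                    c("B", "6M", "12M", "B+6M", "B+12M", "6M+12M",
                      "B+6M+12M"))
  sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 40,
                                     sizeCap = 10,
                                     persistenceProbs = probs),
                        seed = 2)
  tps <- tapply(sim$cells$timepoint, sim$cells$clone_uid,
                function(x) paste(sort(unique(x)), collapse = ","))
  expect_true(all(tps == "12M,6M,B"))

  # configured multi-class frequencies recover within 3 binomial SEs
  probs2 <- setNames(c(0, 0, 0, 0.02, 0.12, 0.26, 0.60), names(probs))
  sim2 <- simulateCohort(cohortConfig(nPatients = 1, nClones = 2000,
                                      sizeCap = 10, shmRate = 0,
                                      persistenceProbs = probs2),
                         seed = 3)
  freq <- table(factor(sim2$clones$persistence_class,
                       names(probs2))) / 2000
  for (cl in names(probs2)[probs2 > 0]) {
    se <- sqrt(probs2[cl] * (1 - probs2[cl]) / 2000)
    expect_lt(abs(freq[cl] - probs2[cl]), 3 * se)
  }
})

test_that("abundance is zero exactly outside the persistence class", {
  cl <- fix_sim$clones
  cells <- fix_sim$cells
  for (i in sample(nrow(cl), 25)) {
    tps <- sort(unique(cells$timepoint[cells$clone_uid == cl$clone_uid[i]]))
    want <- sort(strsplit(cl$persistence_class[i], "+", fixed = TRUE)[[1]])
    expect_identical(tps, want)
  }
})

test_that("memory depletion reduces memory clone counts by the configured factor", {
  mem_count <- function(sim, tp) {
    cells <- sim$cells
    length(unique(cells$clone_uid[cells$subset == "memory" &
                                    cells$timepoint == tp]))
  }
  # null scenario: expected memory clone count equal across time points
  probs <- setNames(c(0, 0, 0, 0, 0, 0, 1), names(cohortConfig()$persistenceProbs))
  null_counts <- sapply(1:6, function(s) {
    sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 250,
                                       sizeCap = 30, shmRate = 0,
                                       memoryDepletion = 1,
                                       persistenceProbs = probs), seed = s)
    c(B = mem_count(sim, "B"), M6 = mem_count(sim, "6M"))
  })
  expect_lt(abs(mean(null_counts["B", ] / null_counts["M6", ]) - 1), 0.1)

  dep_counts <- sapply(1:6, function(s) {
    sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 250,
                                       sizeCap = 30, shmRate = 0,
                                       memoryDepletion = 3,
                                       persistenceProbs = probs), seed = s)
    c(B = mem_count(sim, "B"), M6 = mem_count(sim, "6M"))
  })
  ratio <- mean(dep_counts["B", ]) / mean(dep_counts["M6", ])
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 3.8)
})

test_that("bad scenario configurations are rejected", {
  expect_error(cohortConfig(persistenceProbs = rep(0.2, 7)),
               "sum to 1")
  expect_error(cohortConfig(memoryDepletion = 0.5), "configuration error")
  expect_error(cohortConfig(subsetBaseWeights = c(naive = 1, memory = 1,
                                                  DN = 0, plasmablast = 0)),
               "sum to 1")
})

test_that("simulated reads respect UMI grouping and error rate", {
  cells <- fix_sim$cells[1:40, ]
  # duplication 1 -> exactly one UMI group per molecule
  r1 <- simulateReads(cells, errorRate = 0, pcrDuplication = 1, seed = 4)
  expect_equal(length(unique(r1$umi)), nrow(cells))
  # zero error -> all reads of a UMI group identical
  r3 <- simulateReads(cells, errorRate = 0, pcrDuplication = 3, seed = 4)
  per_umi <- tapply(r3$mate1_seq, r3$umi, function(x) length(unique(x)))
  expect_true(all(per_umi == 1))
  # error rate recovers within binomial error
  rate <- 0.01
  re <- simulateReads(cells, errorRate = rate, pcrDuplication = 2, seed = 9)
  r0 <- simulateReads(cells, errorRate = 0, pcrDuplication = 2, seed = 9)
  expect_identical(re$read_id, r0$read_id)
  mm <- sum(mapply(oracle_mismatches, re$mate1_seq, r0$mate1_seq))
  n_bases <- sum(nchar(r0$mate1_seq))
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(mm / n_bases - rate), 4 * se)
})

test_that("FASTQ round trip preserves reads and UMIs", {
  reads <- simulateReads(fix_sim$cells[1:15, ], errorRate = 0.001,
                         pcrDuplication = 2, seed = 6)
  pre <- tempfile()
  writeFastqPair(reads, pre)
  back <- readFastqPair(paste0(pre, "_R1.fastq"), paste0(pre, "_R2.fastq"))
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$umi, reads$umi)
  expect_identical(back$mate1_seq, reads$mate1_seq)
  expect_identical(back$mate2_qual, reads$mate2_qual)
})

test_that("serum peptides come from the repertoire except configured decoys", {
  pep0 <- simulateSerumPeptides(fix_sim, nPerSample = 40,
                                decoyFraction = 0, seed = 12)
  aa_cat <- paste(vapply(
    fix_sim$clones$sequence,
    function(s) as.character(Biostrings::translate(Biostrings::DNAString(s))),
    character(1)), collapse = "|")
  expect_true(all(vapply(pep0$peptide_aa, grepl, logical(1),
                         x = aa_cat, fixed = TRUE)))
  expect_false(any(pep0$is_decoy))

  pep5 <- simulateSerumPeptides(fix_sim, nPerSample = 100,
                                decoyFraction = 0.5, seed = 13)
  n <- nrow(pep5)
  frac <- mean(pep5$is_decoy)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))
  # decoys never occur in the repertoire
  expect_false(any(vapply(pep5$peptide_aa[pep5$is_decoy], grepl, logical(1),
                          x = aa_cat, fixed = TRUE)))

  expect_error(simulateSerumPeptides(fix_sim$clones[0, ]), "nothing to digest")
})

test_that("fixed seeds give byte-identical simulator output", {
  s1 <- simulateCohort(cohortConfig(nPatients = 1, nClones = 30,
                                    sizeCap = 10), seed = 77)
  s2 <- simulateCohort(cohortConfig(nPatients = 1, nClones = 30,
                                    sizeCap = 10), seed = 77)
  expect_identical(s1$clones, s2$clones)
  expect_identical(s1$cells, s2$cells)
  p1 <- simulateSerumPeptides(s1, nPerSample = 20, seed = 8)
  p2 <- simulateSerumPeptides(s2, nPerSample = 20, seed = 8)
  expect_identical(p1, p2)
})
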
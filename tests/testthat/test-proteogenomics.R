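test_that("translation maps the junction into amino-acid coordinates", {
  sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 20,
                                     sizeCap = 5, shmRate = 0), seed = 71)
  tr <- truthRearrangements(sim)
  bdb <- translateBcr(tr, sim$germline)
  # translated sequence equals the generator's translated truth
  expect_identical(bdb$sequence_aa, tr$sequence_aa)
  for (i in 1:5) {
    iv <- bdb$cdr[[i]]
    cdr3 <- substr(bdb$sequence_aa[i], iv["CDR3", "start"] + 1,
                   iv["CDR3", "end"])
    expect_identical(cdr3, tr$junction_aa[i])
    # CDR3 starts on the conserved cysteine
    expect_identical(substr(cdr3, 1, 1), "C")
    expect_identical(substr(cdr3, nchar(cdr3), nchar(cdr3)), "W")
  }
  # unproductive record -> error
  tr2 <- tr; tr2$productive[1] <- FALSE
  expect_error(translateBcr(tr2, sim$germline), "productive")
})

test_that("tryptic digestion enumerates cleavage products correctly", {
  # hand-enumerated fragments of AAAK|BBBR|CCC (B = placeholder residue)
  frags0 <- trypticDigest("AAAKBBBRCCC", maxMissed = 0, minLength = 1)
  expect_identical(frags0, c("AAAK", "BBBR", "CCC"))
  frags1 <- trypticDigest("AAAKBBBRCCC", maxMissed = 1, minLength = 1)
  expect_setequal(frags1, c("AAAK", "BBBR", "CCC", "AAAKBBBR", "BBBRCCC"))
  expect_setequal(trypticDigest("AAAKBBBRCCC", maxMissed = 1,
                                minLength = 6),
                  c("AAAKBBBR", "BBBRCCC"))
  # proline blocks cleavage after R
  expect_identical(trypticDigest("AAARPAAK", 0, 1), "AAARPAAK")
  # no cleavage sites: whole sequence iff long enough
  expect_identical(trypticDigest("ACDEFG", 0, 6), "ACDEFG")
  expect_length(trypticDigest("ACDEF", 0, 6), 0)
})

test_that("0-missed fragments reconstitute the protein", {
  set.seed(72)
  for (i in 1:1000) {
    aa <- random_protein(sample(20:120, 1))
    expect_identical(paste(trypticDigest(aa, 0, 1), collapse = ""), aa)
  }
})

test_that("peptide specificity enforces both filter clauses", {
  mkdb <- function(seqs, cdr_list) {
    df <- data.frame(sequence_id = sprintf("b%d", seq_along(seqs)),
                     sequence_aa = seqs, stringsAsFactors = FALSE)
    df$cdr <- cdr_list
    df
  }
  iv <- function(s, e) matrix(c(s, e), ncol = 2,
                              dimnames = list("CDR3", c("start", "end")))
  # one sequence, peptide sits 5 residues inside the CDR -> specific
  db1 <- mkdb("AAAKCCCCCWWWKDDDD", list(iv(4, 10)))
  m1 <- matchPeptides("CCCCCWWWK", db1)
  expect_true(m1$is_specific)
  expect_equal(m1$cdr_overlap_aa, 6)
  # same peptide in two distinct sequences -> not specific
  db2 <- mkdb(c("AAAKCCCCCWWWKDDDD", "EEEKCCCCCWWWKFFFF"),
              list(iv(4, 10), iv(4, 10)))
  expect_false(matchPeptides("CCCCCWWWK", db2)$is_specific)
  # CDR overlap of 2 residues only -> not specific
  db3 <- mkdb("AAAKCCCCCWWWKDDDD", list(iv(4, 6)))
  expect_false(matchPeptides("CCCCCWWWK", db3)$is_specific)
  expect_equal(matchPeptides("CCCCCWWWK", db3)$cdr_overlap_aa, 2)
  # decoy -> zero matches
  expect_equal(matchPeptides("YYYYYYYY", db1)$n_distinct_matches, 0)
  # non-standard characters are skipped with a warning
  expect_warning(out <- matchPeptides("CCB1X", db1), "non-standard")
  expect_false(out$valid)
})

test_that("matches require tryptic-consistent boundaries", {
  db <- data.frame(sequence_id = "b1", sequence_aa = "AAAKCCCCCWWWKDDDD",
                   stringsAsFactors = FALSE)
  db$cdr <- list(matrix(c(0, 17), ncol = 2,
                        dimnames = list("CDR3", c("start", "end"))))
  # internal fragment without a preceding K/R is rejected...
  expect_equal(matchPeptides("CCCCWWWK", db)$n_distinct_matches, 0)
  # ...unless tryptic consistency is disabled
  expect_equal(matchPeptides("CCCCWWWK", db,
                             requireTryptic = FALSE)$n_distinct_matches, 1)
})

test_that("specificity can only be lost when the database grows", {
  set.seed(73)
  sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 60,
                                     sizeCap = 5), seed = 74)
  tr <- truthRearrangements(sim)
  rep <- assignCloneIds(tr[tr$productive, ])
  bdb <- translateBcr(rep, sim$germline)
  half <- bdb[seq_len(nrow(bdb) %/% 2), ]
  peps <- simulateSerumPeptides(sim, nPerSample = 30, decoyFraction = 0.1,
                                seed = 75)$peptide_aa
  m_small <- matchPeptides(peps, half)
  m_full <- matchPeptides(peps, bdb)
  # specific in the full db implies specific in the subset db whenever
  # the peptide matched there at all
  gained <- m_full$is_specific & !m_small$is_specific &
    m_small$n_distinct_matches > 0
  expect_false(any(gained))
})

test_that("matcher equals a brute-force substring scan on small inputs", {
  set.seed(76)
  sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 40,
                                     sizeCap = 4), seed = 77)
  tr <- truthRearrangements(sim)
  bdb <- translateBcr(tr, sim$germline)
  bdb <- bdb[seq_len(min(100, nrow(bdb))), ]
  peps <- unique(simulateSerumPeptides(sim, nPerSample = 25,
                                       decoyFraction = 0.2,
                                       seed = 78)$peptide_aa)
  got <- matchPeptides(peps, bdb, requireTryptic = FALSE)
  for (i in seq_along(peps)) {
    brute <- sum(!duplicated(bdb$sequence_aa[
      vapply(bdb$sequence_aa, function(s)
        grepl(peps[i], s, fixed = TRUE), logical(1))]))
    expect_equal(got$n_distinct_matches[i], brute)
  }
})

test_that("specific peptides attribute to their clone's true time points", {
  sim <- simulateCohort(cohortConfig(nPatients = 1, nClones = 80,
                                     sizeCap = 20), seed = 79)
  tr <- truthRearrangements(sim)
  rep <- assignCloneIds(tr[tr$productive, ])
  bdb <- translateBcr(rep, sim$germline)
  peps <- simulateSerumPeptides(sim, nPerSample = 120, decoyFraction = 0.1,
                                seed = 80)
  mm <- matchPeptides(peps$peptide_aa, bdb)
  att <- attributeSpecificPeptides(mm, rep, peptideMeta = peps)
  a <- att$attributions
  expect_gt(nrow(a), 0)
  # every attributed time point lies in the generator clone's class
  truth_class <- fix <- sim$clones$persistence_class[
    match(peps$truth_clone[match(a$peptide_aa, peps$peptide_aa)],
          sim$clones$clone_uid)]
  ok <- vapply(seq_len(nrow(a)), function(i) {
    if (is.na(truth_class[i])) return(NA)
    got <- strsplit(a$attributed_timepoints[i], "+", fixed = TRUE)[[1]]
    want <- strsplit(truth_class[i], "+", fixed = TRUE)[[1]]
    all(got %in% want)
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
  # referential integrity is enforced
  expect_error(attributeSpecificPeptides(mm, rep[1:2, ], peps),
               "referential")
})
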
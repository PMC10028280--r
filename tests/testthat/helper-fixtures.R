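# shared fixtures, built once per test run

fix_db <- generateGermlineDb(3, 2, nAllelesPerFamily = 2, seed = 11)

fix_sim <- simulateCohort(
  cohortConfig(nPatients = 2, nClones = 100, sizeCap = 30), seed = 101)

fix_truth <- truthRearrangements(fix_sim)

fix_rep <- assignCloneIds(fix_truth[fix_truth$productive, ])

# ---- independent oracles (kept free of package internals) ----

# mismatch count by direct character comparison
oracle_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# connected components of the thresholded identity graph by
# breadth-first search over an explicit adjacency matrix
oracle_components <- function(junctions, min_identity) {
  n <- length(junctions)
  L <- nchar(junctions[1])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ident <- 1 - oracle_mismatches(junctions[i], junctions[j]) / L
    adj[i, j] <- ident >= min_identity
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# two labelings describe the same partition iff their contingency
# table has exactly one nonzero cell per row and per column
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

random_junctions <- function(n, L, n_templates = 2) {
  templates <- vapply(seq_len(n_templates), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  vapply(seq_len(n), function(i) {
    s <- strsplit(sample(templates, 1), "")[[1]]
    k <- sample(0:max(1, round(0.2 * L)), 1)
    if (k > 0) {
      pos <- sample(L, k)
      s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
}

random_protein <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
               replace = TRUE), collapse = "")
}
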
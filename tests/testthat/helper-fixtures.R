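# fixtures and independent oracles shared across test files

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# one gapless pairwise alignment block, texts taken verbatim
pw_block <- function(qasm, qchrom, qstart, tasm, tchrom, tstart, qtext, ttext,
                     tstrand = "+") {
  qlen <- nchar(gsub("-", "", qtext)); tlen <- nchar(gsub("-", "", ttext))
  list(query = genomic_interval(qasm, qchrom, qstart, qstart + qlen),
       target = genomic_interval(tasm, tchrom, tstart, tstart + tlen, tstrand),
       qtext = qtext, ttext = ttext)
}

pw_aln <- function(..., qasm = "A", tasm = "B") {
  structure(list(blocks = list(...), query_assembly = qasm,
                 target_assembly = tasm), class = "pairwise_alignment")
}

# brute-force per-column coordinate table of a gapped alignment block:
# walks the two gapped texts one column at a time
oracle_column_table <- function(qstart, tstart, qtext, ttext) {
  qc <- strsplit(qtext, "")[[1]]; tc <- strsplit(ttext, "")[[1]]
  qp <- qstart - 1; tp <- tstart - 1
  rows <- list()
  for (i in seq_along(qc)) {
    if (qc[i] != "-") qp <- qp + 1
    if (tc[i] != "-") tp <- tp + 1
    rows[[i]] <- data.frame(col = i,
                            qpos = if (qc[i] != "-") qp else NA,
                            tpos = if (tc[i] != "-") tp else NA)
  }
  do.call(rbind, rows)
}

# brute-force pruning likelihood: sum over all internal-node state
# assignments (trees <= 5 leaves)
oracle_tree_likelihood <- function(column, tree, model, scale = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (ntip + 1):nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    prob_matrix(model, tree$edge.length[k] * scale))
  root <- tree$edge[nrow(tree$edge), 1]
  obs <- match(toupper(column[tree$tip.label]), c("A", "C", "G", "T"))
  # enumerate states of internal nodes and of missing-data leaves
  free <- c(internal, which(is.na(obs)))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(free))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    states <- integer(nnode)
    states[seq_len(ntip)] <- obs
    states[free] <- grid[g, ]
    pr <- model$pi[states[root]]
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * P[[k]][states[tree$edge[k, 1]], states[tree$edge[k, 2]]]
    total <- total + pr
  }
  unname(total)
}

# brute-force exhaustive forward probability of the 2-state HMM over all
# state paths (n <= 12 columns)
oracle_hmm_loglik <- function(emis, csm) {
  n <- nrow(emis)
  A <- matrix(c(1 - csm$nu, csm$nu, csm$mu, 1 - csm$mu), 2, 2, byrow = TRUE)
  init <- c(1 - csm$coverage, csm$coverage)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    pr <- init[s[1]] * emis[1, s[1]]
    if (n > 1) for (t in 2:n) pr <- pr * A[s[t - 1], s[t]] * emis[t, s[t]]
    total <- total + pr
  }
  log(total)
}

# O(n*m) brute-force maximal exact match scan via the full match matrix
oracle_exact_hits <- function(seq_a, seq_b, min_n) {
  scan_one <- function(a, b, strand, nb_fwd) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    masked_a <- ac %in% letters; masked_b <- bc %in% letters
    M <- outer(toupper(ac), toupper(bc), "==")
    M[masked_a, ] <- FALSE; M[, masked_b] <- FALSE
    na <- length(ac); nb <- length(bc)
    out <- list()
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      if (!M[i, j]) next
      if (i > 1 && j > 1 && M[i - 1, j - 1]) next    # not a run start
      len <- 0
      while (i + len <= na && j + len <= nb && M[i + len, j + len]) len <- len + 1
      if (len < min_n) next
      if (strand == "+") {
        out[[length(out) + 1L]] <- data.frame(
          a_start = i - 1L, a_end = i + len - 1L,
          b_start = j - 1L, b_end = j + len - 1L, strand = "+")
      } else {
        out[[length(out) + 1L]] <- data.frame(
          a_start = i - 1L, a_end = i + len - 1L,
          b_start = nb_fwd - (j + len - 1L), b_end = nb_fwd - j + 1L,
          strand = "-")
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  nb_fwd <- nchar(seq_b)
  res <- rbind(scan_one(seq_a, seq_b, "+", nb_fwd),
               scan_one(seq_a, revcomp(seq_b), "-", nb_fwd))
  if (is.null(res)) return(res)
  res <- res[order(res$a_start, res$b_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# memoized synthetic bundle + pipeline shared by the heavier tests
.shared <- new.env()
shared_bundle <- function() {
  if (is.null(.shared$bundle))
    .shared$bundle <- generate_study(simulation_config(seed = 20240915))
  .shared$bundle
}
shared_pipeline <- function() {
  if (is.null(.shared$pipe)) .shared$pipe <- run_pipeline(shared_bundle())
  .shared$pipe
}

# reciprocal-overlap recall of truth elements against a called set
recall_reciprocal <- function(called, truth, min_ro = 0.8) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(called) == 0L) return(FALSE)
    ov <- pmax(pmin(called$end, truth$end[i]) - pmax(called$start, truth$start[i]), 0)
    ro <- ov / pmax(called$end - called$start, truth$end[i] - truth$start[i])
    any(ro >= min_ro & called$chrom == truth$chrom[i])
  }, TRUE)
  mean(hit)
}
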
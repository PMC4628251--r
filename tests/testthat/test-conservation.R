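# pruning likelihoods, neutral-model fitting, the two-state HMM,
# and overlap resolution

test_that("pruning likelihood equals hand/brute-force values", {
  m <- subst_model("JC69")
  # single leaf observed A: likelihood = pi_A
  tr1 <- ape::read.tree(text = "(a:0);")
  expect_equal(prune_likelihood(c(a = "A"), neutral_model(tr1, m)), 0.25)
  # two leaves A,A at total d = 0.2: brute-force sum over 4 root states
  tr2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  lik <- prune_likelihood(c(a = "A", b = "A"), neutral_model(tr2, m))
  brute <- sum(0.25 * prob_matrix(m, 0.1)[, 1] * prob_matrix(m, 0.1)[, 1])
  expect_equal(lik, brute, tolerance = 1e-12)
  # all leaves missing: full marginalization
  expect_equal(prune_likelihood(c(a = "-", b = "N"), neutral_model(tr2, m)), 1)
  expect_error(prune_likelihood(c(zz = "A"), neutral_model(tr2, m)), "unknown leaf")
})

test_that("pruning equals internal-state enumeration on random <=5-leaf trees", {
  set.seed(301)
  for (rep in 1:8) {
    ntip <- sample(3:5, 1)
    tr <- ape::rtree(ntip, br = function(n) runif(n, 0.05, 0.6))
    tr$tip.label <- paste0("t", seq_len(ntip))
    model <- if (rep %% 2) subst_model("JC69") else
      subst_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3), kappa = 3)
    nm <- neutral_model(tr, model)
    col <- setNames(sample(c("A", "C", "G", "T", "-"), ntip, TRUE),
                    tr$tip.label)
    if (all(col == "-")) col[1] <- "A"
    scale <- sample(c(0.3, 1), 1)
    expect_equal(prune_likelihood(col, nm, scale),
                 oracle_tree_likelihood(col, tr, model, scale),
                 tolerance = 1e-10)
  }
})

test_that("HKY85 transition probabilities are valid and reversible", {
  m <- subst_model("HKY85", pi = c(0.4, 0.1, 0.2, 0.3), kappa = 4)
  P <- prob_matrix(m, 0.35)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(P >= 0))
  # detailed balance: pi_i P_ij = pi_j P_ji
  F <- diag(m$pi) %*% P
  expect_equal(F, t(F), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(prob_matrix(m, 0), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fit_neutral recovers branch lengths (JC closed-form oracle)", {
  set.seed(302)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  n <- 50000
  ev <- evolve_on_tree(rand_dna(n), tr, subst_model("JC69"))
  chars <- rbind(a = strsplit(ev$leaves[["a"]], "")[[1]],
                 b = strsplit(ev$leaves[["b"]], "")[[1]])
  fit <- fit_neutral(chars, tr, family = "JC69")
  total <- sum(fit$tree$edge.length)
  # JC distance oracle: d_hat = -3/4 log(1 - 4/3 p_hat), SE by delta method
  p_hat <- mean(chars[1, ] != chars[2, ])
  d_hat <- -0.75 * log(1 - 4 * p_hat / 3)
  se <- sqrt(p_hat * (1 - p_hat) / n) / (1 - 4 * p_hat / 3)
  expect_lt(abs(total - 0.2), 3 * se + abs(d_hat - 0.2))
  expect_error(fit_neutral(chars[, 1:100], tr), "columns")
})

test_that("fit_neutral hits the zero boundary on identical columns", {
  chars <- rbind(a = rep("A", 600), b = rep("A", 600))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expect_warning(fit <- fit_neutral(chars, tr, family = "JC69"), "boundary")
  expect_true(all(fit$tree$edge.length <= 1e-6))
})

test_that("conserved-state model transition parameterization", {
  csm <- conserved_state_model(rho = 0.3, expected_length = 45, coverage = 0.3)
  expect_equal(csm$mu, 1 / 45)
  expect_equal(csm$nu, (1 / 45) * 0.3 / 0.7)
  expect_error(conserved_state_model(rho = 1.2), "rho")
})

test_that("forward probability equals exhaustive path enumeration (<=10 cols)", {
  set.seed(303)
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,c:0.3);")
  nm <- neutral_model(tr, subst_model("JC69"))
  csm <- conserved_state_model()
  for (ncol in c(4, 10)) {
    txt <- vapply(1:3, function(i) rand_dna(ncol), "")
    block <- data.frame(species = c("a", "b", "c"), chrom = "chr1", start = 0,
                        size = ncol, strand = "+", src_size = 1000, text = txt,
                        stringsAsFactors = FALSE)
    maf <- structure(list(blocks = list(block), reference = "a"),
                     class = "maf_alignment")
    seg <- segment_conserved(maf, nm, csm, min_ecr_length = 1)
    emis <- cbind(
      vapply(seq_len(ncol), function(j) prune_likelihood(
        setNames(substring(txt, j, j), c("a", "b", "c")), nm, 1), 0),
      vapply(seq_len(ncol), function(j) prune_likelihood(
        setNames(substring(txt, j, j), c("a", "b", "c")), nm, csm$rho), 0))
    expect_equal(seg$tracks[[1]]$loglik, oracle_hmm_loglik(emis, csm),
                 tolerance = 1e-10)
  }
})

test_that("posteriors sum to one and a planted block is recovered", {
  set.seed(304)
  tr <- ape::read.tree(text = "((a:0.25,b:0.25):0.1,(c:0.3,d:0.3):0.05);")
  sp <- tr$tip.label
  nm <- neutral_model(tr, subst_model("JC69"))
  # columns 100-199 identical across species, the rest independent random
  ident <- rand_dna(100)
  rows <- vapply(sp, function(s)
    paste0(rand_dna(100), ident, rand_dna(100)), "")
  block <- data.frame(species = sp, chrom = "chr1", start = 0, size = 300,
                      strand = "+", src_size = 300, text = rows,
                      stringsAsFactors = FALSE)
  maf <- structure(list(blocks = list(block), reference = sp[1]),
                   class = "maf_alignment")
  seg <- segment_conserved(maf, nm, conserved_state_model())
  post <- seg$tracks[[1]]$posterior
  expect_true(all(abs(post + (1 - post) - 1) < 1e-9))
  expect_equal(nrow(seg$ecrs), 1)
  expect_lt(abs(seg$ecrs$start - 100), 6)
  expect_lt(abs(seg$ecrs$end - 200), 6)
  expect_gt(seg$ecrs$score, 0.9)
})

test_that("neutral alignments yield no conserved calls", {
  tr <- ape::read.tree(text = "((a:0.25,b:0.25):0.1,(c:0.3,d:0.3):0.05);")
  nm <- neutral_model(tr, subst_model("JC69"))
  n_called <- 0L
  set.seed(305)
  for (rep in 1:10) {
    ev <- evolve_on_tree(rand_dna(1000), tr, subst_model("JC69"))
    block <- data.frame(species = tr$tip.label, chrom = "chr1", start = 0,
                        size = 1000, strand = "+", src_size = 1000,
                        text = unname(ev$alignment[tr$tip.label]),
                        stringsAsFactors = FALSE)
    maf <- structure(list(blocks = list(block), reference = "a"),
                     class = "maf_alignment")
    if (nrow(segment_conserved(maf, nm, conserved_state_model())$ecrs) > 0)
      n_called <- n_called + 1L
  }
  expect_lte(n_called, 1L)       # 0 ECRs in >= 95 % of neutral simulations
})

test_that("rho -> 0 cannot reduce conserved columns on an identical alignment", {
  tr <- ape::read.tree(text = "((a:0.25,b:0.25):0.1,c:0.3);")
  nm <- neutral_model(tr, subst_model("JC69"))
  set.seed(306)
  row <- rand_dna(200)
  block <- data.frame(species = c("a", "b", "c"), chrom = "chr1", start = 0,
                      size = 200, strand = "+", src_size = 200, text = row,
                      stringsAsFactors = FALSE)
  maf <- structure(list(blocks = list(block), reference = "a"),
                   class = "maf_alignment")
  count_conserved <- function(rho) {
    seg <- segment_conserved(maf, nm, conserved_state_model(rho = rho),
                             min_ecr_length = 1)
    sum(seg$tracks[[1]]$viterbi == 2L)
  }
  counts <- vapply(c(0.9, 0.5, 0.3, 0.1, 0.01), count_conserved, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("reference-gap columns are skipped in projected coordinates", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  nm <- neutral_model(tr, subst_model("JC69"))
  # identical 40-col alignment, reference gapped in columns 11-20
  common <- rand_dna(40)
  reftxt <- paste0(substr(common, 1, 10), strrep("-", 10),
                   substr(common, 21, 40))
  block <- data.frame(species = c("a", "b"), chrom = "chr1", start = 0,
                      size = c(30, 40), strand = "+", src_size = 100,
                      text = c(reftxt, common), stringsAsFactors = FALSE)
  maf <- structure(list(blocks = list(block), reference = "a"),
                   class = "maf_alignment")
  seg <- segment_conserved(maf, nm, conserved_state_model(), min_ecr_length = 5)
  expect_equal(nrow(seg$ecrs), 1)
  expect_lte(seg$ecrs$end, 30)   # spans at most the 30 reference bases
})

test_that("overlap resolution drops >90 %-overlapped shorter regions", {
  mk <- function(s, e, score = 0.5)
    genomic_interval("x", "chr1", s, e, score = score)
  # [0,100) vs [2,97): overlap 95 = 100 % of the shorter -> keep the longer
  out <- resolve_overlaps(rbind(mk(0, 100), mk(2, 97)))
  expect_equal(out$start, 0); expect_equal(out$end, 100)
  # 50 % mutual overlap: both kept
  out2 <- resolve_overlaps(rbind(mk(0, 100), mk(50, 150)))
  expect_equal(nrow(out2), 2)
  # three mutually nested regions: only the longest survives
  out3 <- resolve_overlaps(rbind(mk(10, 90), mk(0, 100), mk(20, 80)))
  expect_equal(nrow(out3), 1)
  expect_equal(c(out3$start, out3$end), c(0, 100))
  # equal length: higher score wins
  out4 <- resolve_overlaps(rbind(mk(0, 100, 0.4), mk(5, 105, 0.9)))
  expect_equal(out4$start, 5)
})

test_that("overlap resolution is stable under input permutation", {
  set.seed(307)
  regs <- do.call(rbind, lapply(1:25, function(i) {
    s <- sample(0:500, 1)
    genomic_interval("x", "chr1", s, s + sample(10:120, 1),
                     score = runif(1))
  }))
  ref <- resolve_overlaps(regs)
  for (k in 1:5) {
    perm <- regs[sample(nrow(regs)), , drop = FALSE]
    out <- resolve_overlaps(perm)
    expect_equal(out$start, ref$start)
    expect_equal(out$end, ref$end)
  }
})

test_that("neutral-model serialization round-trips", {
  tr <- ape::read.tree(text = "((a:0.21,b:0.17):0.08,c:0.3);")
  nm <- neutral_model(tr, subst_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3),
                                      kappa = 3.5), chrom_class = "X")
  f <- tempfile(fileext = ".mod")
  write_neutral_model(nm, f)
  back <- read_neutral_model(f)
  expect_equal(back$model$kappa, 3.5, tolerance = 1e-6)
  expect_equal(back$chrom_class, "X")
  expect_equal(sort(back$tree$tip.label), c("a", "b", "c"))
  expect_equal(sum(back$tree$edge.length), sum(tr$edge.length), tolerance = 1e-6)
})
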
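# repeat masking, exact shared n-mers, three-way intersection,
# chance statistics and PFM matching

test_that("simple-repeat masking: boundary cases and exhaustive oracle", {
  expect_equal(mask_simple_repeats("ACACACACACACAC")$masked,
               tolower("ACACACACACACAC"))
  expect_equal(mask_simple_repeats("ACGTACGTTGCA")$masked, "ACGTACGTTGCA")
  # planted (AAT)x6 in a random background, checked against an exhaustive
  # tandem-scan oracle (naive per-unit while-loop scan)
  oracle_mask <- function(s, unit_max = 6, min_span = 12, min_copies = 2.5) {
    ch <- strsplit(toupper(s), "")[[1]]; n <- length(ch)
    masked <- rep(FALSE, n)
    for (u in 1:unit_max) for (i in seq_len(n)) {
      if (i + u > n || ch[i + u] != ch[i]) next
      if (i > 1 && i + u - 1 <= n && ch[i - 1] == ch[i - 1 + u]) next # not a start
      j <- i
      while (j + u <= n && ch[j + u] == ch[j]) j <- j + 1
      span <- j + u - i
      if (span >= min_span && span / u >= min_copies) masked[i:(j + u - 1)] <- TRUE
    }
    which(masked)
  }
  set.seed(601)
  s <- paste0(rand_dna(500), strrep("AAT", 6), rand_dna(500))
  mk <- mask_simple_repeats(s)
  masked_pos <- which(strsplit(mk$masked, "")[[1]] %in% letters)
  expect_equal(masked_pos, oracle_mask(s))
  expect_true(all(501:518 %in% masked_pos))   # the planted run is masked
})

test_that("exact hits: identity, reverse strand, masked exclusion", {
  set.seed(602)
  s <- rand_dna(20)
  hits <- find_exact_hits(s, s, 7)
  full <- hits[hits$length == 20, ]
  expect_gte(nrow(full), 1)
  expect_equal(full$a_start[1], 0); expect_equal(full$b_end[1], 20)

  # reverse-strand hit: GATTACAG present as CTGTAATC in B
  a <- paste0(rand_dna(20), "GATTACAG", rand_dna(20))
  b <- paste0(rand_dna(20), "CTGTAATC", rand_dna(20))
  hits2 <- find_exact_hits(a, b, 7)
  rc <- hits2[hits2$strand == "-" & grepl("GATTACAG", hits2$seq), ]
  expect_gte(nrow(rc), 1)
  # coordinates verify by substring extraction on both sides
  expect_equal(substr(a, rc$a_start[1] + 1, rc$a_end[1]), rc$seq[1])
  expect_equal(revcomp(substr(b, rc$b_start[1] + 1, rc$b_end[1])), rc$seq[1])

  # lower-case (masked) bases can not participate
  am <- paste0(substr(a, 1, 20), tolower("GATTACAG"), substr(a, 29, 48))
  hits3 <- find_exact_hits(am, b, 7)
  expect_false(any(grepl("GATTACAG", hits3$seq)))
})

test_that("exact hits equal the O(n*m) brute-force scan", {
  set.seed(603)
  for (rep in 1:3) {
    # low-entropy alphabet inflates the hit count enough to be interesting
    a <- paste(sample(c("A", "C", "G"), 400, TRUE, prob = c(.4, .4, .2)),
               collapse = "")
    b <- paste(sample(c("A", "C", "G"), 400, TRUE, prob = c(.4, .4, .2)),
               collapse = "")
    got <- find_exact_hits(a, b, 7)
    want <- oracle_exact_hits(a, b, 7)
    key <- function(h) sort(paste(h$a_start, h$a_end, h$b_start, h$b_end,
                                  h$strand))
    if (is.null(want)) expect_equal(nrow(got), 0)
    else expect_equal(key(got), key(want))
  }
})

test_that("three-way intersection requires all three species", {
  set.seed(604)
  motif <- "TTGACGCA"
  zf <- paste0(rand_dna(80), motif, rand_dna(80))
  mm <- paste0(rand_dna(40), motif, rand_dna(120))
  # human genome: mouse region embedded at offset 1000, identity alignment
  mm_chrom <- paste0(rand_dna(300), mm, rand_dna(300))
  hs_chrom <- paste0(rand_dna(1000), mm, rand_dna(500))
  aln <- pw_aln(pw_block("mm9", "chr5", 0, "hg19", "chr2", 1000 - 300,
                         mm_chrom, mm_chrom),
                qasm = "mm9", tasm = "hg19")
  mm_iv <- genomic_interval("mm9", "chr5", 300, 300 + nchar(mm))
  sm <- intersect_threeway(zf, mm, mm_iv, aln, c(chr2 = hs_chrom), 7)
  hit <- sm[grepl(motif, sm$seq) | vapply(sm$seq, grepl, TRUE, x = motif), ]
  expect_gte(nrow(sm), 1)
  expect_true(any(vapply(sm$seq, function(s)
    grepl(s, motif, fixed = TRUE) || grepl(motif, s, fixed = TRUE), TRUE)))
  # every reported string occurs verbatim (modulo strand) in all three
  for (i in seq_len(nrow(sm))) {
    s <- sm$seq[i]
    expect_true(grepl(s, toupper(zf), fixed = TRUE))
    mm_sub <- substr(mm, sm$mm_start[i] + 1, sm$mm_end[i])
    expect_equal(toupper(if (sm$mm_strand[i] == "+") mm_sub else revcomp(mm_sub)), s)
  }
  # motif present in only two species: no shared motif containing it
  zf2 <- paste0(rand_dna(80), "CCATAGTC", rand_dna(80))
  mm2 <- paste0(rand_dna(40), "CCATAGTC", rand_dna(40))
  hs2 <- rand_dna(160)
  aln2 <- pw_aln(pw_block("mm9", "chr5", 0, "hg19", "chr2", 0, mm2, mm2),
                 qasm = "mm9", tasm = "hg19")
  sm2 <- intersect_threeway(zf2, mm2,
                            genomic_interval("mm9", "chr5", 0, nchar(mm2)),
                            aln2, c(chr2 = hs2), 7)
  expect_false(any(vapply(sm2$seq, function(s)
    grepl("CCATAGTC", s, fixed = TRUE) || grepl(s, "CCATAGTC", fixed = TRUE),
    TRUE)))
})

test_that("chance statistics reproduce the joint-probability calculus", {
  # a chance fraction of 0.53 squares to 0.2809 (printed as 0.28)
  cm <- chance_statistics(cbind(1000, 1000), observed = round(
    karlin_expected(1000, 1000) / 0.53))
  expect_equal(cm$fraction, 0.53, tolerance = 0.01)
  expect_equal(cm$p_joint, cm$fraction^2)
  expect_equal(round(cm$p_joint, 2), 0.28)
  # E = m n 2^-B is monotone in m, n and decreasing in B
  expect_lt(karlin_expected(900, 1000), karlin_expected(1000, 1000))
  expect_lt(karlin_expected(1000, 900), karlin_expected(1000, 1000))
  expect_gt(karlin_expected(1000, 1000, 13), karlin_expected(1000, 1000, 13.9))
  expect_equal(karlin_expected(0, 500), 0)
  # observed zero with positive expectation: capped with a warning
  expect_warning(cm0 <- chance_statistics(cbind(1000, 1000), 0), "capped")
  expect_equal(cm0$fraction, 1)
})

near_det_pfm <- function(id, consensus) {
  M <- matrix(0.01, 4, nchar(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  M[cbind(idx, seq_len(nchar(consensus)))] <- 0.97
  list(id = id, name = paste0("TF_", id), matrix = M)
}

test_that("PFM matching: self-retrieval, uniform column analytics, overlap rule", {
  db <- list(near_det_pfm("M1", "GATTACAG"),
             near_det_pfm("M2", "CCGGAATT"),
             near_det_pfm("M3", "TTTTCCCC"),
             list(id = "U", name = "uniform",
                  matrix = matrix(0.25, 4, 8,
                                  dimnames = list(c("A", "C", "G", "T"), NULL))))
  cfg <- motif_match_config(n_permutations = 2000, seed = 9)
  res <- match_pfm("GATTACAG", db, cfg)
  expect_equal(res$motif_id[1], "M1")
  expect_lte(res$evalue[1], 0.1)
  expect_false("U" %in% res$motif_id)
  # uniform PFM distance is the analytic constant for any 0/1 query
  u <- db[[4]]$matrix
  q <- query_matrix("GATTACAG")
  expect_equal(mean(sqrt(colSums((q - u)^2))), sqrt(0.75), tolerance = 1e-12)
  # reverse-complement consensus is found on the minus strand
  res_rc <- match_pfm(revcomp("GATTACAG"), db, cfg)
  expect_equal(res_rc$motif_id[1], "M1")
  expect_equal(res_rc$strand[1], "-")
  # permutation determinism under a fixed seed
  res2 <- match_pfm("GATTACAG", db, cfg)
  expect_equal(res, res2)
  # narrow PFMs are skipped with a warning
  db2 <- c(db, list(list(id = "W", name = "narrow",
                         matrix = matrix(0.25, 4, 2))))
  expect_warning(match_pfm("GATTACAG", db2, cfg), "narrower")
})

test_that("overlapping reported sites keep only the smaller E-value", {
  sites <- data.frame(start = c(10, 14, 40), end = c(18, 22, 48),
                      evalue = c(0.05, 0.01, 0.02))
  out <- resolve_tfbs_overlaps(sites)
  expect_setequal(out$evalue, c(0.01, 0.02))    # the 0.05 site overlapped 0.01
})

test_that("bundle: all planted three-way motifs are recovered", {
  b <- shared_bundle()
  cfgp <- b$cfg
  refs <- b$references
  mm_sp <- refs[[1]]; zf_sp <- refs[[length(refs)]]
  g1 <- names(refs)[1]; g3 <- names(refs)[length(refs)]
  aln_hs <- as_pairwise(b$hs_maf, mm_sp, "hs")
  truth <- b$truth$motifs
  el <- b$truth$elements[b$truth$elements$kind == "true", ]
  for (i in seq_len(nrow(el))) {
    zf_seq <- mask_simple_repeats(substr(b$genomes[[zf_sp]], el$start[i] + 1,
                                         el$end[i]))$masked
    mm_seq <- mask_simple_repeats(substr(b$genomes[[mm_sp]], el$start[i] + 1,
                                         el$end[i]))$masked
    mm_iv <- genomic_interval(mm_sp, b$chrom, el$start[i], el$end[i])
    sm <- intersect_threeway(zf_seq, mm_seq, mm_iv, aln_hs,
                             setNames(b$genomes["hs"], b$chrom), 7)
    for (mo in unique(truth$motif[truth$ecr_id == el$ecr_id[i]])) {
      found <- any(vapply(sm$seq, function(s)
        grepl(mo, s, fixed = TRUE) || grepl(revcomp(mo), s, fixed = TRUE) ||
          grepl(s, mo, fixed = TRUE) || grepl(s, revcomp(mo), fixed = TRUE),
        TRUE))
      expect_true(found, label = paste("motif", mo, "in", el$ecr_id[i]))
    }
  }
})
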
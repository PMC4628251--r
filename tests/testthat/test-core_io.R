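# interval conventions, MAF round-trips, interval mapping

test_that("interval constructors enforce the coordinate contract", {
  gi <- genomic_interval("mm9", "chr1", 100, 200)
  expect_equal(gi_width(gi), 100)
  expect_error(genomic_interval("mm9", "chr1", 200, 200), "start < end")
  expect_error(genomic_interval("mm9", "chr1", -1, 5), ">= 0")
  expect_error(genomic_interval("mm9", "chr1", 5, 10, "x"), "strand")
})

test_that("browser-style regions are converted from 1-based inclusive", {
  gi <- parse_region("chr2:39,790,777-39,791,782", "danRer7")
  expect_equal(gi$start, 39790776)
  expect_equal(gi$end, 39791782)
  expect_equal(gi_width(gi), 1006)     # inclusive length
  expect_error(parse_region("chr2:10-5"), "exceeds")
  expect_error(parse_region("oops"), "malformed")
})

test_that("MAF parsing: gapped lengths, strand normalization, errors", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=0",
               "s mm.chr1 10 4 + 1000 AC-GT",
               "s rn.chr1 50 5 + 2000 ACAGT", ""), maf)
  m <- read_maf(maf)
  b <- m$blocks[[1]]
  expect_equal(nchar(b$text), c(5, 5))
  expect_equal(b$size, c(4, 5))
  expect_equal(m$reference, "mm")

  # minus-strand rows are normalized to forward intervals
  writeLines(c("a", "s mm.chr1 10 4 + 1000 ACGT",
               "s rn.chr1 30 4 - 2000 ACGT"), maf)
  m2 <- read_maf(maf)
  expect_equal(m2$blocks[[1]]$start[2], 2000 - 30 - 4)
  expect_equal(m2$blocks[[1]]$strand[2], "-")

  writeLines(c("a", "s mm.chr1 10 5 + 1000 AC-GT"), maf)
  expect_error(read_maf(maf), "line 2")
  writeLines(c("a", "s mm.chr1 10 4 + 1000 ACGT",
               "s rn.chr1 30 5 + 2000 ACGTA-"), maf)
  expect_error(read_maf(maf), "unequal|size")
  writeLines("##maf version=1", maf)
  expect_error(read_maf(maf), "no alignment blocks")
})

test_that("a multi-block synthetic MAF round-trips through write/read", {
  set.seed(11)
  blocks <- lapply(c(0, 500, 900), function(s) {
    txt <- c(rand_dna(60), rand_dna(60))
    data.frame(species = c("mm", "rn"), chrom = "chr1", start = s, size = 60,
               strand = "+", src_size = 5000, text = txt,
               stringsAsFactors = FALSE)
  })
  maf <- structure(list(blocks = blocks, reference = "mm"),
                   class = "maf_alignment")
  f <- tempfile(fileext = ".maf")
  write_maf(maf, f)
  back <- read_maf(f)
  expect_equal(length(back$blocks), 3)
  for (i in 1:3) {
    expect_equal(back$blocks[[i]]$text, maf$blocks[[i]]$text)
    expect_equal(back$blocks[[i]]$start, maf$blocks[[i]]$start)
  }
})

test_that("map_interval: offset identity, deletions, gap runs, threshold", {
  # gapless block query[100,200) <-> target[300,400)
  aln <- pw_aln(pw_block("A", "chr1", 100, "B", "chr2", 300,
                         strsplit(rand_dna(100), "")[[1]] |> paste(collapse = ""),
                         rand_dna(100)))
  iv <- genomic_interval("A", "chr1", 110, 120)
  out <- map_interval(iv, aln)
  expect_equal(c(out$start, out$end), c(310, 320))
  expect_equal(out$assembly, "B")

  # 5-base target deletion spanning query [110,115): oracle = per-column table
  qtext <- rand_dna(100)
  tchars <- strsplit(rand_dna(95), "")[[1]]
  ttext <- paste(c(tchars[1:10], rep("-", 5), tchars[11:95]), collapse = "")
  aln2 <- pw_aln(pw_block("A", "chr1", 100, "B", "chr2", 300, qtext, ttext))
  tab <- oracle_column_table(100, 300, qtext, ttext)
  iv2 <- genomic_interval("A", "chr1", 100, 120)
  mapped_cols <- tab[!is.na(tab$qpos) & tab$qpos >= 100 & tab$qpos < 120 &
                       !is.na(tab$tpos), ]
  expect_equal(nrow(mapped_cols), 15)
  out2 <- map_interval(iv2, aln2)
  expect_equal(c(out2$start, out2$end),
               c(min(mapped_cols$tpos), max(mapped_cols$tpos) + 1))

  # interval fully inside a target gap run maps nowhere
  iv3 <- genomic_interval("A", "chr1", 110, 115)
  expect_null(map_interval(iv3, aln2))
  # below min_mapped_fraction
  iv4 <- genomic_interval("A", "chr1", 108, 116)   # 3 of 8 bases map
  expect_null(map_interval(iv4, aln2))
  expect_false(is.null(map_interval(iv4, aln2, min_mapped_fraction = 0.3)))
  # outside all blocks
  expect_null(map_interval(genomic_interval("A", "chr1", 5000, 5100), aln))
})

test_that("mapping properties: self-identity and monotone order", {
  set.seed(21)
  txt <- rand_dna(300)
  self <- pw_aln(pw_block("A", "chr1", 0, "A", "chr1", 0, txt, txt),
                 qasm = "A", tasm = "A")
  for (k in 1:20) {
    s <- sample(0:290, 1); e <- s + sample(1:(300 - s), 1)
    iv <- genomic_interval("A", "chr1", s, e)
    out <- map_interval(iv, self)
    expect_equal(c(out$start, out$end), c(s, e))
  }
  # monotone: disjoint ordered intervals do not invert after mapping
  qtext <- rand_dna(200)
  tt <- strsplit(rand_dna(180), "")[[1]]
  ttext <- paste(c(tt[1:50], rep("-", 10), tt[51:170], rep("-", 10),
                   tt[171:180]), collapse = "")
  aln <- pw_aln(pw_block("A", "chr1", 0, "B", "chr1", 1000, qtext, ttext))
  prev_end <- -Inf
  for (s in seq(0, 180, by = 20)) {
    out <- map_interval(genomic_interval("A", "chr1", s, s + 15), aln,
                        min_mapped_fraction = 0.1)
    if (is.null(out)) next
    expect_gte(out$start, prev_end - 1)
    prev_end <- out$end
  }
})

test_that("BED and annotation round-trips keep the half-open convention", {
  gi <- genomic_interval("mm9", "chr1", c(0, 100), c(50, 230),
                         name = c("a", "b"), score = c(1, 2))
  f <- tempfile(fileext = ".bed")
  write_bed(gi, f)
  back <- read_bed(f, "mm9")
  expect_equal(back$start, gi$start)
  expect_equal(back$end, gi$end)
  expect_equal(back$name, gi$name)

  annot <- genomic_interval("mm9", "chr1", c(10, 200, 400), c(100, 300, 480),
                            gene_id = "g1", exon_rank = 1:3)
  g <- tempfile(fileext = ".gff3")
  write_annotation(annot, g)
  back <- read_annotation(g, "mm9")
  expect_equal(back$start, annot$start)
  expect_equal(back$end, annot$end)
  expect_equal(back$gene_id, rep("g1", 3))
  expect_equal(back$exon_rank, 1:3)
})

test_that("MEME minimal motifs round-trip and are validated", {
  mats <- list(list(id = "M1", name = "TFA",
                    matrix = query_cols <- matrix(c(0.97, 0.01, 0.01, 0.01,
                                                    0.01, 0.97, 0.01, 0.01,
                                                    0.25, 0.25, 0.25, 0.25),
                                                  4, 3,
                                                  dimnames = list(c("A","C","G","T"), NULL))))
  f <- tempfile(fileext = ".meme")
  write_meme(mats, f)
  back <- read_meme(f)
  expect_equal(back[[1]]$id, "M1")
  expect_equal(back[[1]]$matrix, mats[[1]]$matrix, tolerance = 1e-5)
})

test_that("revcomp preserves case (soft masks)", {
  expect_equal(revcomp("GATTACAG"), "CTGTAATC")
  expect_equal(revcomp("AcgT"), "AcgT")
  expect_equal(revcomp(revcomp("ACGTTGCA")), "ACGTTGCA")
})
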
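#' Soft-mask simple tandem repeats
#'
#' Tandem repeats with unit length 1-6 spanning at least `min_span` bases
#' and at least `min_copies` copies are lower-cased.  Masked bases can
#' neither seed nor be contained in exact shared n-mer hits.
#'
#' @param seq nucleotide string.
#' @param unit_max maximum repeat unit length (default 6).
#' @param min_span minimum masked span in bp (default 12).
#' @param min_copies minimum number of unit copies (default 2.5).
#' @return list with `masked` (string with lower-case masked runs) and
#'   `runs` (data.frame of 0-based half-open masked spans with unit size).
#' @examples
#' mask_simple_repeats("ACACACACACACAC")$masked
#' @export
mask_simple_repeats <- function(seq, unit_max = 6, min_span = 12,
                                min_copies = 2.5) {
  s <- toupper(seq)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  mask <- rep(FALSE, n)
  runs <- list()
  for (u in seq_len(min(unit_max, max(n - 1, 0)))) {
    if (n <= u) break
    eq <- ch[(u + 1):n] == ch[1:(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- r$lengths[k] + u            # repeated segment incl. first unit
      if (span < min_span) next
      if (span / u < min_copies) next
      from <- starts[k]; to <- ends[k] + u  # 1-based inclusive positions
      mask[from:to] <- TRUE
      runs[[length(runs) + 1L]] <- data.frame(start = from - 1L, end = to,
                                              unit = u)
    }
  }
  out <- ch
  out[mask] <- tolower(out[mask])
  runs <- if (length(runs)) {
    rr <- do.call(rbind, runs)
    rr[order(rr$start, rr$end), , drop = FALSE]
  } else data.frame(start = integer(0), end = integer(0), unit = integer(0))
  list(masked = paste(out, collapse = ""), runs = runs)
}

# replace soft-masked (lower-case) characters by a sentinel that never
# matches across sequences
sentinel <- function(s, token) {
  gsub("[acgtn]", token, s)
}

empty_hits <- function() {
  data.frame(seq = character(0), length = integer(0),
             a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# maximal equality runs >= min_n between two char vectors along all
# diagonals; returns 1-based starts in each
diagonal_runs <- function(ac, bc, min_n) {
  na <- length(ac); nb <- length(bc)
  out <- list()
  for (t in (1 - na):(nb - 1)) {
    i0 <- max(1L, 1L - t); i1 <- min(na, nb - t)
    if (i1 - i0 + 1L < min_n) next
    idx <- i0:i1
    eq <- ac[idx] == bc[idx + t]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_n)) {
      out[[length(out) + 1L]] <- c(a = idx[starts[k]],
                                   b = idx[starts[k]] + t,
                                   len = r$lengths[k])
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Find maximal exact shared n-mers between two sequences
#'
#' All maximal exact matches of length at least `min_n` between the two
#' (repeat-masked) sequences, on the forward and reverse-complement
#' orientations.  A match is maximal when it cannot be extended on either
#' side; soft-masked (lower-case) bases never participate.
#'
#' @param seq_a,seq_b nucleotide strings (soft masks as lower case).
#' @param min_n minimum match length (default 7, the length of most
#'   transcription-factor binding sites).
#' @return data.frame of hits with the shared string, its length, 0-based
#'   half-open spans in both sequences (forward-strand coordinates), and
#'   the strand of the B-side occurrence.
#' @export
find_exact_hits <- function(seq_a, seq_b, min_n = 7) {
  ac <- strsplit(sentinel(seq_a, "#"), "")[[1]]
  bc <- strsplit(sentinel(seq_b, "$"), "")[[1]]
  nb <- length(bc)
  res <- list()
  fw <- diagonal_runs(ac, bc, min_n)
  if (!is.null(fw)) for (k in seq_len(nrow(fw))) {
    res[[length(res) + 1L]] <- data.frame(
      seq = paste(ac[fw[k, "a"]:(fw[k, "a"] + fw[k, "len"] - 1L)], collapse = ""),
      length = fw[k, "len"],
      a_start = fw[k, "a"] - 1L, a_end = fw[k, "a"] + fw[k, "len"] - 1L,
      b_start = fw[k, "b"] - 1L, b_end = fw[k, "b"] + fw[k, "len"] - 1L,
      strand = "+", stringsAsFactors = FALSE)
  }
  rc <- diagonal_runs(ac, strsplit(sentinel(revcomp(seq_b), "$"), "")[[1]], min_n)
  if (!is.null(rc)) for (k in seq_len(nrow(rc))) {
    len <- rc[k, "len"]; p <- rc[k, "b"]
    res[[length(res) + 1L]] <- data.frame(
      seq = paste(ac[rc[k, "a"]:(rc[k, "a"] + len - 1L)], collapse = ""),
      length = len,
      a_start = rc[k, "a"] - 1L, a_end = rc[k, "a"] + len - 1L,
      b_start = nb - (p + len - 1L), b_end = nb - p + 1L,
      strand = "-", stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty_hits())
  hits <- do.call(rbind, res)
  rownames(hits) <- NULL
  hits[order(hits$a_start, hits$b_start), , drop = FALSE]
}

#' Three-way shared motifs across zebrafish, mouse and human sequences
#'
#' Implements the stepwise shared-block search: exact hits between the
#' fish and mouse sequences, extraction of the orthologous human sequence
#' through a mouse-to-human pairwise alignment, exact hits between the
#' fish and human sequences, and finally fish-coordinate overlaps of
#' length at least `min_n` between the two hit sets.  The shared string is
#' the overlapping fish substring.
#'
#' @param seq_zf,seq_mm repeat-masked sequences of the fish and mouse
#'   conserved regions.
#' @param mm_iv single-row `gint`: genomic span of the mouse region on the
#'   alignment's query assembly.
#' @param aln_mm_hs `pairwise_alignment` mouse -> human.
#' @param hs_genome named character vector of human chromosome sequences.
#' @param min_n minimum shared length (default 7).
#' @param hits_zf_mm optionally precomputed [find_exact_hits()] output.
#' @return data.frame of shared motifs: shared string, spans within the
#'   three sequences (`zf_*`, `mm_*`, `hs_*`; 0-based half-open offsets,
#'   human offsets within the extracted orthologous subsequence whose
#'   genomic span is attached as attribute `hs_interval`), and per-species
#'   strands.
#' @export
intersect_threeway <- function(seq_zf, seq_mm, mm_iv, aln_mm_hs, hs_genome,
                               min_n = 7, hits_zf_mm = NULL) {
  if (is.null(hits_zf_mm)) hits_zf_mm <- find_exact_hits(seq_zf, seq_mm, min_n)
  hs_iv <- map_interval(mm_iv, aln_mm_hs)
  if (is.null(hs_iv)) {
    message("mouse region unmappable to the human assembly; no shared motifs")
    return(empty_shared())
  }
  seq_hs <- substr(hs_genome[[hs_iv$chrom]], hs_iv$start + 1, hs_iv$end)
  if (hs_iv$strand == "-") seq_hs <- revcomp(seq_hs)
  hits_zf_hs <- find_exact_hits(seq_zf, seq_hs, min_n)
  out <- list()
  for (i in seq_len(nrow(hits_zf_mm))) for (j in seq_len(nrow(hits_zf_hs))) {
    s <- max(hits_zf_mm$a_start[i], hits_zf_hs$a_start[j])
    e <- min(hits_zf_mm$a_end[i], hits_zf_hs$a_end[j])
    if (e - s < min_n) next
    off_m <- s - hits_zf_mm$a_start[i]; len <- e - s
    off_h <- s - hits_zf_hs$a_start[j]
    mm_span <- sub_span(hits_zf_mm[i, ], off_m, len)
    hs_span <- sub_span(hits_zf_hs[j, ], off_h, len)
    out[[length(out) + 1L]] <- data.frame(
      seq = toupper(substr(seq_zf, s + 1, e)), length = len,
      zf_start = s, zf_end = e,
      mm_start = mm_span[1], mm_end = mm_span[2],
      mm_strand = hits_zf_mm$strand[i],
      hs_start = hs_span[1], hs_end = hs_span[2],
      hs_strand = hits_zf_hs$strand[j], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_shared())
  sm <- unique(do.call(rbind, out))
  rownames(sm) <- NULL
  attr(sm, "hs_interval") <- hs_iv
  sm[order(sm$zf_start), , drop = FALSE]
}

# sub-span of the B side of a hit corresponding to an offset window on its
# A side (reverse-strand hits count from the right)
sub_span <- function(hit, off, len) {
  if (hit$strand == "+") c(hit$b_start + off, hit$b_start + off + len)
  else c(hit$b_end - off - len, hit$b_end - off)
}

empty_shared <- function() {
  data.frame(seq = character(0), length = integer(0),
             zf_start = integer(0), zf_end = integer(0),
             mm_start = integer(0), mm_end = integer(0),
             mm_strand = character(0), hs_start = integer(0),
             hs_end = integer(0), hs_strand = character(0),
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul expected chance alignment count
#'
#' `E = m * n * 2^(-B)`: the number of length-7 alignments expected by
#' chance between sequences of lengths `m` and `n`, with `B` the bitscore
#' of a heptamer (13.9 bits).
#'
#' @param m,n sequence lengths in bp.
#' @param bitscore heptamer bitscore in bits (default 13.9).
#' @export
karlin_expected <- function(m, n, bitscore = 13.9) {
  stopifnot(all(m >= 0), all(n >= 0), bitscore > 0)
  m * n * 2^(-bitscore)
}

#' Chance statistics for shared n-mer counts
#'
#' For each pairwise comparison, the expected chance count is the
#' Karlin-Altschul expectation; the chance fraction of a pair is
#' `min(E_i / O_i, 1)`, the joint probability that a motif shared three
#' ways arose by chance is the squared mean chance fraction (conservative:
#' assumes the same chance alignments occur in both pairwise sets), and
#' the expected chance count among shared motifs is that probability times
#' the observed shared-motif count.
#'
#' @param pair_lengths two-column matrix (or data.frame) of sequence
#'   length pairs (m, n), one row per pairwise comparison.
#' @param observed observed pairwise alignment counts, one per row.
#' @param bitscore heptamer bitscore (default 13.9).
#' @return object of class `chance_model`: list with `expected` (E_i),
#'   `observed`, `fraction` (mean chance fraction f), `p_joint` (= f^2)
#'   and `bitscore`.
#' @export
chance_statistics <- function(pair_lengths, observed, bitscore = 13.9) {
  pl <- as.matrix(pair_lengths)
  stopifnot(ncol(pl) == 2, nrow(pl) == length(observed), all(observed >= 0))
  E <- karlin_expected(pl[, 1], pl[, 2], bitscore)
  ratio <- numeric(length(E))
  for (i in seq_along(E)) {
    if (observed[i] == 0 && E[i] > 0) {
      warning("pair ", i, ": expected ", round(E[i], 1),
              " chance alignments but observed 0; chance fraction capped at 1")
      ratio[i] <- 1
    } else if (observed[i] == 0) ratio[i] <- 0
    else ratio[i] <- min(E[i] / observed[i], 1)
  }
  f <- mean(ratio)
  structure(list(expected = E, observed = observed, fraction = f,
                 p_joint = f^2, bitscore = bitscore), class = "chance_model")
}

#' @rdname chance_statistics
#' @param cm a `chance_model`.
#' @param shared_counts observed three-way shared-motif counts per region.
#' @return expected numbers of chance shared motifs, same length.
#' @export
expected_shared_by_chance <- function(cm, shared_counts) {
  stopifnot(inherits(cm, "chance_model"))
  cm$p_joint * shared_counts
}

#' Motif-to-PFM matching configuration
#'
#' @param e_threshold maximum reported E-value (default 0.1).
#' @param n_permutations permutation-null size (default 10000, minimum 1000).
#' @param min_width PFMs narrower than this are skipped (default 4).
#' @param seed RNG seed for the permutation null (reproducibility).
#' @export
motif_match_config <- function(e_threshold = 0.1, n_permutations = 10000,
                               min_width = 4, seed = 1) {
  stopifnot(e_threshold > 0, n_permutations >= 1000)
  structure(as.list(environment()), class = "motif_match_config")
}

query_matrix <- function(nmer) {
  ch <- strsplit(toupper(nmer), "")[[1]]
  stopifnot(all(ch %in% BASES))
  Q <- matrix(0, 4, length(ch), dimnames = list(BASES, NULL))
  Q[cbind(match(ch, BASES), seq_along(ch))] <- 1
  Q
}

revcomp_pfm <- function(M) M[4:1, rev(seq_len(ncol(M))), drop = FALSE]

# mean per-aligned-column Euclidean distance at every full-overlap offset
# of the shorter matrix within the longer; returns min and its offset
best_distance <- function(Q, M) {
  L <- ncol(Q); w <- ncol(M)
  if (w >= L) {
    offs <- 0:(w - L)
    d <- vapply(offs, function(o)
      mean(sqrt(colSums((Q - M[, (o + 1):(o + L), drop = FALSE])^2))), 0)
  } else {
    offs <- 0:(L - w)
    d <- vapply(offs, function(o)
      mean(sqrt(colSums((Q[, (o + 1):(o + w), drop = FALSE] - M)^2))), 0)
  }
  k <- which.min(d)
  c(dist = d[k], offset = offs[k])
}

#' Annotate a shared motif with matching transcription-factor PFMs
#'
#' The query n-mer is encoded as a 0/1 column matrix and compared to every
#' database PFM at every full-overlap offset on both strands by mean
#' per-aligned-column Euclidean distance.  Significance comes from a
#' permutation null: queries of the same width assembled from the
#' database's pooled columns.  The E-value is the Bonferroni-style
#' `p x (number of database PFMs)`; matches with `E <= e_threshold` are
#' reported, best (smallest distance) offset and strand per PFM.
#'
#' @param nmer shared motif string (ACGT).
#' @param pfm_db motif list from [read_meme()].
#' @param cfg a [motif_match_config()].
#' @return data.frame of reported matches: `motif_id`, `tf_name`,
#'   `distance`, `p_value`, `evalue`, `offset`, `strand`, sorted by
#'   E-value.  Zero rows when nothing passes.
#' @export
match_pfm <- function(nmer, pfm_db, cfg = motif_match_config()) {
  keep <- vapply(pfm_db, function(m) ncol(m$matrix) >= cfg$min_width, TRUE)
  if (any(!keep))
    warning(sum(!keep), " PFM(s) narrower than ", cfg$min_width, " skipped")
  pfm_db <- pfm_db[keep]
  n_db <- length(pfm_db)
  if (n_db == 0L) stop("empty PFM database after width filtering")
  Q <- query_matrix(nmer)
  L <- ncol(Q)
  pool <- do.call(cbind, lapply(pfm_db, function(m) m$matrix))
  set.seed(cfg$seed)
  idx <- matrix(sample.int(ncol(pool), cfg$n_permutations * L, replace = TRUE),
                cfg$n_permutations, L)
  rows <- list()
  for (m in pfm_db) {
    obs <- rbind(c(best_distance(Q, m$matrix), strand = 1),
                 c(best_distance(Q, revcomp_pfm(m$matrix)), strand = 2))
    b <- obs[which.min(obs[, "dist"]), ]
    # null distribution: pooled-column queries against this PFM (both strands)
    null_best <- rep(Inf, cfg$n_permutations)
    for (Ms in list(m$matrix, revcomp_pfm(m$matrix))) {
      w <- ncol(Ms)
      D <- matrix(0, ncol(pool), w)
      for (cidx in seq_len(w))
        D[, cidx] <- sqrt(colSums((pool - Ms[, cidx])^2))
      if (w >= L) {
        for (o in 0:(w - L)) {
          s <- rowMeans(vapply(seq_len(L), function(j) D[idx[, j], o + j],
                               numeric(cfg$n_permutations)))
          null_best <- pmin(null_best, s)
        }
      } else {
        for (o in 0:(L - w)) {
          s <- rowMeans(vapply(seq_len(w), function(j) D[idx[, o + j], j],
                               numeric(cfg$n_permutations)))
          null_best <- pmin(null_best, s)
        }
      }
    }
    p <- (1 + sum(null_best <= b["dist"])) / (cfg$n_permutations + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      motif_id = m$id, tf_name = m$name, distance = b[["dist"]],
      p_value = p, evalue = p * n_db, offset = b[["offset"]],
      strand = c("+", "-")[b[["strand"]]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[res$evalue <= cfg$e_threshold, , drop = FALSE]
  res <- res[order(res$evalue, res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Resolve overlapping reported binding sites
#'
#' When two reported sites occupy overlapping query positions, only the
#' one with the smaller E-value is kept (greedy by ascending E-value).
#'
#' @param sites data.frame with `start`, `end` (any shared coordinate
#'   system) and `evalue`.
#' @return the retained subset.
#' @export
resolve_tfbs_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- sites[order(sites$evalue), , drop = FALSE]
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(sites))) {
      if (j <= i || !keep[j]) next
      if (sites$start[j] < sites$end[i] && sites$end[j] > sites$start[i])
        keep[j] <- FALSE
    }
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
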
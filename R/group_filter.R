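#' Seed-and-extend homology search configuration
#'
#' Thresholds follow the BLAT-style criteria used for cross-group homolog
#' screening: a hit is reported when `score = matches - mismatches -
#' gap_openings >= min_score` and `identity = 100 * matches /
#' (matches + mismatches) >= min_identity`.
#'
#' @param min_score minimum hit score (default 30).
#' @param min_identity minimum percent identity (default 50).
#' @param word_size exact seed length (default 11).
#' @param max_gap maximum distance when chaining seeds on a diagonal
#'   (default 100).
#' @param x_drop score drop terminating ungapped extension (default 10).
#' @export
homology_config <- function(min_score = 30, min_identity = 50,
                            word_size = 11, max_gap = 100, x_drop = 10) {
  stopifnot(min_score > 0, min_identity > 0, min_identity <= 100,
            word_size >= 4, max_gap >= 0, x_drop > 0)
  structure(as.list(environment()), class = "homology_config")
}

#' Remove conserved regions overlapping between-group alignments
#'
#' A region is removed as soon as one of its reference bases lies inside
#' any aligned block of any between-group pairwise alignment — the
#' one-base-pair removal criterion.  The operation is idempotent and
#' order-independent.
#'
#' @param ecrs `gint` of conserved regions on a group reference assembly.
#' @param inter_group_alns list of `pairwise_alignment`s; blocks whose
#'   query or target assembly equals the regions' assembly are screened.
#' @return list with `kept` and `removed` subsets (stage flags updated).
#' @export
remove_aligned <- function(ecrs, inter_group_alns) {
  if (nrow(ecrs) == 0L) return(list(kept = ecrs, removed = ecrs))
  blocks <- list()
  asm <- ecrs$assembly[1]
  for (aln in inter_group_alns) {
    for (b in aln$blocks) {
      if (aln$query_assembly == asm) blocks[[length(blocks) + 1L]] <- b$query
      if (aln$target_assembly == asm) blocks[[length(blocks) + 1L]] <- b$target
    }
  }
  if (length(blocks) == 0L)
    return(list(kept = ecrs, removed = ecrs[0, , drop = FALSE]))
  bl <- validate_gint(do.call(rbind, blocks))
  hit <- unique(gi_overlaps(ecrs, bl, min_bp = 1L)$query)
  removed <- ecrs[sort(hit), , drop = FALSE]
  kept <- ecrs[setdiff(seq_len(nrow(ecrs)), hit), , drop = FALSE]
  if (nrow(removed) && "stage" %in% names(removed))
    removed$stage <- "intergroup-removed"
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

# exact word_size seed positions between query and target strings
# (uppercased); returns data.frame(q, t) of 1-based start pairs
seed_hits <- function(query, target, w) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq < w || nt < w) return(data.frame(q = integer(0), t = integer(0)))
  qk <- substring(query, 1:(nq - w + 1), w:nq)
  tk <- substring(target, 1:(nt - w + 1), w:nt)
  tmap <- split(seq_along(tk), tk)
  hits <- lapply(seq_along(qk), function(i) {
    tp <- tmap[[qk[i]]]
    if (is.null(tp)) NULL else data.frame(q = i, t = tp)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits)) do.call(rbind, hits) else data.frame(q = integer(0),
                                                         t = integer(0))
}

# ungapped X-drop extension of a diagonal segment; returns hit stats
extend_ungapped <- function(qc, tc, qs, qe, diag_off, x_drop) {
  # extend right from qe
  best <- 0; run <- 0; i <- qe
  while (i < length(qc) && i + diag_off < length(tc)) {
    i <- i + 1
    run <- run + ifelse(qc[i] == tc[i + diag_off], 1, -1)
    if (run > best) { best <- run; qe <- i }
    if (best - run >= x_drop) break
  }
  best <- 0; run <- 0; i <- qs
  while (i > 1 && i + diag_off > 1) {
    i <- i - 1
    run <- run + ifelse(qc[i] == tc[i + diag_off], 1, -1)
    if (run > best) { best <- run; qs <- i }
    if (best - run >= x_drop) break
  }
  m <- sum(qc[qs:qe] == tc[(qs:qe) + diag_off])
  mm <- (qe - qs + 1) - m
  list(qs = qs, qe = qe, matches = m, mismatches = mm)
}

#' Seed-and-extend homology search of a query against a genome
#'
#' Exact `word_size` seeds are found on both strands, chained along
#' diagonals within `max_gap`, and extended ungapped with +1/-1 scoring
#' until the running score drops `x_drop` below its best.  Hits passing
#' the score and identity thresholds are reported; a caller removes any
#' conserved region with at least one hit.
#'
#' @param query nucleotide string (length >= `word_size`).
#' @param target_genome named character vector of target sequences.
#' @param cfg a [homology_config()].
#' @param query_assembly,target_assembly labels stamped on the hits.
#' @return data.frame of hits: query/target spans (0-based half-open),
#'   strand, matches, mismatches, gap openings, score, identity.
#' @export
homology_search <- function(query, target_genome, cfg = homology_config(),
                            query_assembly = "query", target_assembly = "target") {
  stopifnot(nchar(query) >= cfg$word_size)
  out <- list()
  for (chromname in names(target_genome)) {
    tseq <- toupper(target_genome[[chromname]])
    if (nchar(tseq) < cfg$word_size) next
    tc <- strsplit(tseq, "")[[1]]
    for (strand in c("+", "-")) {
      qseq <- toupper(if (strand == "+") query else revcomp(query))
      qc <- strsplit(qseq, "")[[1]]
      seeds <- seed_hits(qseq, tseq, cfg$word_size)
      if (nrow(seeds) == 0L) next
      seeds$diag <- seeds$t - seeds$q
      seeds <- seeds[order(seeds$diag, seeds$q), , drop = FALSE]
      # chain seeds on the same diagonal within max_gap
      newchain <- c(TRUE, diff(seeds$diag) != 0 |
                            diff(seeds$q) > cfg$word_size + cfg$max_gap)
      chain_id <- cumsum(newchain)
      for (ch in split(seq_len(nrow(seeds)), chain_id)) {
        qs <- min(seeds$q[ch]); qe <- max(seeds$q[ch]) + cfg$word_size - 1L
        ext <- extend_ungapped(qc, tc, qs, qe, seeds$diag[ch][1], cfg$x_drop)
        score <- ext$matches - ext$mismatches
        idn <- 100 * ext$matches / (ext$matches + ext$mismatches)
        if (score < cfg$min_score || idn < cfg$min_identity) next
        ts0 <- ext$qs + seeds$diag[ch][1] - 1L   # 0-based target start
        qlen <- nchar(query)
        q0 <- if (strand == "+") ext$qs - 1L else qlen - ext$qe
        q1 <- if (strand == "+") ext$qe else qlen - ext$qs + 1L
        out[[length(out) + 1L]] <- data.frame(
          query_assembly = query_assembly, q_start = q0, q_end = q1,
          target_assembly = target_assembly, chrom = chromname,
          t_start = ts0, t_end = ts0 + (ext$qe - ext$qs + 1L),
          strand = strand, matches = ext$matches,
          mismatches = ext$mismatches, gap_openings = 0L,
          score = score, identity = idn, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(query_assembly = character(0), q_start = integer(0),
                      q_end = integer(0), target_assembly = character(0),
                      chrom = character(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0),
                      matches = integer(0), mismatches = integer(0),
                      gap_openings = integer(0), score = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits <- hits[!duplicated(hits[, c("chrom", "t_start", "t_end", "strand")]), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[order(-hits$score), , drop = FALSE]
}

#' Screen conserved regions against other reference genomes
#'
#' @param ecrs `gint` of regions with sequences extractable from
#'   `genome` (the regions' own genome).
#' @param genome named character vector holding the regions' chromosomes.
#' @param other_genomes named list (by assembly) of target genomes.
#' @param cfg a [homology_config()].
#' @return list with `kept` and `removed` (regions with >= 1 hit).
#' @export
homology_filter <- function(ecrs, genome, other_genomes,
                            cfg = homology_config()) {
  if (nrow(ecrs) == 0L) return(list(kept = ecrs, removed = ecrs))
  has_hit <- vapply(seq_len(nrow(ecrs)), function(i) {
    q <- substr(genome[[ecrs$chrom[i]]], ecrs$start[i] + 1, ecrs$end[i])
    for (asm in names(other_genomes)) {
      h <- homology_search(q, other_genomes[[asm]], cfg,
                           query_assembly = ecrs$assembly[1],
                           target_assembly = asm)
      if (nrow(h) > 0L) return(TRUE)
    }
    FALSE
  }, TRUE)
  removed <- ecrs[has_hit, , drop = FALSE]
  if (nrow(removed) && "stage" %in% names(removed))
    removed$stage <- "intergroup-removed"
  kept <- ecrs[!has_hit, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}
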
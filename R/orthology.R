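#' Projection / confirmation thresholds for exon orthology
#'
#' Exon orthology inferred through an alignment is accepted when some
#' sliding window of `window` aligned bases reaches `threshold` identity
#' (the conventional 70 %/100 bp conservation criterion); exons shorter
#' than the window are scored over their whole aligned length.
#'
#' @param threshold identity fraction in (0, 1] (default 0.70).
#' @param window window size in aligned bases (default 100).
#' @export
projection_config <- function(threshold = 0.70, window = 100) {
  stopifnot(threshold > 0, threshold <= 1, window >= 1)
  structure(list(threshold = threshold, window = window),
            class = "projection_config")
}

#' Match orthologous exons between two annotated assemblies
#'
#' For every ortholog gene pair, each exon of the first species is mapped
#' through the pairwise alignment; exon pairs whose mapped span overlaps an
#' annotated exon of the partner gene by at least one base are emitted,
#' provided the ungapped identity over the aligned exon reaches the
#' projection threshold.  Genes listed in the ortholog table but absent
#' from an annotation are skipped with a warning.
#'
#' @param annot_a,annot_b exon annotations (from [read_annotation()]) on
#'   the alignment's query and target assemblies.
#' @param orthologs long-format ortholog table with columns `cluster`,
#'   `species`, `gene_id`.
#' @param aln `pairwise_alignment` from species A to species B.
#' @param cfg a [projection_config()].
#' @return data.frame of exon matches with `support = "annotated-both"`.
#' @export
match_exons <- function(annot_a, annot_b, orthologs, aln,
                        cfg = projection_config()) {
  sp_a <- annot_a$assembly[1]; sp_b <- annot_b$assembly[1]
  stopifnot(sp_a == aln$query_assembly, sp_b == aln$target_assembly)
  out <- list()
  for (cl in unique(orthologs$cluster)) {
    sub <- orthologs[orthologs$cluster == cl, , drop = FALSE]
    ga <- sub$gene_id[sub$species == sp_a]
    gb <- sub$gene_id[sub$species == sp_b]
    if (length(ga) != 1L || length(gb) != 1L) next
    ea <- annot_a[annot_a$gene_id == ga, , drop = FALSE]
    eb <- annot_b[annot_b$gene_id == gb, , drop = FALSE]
    if (nrow(ea) == 0L || nrow(eb) == 0L) {
      warning("ortholog cluster ", cl, ": gene ",
              if (nrow(ea) == 0L) ga else gb, " absent from annotation; skipped")
      next
    }
    for (i in seq_len(nrow(ea))) {
      exon_a <- ea[i, , drop = FALSE]
      mapped <- map_interval(exon_a, aln)
      if (is.null(mapped)) next
      hit <- which(eb$chrom == mapped$chrom & eb$start < mapped$end &
                     eb$end > mapped$start)
      if (length(hit) == 0L) next
      m <- aligned_matches(exon_a, aln)
      identity <- if (length(m)) mean(m) else 0
      if (identity < cfg$threshold) next
      for (j in hit) {
        out[[length(out) + 1L]] <- data.frame(
          species_a = sp_a, gene_a = ga, chrom_a = exon_a$chrom,
          start_a = exon_a$start, end_a = exon_a$end, rank_a = exon_a$exon_rank,
          species_b = sp_b, gene_b = gb, chrom_b = eb$chrom[j],
          start_b = eb$start[j], end_b = eb$end[j], rank_b = eb$exon_rank[j],
          support = "annotated-both", identity = identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Project an exon onto an unannotated assembly
#'
#' Maps the exon through the pairwise alignment and accepts the projection
#' if some sliding window of `cfg$window` aligned bases reaches
#' `cfg$threshold` identity (whole-exon window for shorter exons).
#'
#' @param exon single-row annotation `gint` (query assembly).
#' @param aln `pairwise_alignment` whose query is the exon's assembly.
#' @param cfg a [projection_config()].
#' @param gene_b optional partner gene id to stamp on the projected match
#'   (e.g. from the ortholog table).
#' @return a one-row exon-match data.frame with `support = "projected"`,
#'   or `NULL` if the exon is unmappable or below threshold.
#' @export
project_exon <- function(exon, aln, cfg = projection_config(), gene_b = NA) {
  mapped <- map_interval(exon, aln)
  if (is.null(mapped)) return(NULL)
  m <- aligned_matches(exon, aln)
  if (length(m) == 0L) return(NULL)
  identity <- if (length(m) < cfg$window) mean(m) else {
    cs <- c(0, cumsum(m))
    w <- cfg$window
    max((cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w)
  }
  if (identity < cfg$threshold) return(NULL)
  data.frame(species_a = exon$assembly, gene_a = exon$gene_id,
             chrom_a = exon$chrom, start_a = exon$start, end_a = exon$end,
             rank_a = exon$exon_rank,
             species_b = aln$target_assembly, gene_b = gene_b,
             chrom_b = mapped$chrom, start_b = mapped$start,
             end_b = mapped$end, rank_b = NA_integer_,
             support = "projected", identity = identity,
             stringsAsFactors = FALSE)
}

# full exon list of a gene on the B side: annotated exons of gene_b merged
# with projected exons for it, sorted by start
b_side_exons <- function(annot_b, matches_b, gene_b) {
  ann <- if (!is.null(annot_b)) annot_b[annot_b$gene_id %in% gene_b, , drop = FALSE]
  ex <- unique(rbind(
    if (!is.null(ann) && nrow(ann))
      data.frame(start = ann$start, end = ann$end, stringsAsFactors = FALSE),
    data.frame(start = matches_b$start_b, end = matches_b$end_b,
               stringsAsFactors = FALSE)))
  ex[order(ex$start), , drop = FALSE]
}

#' Derive orthologous introns from exon matches
#'
#' Takes exon matches from a pivot reference species to each of the other
#' reference species and emits one orthologous-intron set per pair of
#' pivot-adjacent matched exons whose partners are adjacent (no intervening
#' annotated or projected exon of the same gene) in every other species.
#' Ambiguous matches (an exon matched to several partners) and
#' inconsistent exon orders cause the candidate set to be skipped with a
#' message, never mis-assigned.
#'
#' @param matches named list (by partner species) of exon-match
#'   data.frames sharing the same pivot `species_a`.
#' @param annotations named list of exon annotations by species (pivot
#'   included; partner species may be absent if fully projected).
#' @return long-format data.frame: one row per (intron set, species) with
#'   `set_id`, `species`, `gene_id`, `chrom`, `start`, `end`.
#' @export
derive_introns <- function(matches, annotations) {
  stopifnot(length(matches) >= 1)
  pivots <- unique(unlist(lapply(matches, function(m) m$species_a)))
  stopifnot(length(pivots) == 1L)
  pivot <- pivots
  annot_p <- annotations[[pivot]]
  out <- list()
  for (gene in unique(annot_p$gene_id)) {
    ep <- annot_p[annot_p$gene_id == gene, , drop = FALSE]
    ep <- ep[order(ep$start), , drop = FALSE]
    if (nrow(ep) < 2L) next
    for (i in seq_len(nrow(ep) - 1L)) {
      left <- ep[i, ]; right <- ep[i + 1L, ]
      if (right$start <= left$end) next
      rows <- list(data.frame(species = pivot, gene_id = gene,
                              chrom = left$chrom, start = left$end,
                              end = right$start, stringsAsFactors = FALSE))
      ok <- TRUE
      for (sp in names(matches)) {
        m <- matches[[sp]]
        m <- m[m$gene_a == gene, , drop = FALSE]
        ml <- m[m$start_a == left$start & m$end_a == left$end, , drop = FALSE]
        mr <- m[m$start_a == right$start & m$end_a == right$end, , drop = FALSE]
        if (nrow(ml) != 1L || nrow(mr) != 1L) { ok <- FALSE; break }
        gene_b <- unique(stats::na.omit(c(ml$gene_b, mr$gene_b)))
        if (length(gene_b) > 1L) {
          message("gene ", gene, ": partners in different ", sp,
                  " genes; set skipped")
          ok <- FALSE; break
        }
        if (!is.na(ml$chrom_b) && !is.na(mr$chrom_b) &&
            ml$chrom_b != mr$chrom_b) { ok <- FALSE; break }
        full <- b_side_exons(annotations[[sp]], m,
                             if (length(gene_b)) gene_b else character(0))
        bl <- m[m$start_a == left$start, c("start_b", "end_b")]
        br <- m[m$start_a == right$start, c("start_b", "end_b")]
        lo <- min(bl$start_b, br$start_b); hi <- max(bl$start_b, br$start_b)
        il <- which(full$start == lo); ir <- which(full$start == hi)
        if (length(il) != 1L || length(ir) != 1L || ir - il != 1L) {
          message("gene ", gene, ": matched exons not adjacent in ", sp,
                  "; set skipped")
          ok <- FALSE; break
        }
        b_left_end <- full$end[il]; b_right_start <- full$start[ir]
        if (b_right_start <= b_left_end) { ok <- FALSE; break }
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, gene_id = if (length(gene_b)) gene_b else NA_character_,
          chrom = ml$chrom_b, start = b_left_end, end = b_right_start,
          stringsAsFactors = FALSE)
      }
      if (!ok) next
      set <- do.call(rbind, rows)
      set$set_id <- paste0(gene, ".i", i)
      out[[length(out) + 1L]] <- set[, c("set_id", "species", "gene_id",
                                         "chrom", "start", "end")]
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
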
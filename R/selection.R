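#' Candidate selection configuration
#'
#' @param max_ecrs_per_group maximum conserved regions per group in a
#'   retained intron set (default 3; the stricter validation-style
#'   selection uses 2).
#' @param positive_mark,negative_mark labels of the enhancer-associated
#'   and promoter-associated histone marks.
#' @param go_terms Gene Ontology term labels, matched exactly against the
#'   provided gene-to-GO table (no ontology traversal).
#' @export
selection_config <- function(max_ecrs_per_group = 3,
                             positive_mark = "H3K4me1",
                             negative_mark = "H3K4me3",
                             go_terms = c("developmental process",
                                          "anatomical structure development")) {
  stopifnot(max_ecrs_per_group >= 1)
  structure(as.list(environment()), class = "selection_config")
}

#' Group conserved regions into syntenic intron sets
#'
#' Assigns each region to the orthologous intron that fully contains it
#' (regions crossing an exon boundary are excluded with a warning) and
#' retains only intron sets holding at least one region in every group —
#' the syntenic-ECR criterion.
#'
#' @param intron_sets long-format orthologous-intron table from
#'   [derive_introns()] (columns `set_id`, `species`, `gene_id`, `chrom`,
#'   `start`, `end`).
#' @param ecrs_by_group named list (by group label) of `gint` region sets;
#'   each group's regions must be on the assembly named in `group_refs`.
#' @param group_refs named character vector: group label -> reference
#'   species as used in `intron_sets`.
#' @return list of syntenic sets; each has `set_id`, `genes`, and `ecrs`
#'   (named list by group of `gint` subsets).
#' @export
group_syntenic <- function(intron_sets, ecrs_by_group, group_refs) {
  stopifnot(all(names(ecrs_by_group) %in% names(group_refs)))
  out <- list()
  for (sid in unique(intron_sets$set_id)) {
    set <- intron_sets[intron_sets$set_id == sid, , drop = FALSE]
    per_group <- list()
    complete <- TRUE
    for (g in names(ecrs_by_group)) {
      sp <- group_refs[[g]]
      intr <- set[set$species == sp, , drop = FALSE]
      if (nrow(intr) != 1L) { complete <- FALSE; break }
      e <- ecrs_by_group[[g]]
      inside <- e$chrom == intr$chrom & e$start >= intr$start & e$end <= intr$end
      partial <- e$chrom == intr$chrom & e$start < intr$end &
        e$end > intr$start & !inside
      if (any(partial))
        warning(sum(partial), " region(s) cross an exon boundary of ",
                sid, " in group ", g, "; excluded")
      if (!any(inside)) { complete <- FALSE; break }
      per_group[[g]] <- e[inside, , drop = FALSE]
    }
    if (!complete) next
    genes <- stats::setNames(set$gene_id, set$species)
    out[[length(out) + 1L]] <- list(set_id = sid, genes = genes,
                                    ecrs = per_group)
  }
  out
}

#' Partition conserved regions by histone-mark overlap
#'
#' A region is `marked` when it overlaps the positive mark (H3K4me1, the
#' distal-enhancer mark) by at least one base and does not overlap the
#' negative mark (H3K4me3, the promoter mark).  Regions overlapping both
#' are tracked separately; the three outputs partition the input.  When a
#' group has no mark data (`positive_peaks = NULL`, as for bird species),
#' all regions pass through unfiltered with a notice.
#'
#' @param ecrs `gint` of conserved regions.
#' @param positive_peaks,negative_peaks `gint` peak sets on the same
#'   assembly, or `NULL` when unavailable.
#' @return list with `marked`, `unmarked`, `both_marked`, and
#'   `had_data` (FALSE when marks were unavailable).
#' @export
mark_filter <- function(ecrs, positive_peaks, negative_peaks = NULL) {
  if (is.null(positive_peaks)) {
    message("no histone-mark data for assembly ",
            if (nrow(ecrs)) ecrs$assembly[1] else "?",
            ": regions pass through unfiltered")
    return(list(marked = ecrs, unmarked = ecrs[0, , drop = FALSE],
                both_marked = ecrs[0, , drop = FALSE], had_data = FALSE))
  }
  pos <- rep(FALSE, nrow(ecrs)); neg <- rep(FALSE, nrow(ecrs))
  if (nrow(ecrs)) {
    pos[unique(gi_overlaps(ecrs, positive_peaks)$query)] <- TRUE
    if (!is.null(negative_peaks) && nrow(negative_peaks))
      neg[unique(gi_overlaps(ecrs, negative_peaks)$query)] <- TRUE
  }
  marked <- ecrs[pos & !neg, , drop = FALSE]
  if (nrow(marked) && "stage" %in% names(marked)) marked$stage <- "marked"
  list(marked = marked,
       unmarked = ecrs[!pos & !neg | (!pos & neg), , drop = FALSE],
       both_marked = ecrs[pos & neg, , drop = FALSE],
       had_data = TRUE)
}

#' Prioritize syntenic sets by marks, multiplicity and gene ontology
#'
#' Retains sets whose per-group region counts do not exceed the maximum,
#' whose host gene carries at least one configured GO term, and ranks by
#' (number of groups with marked regions, descending; then number of
#' single-region groups, descending) to favor univocal correspondence.
#'
#' @param sets list of syntenic sets from [group_syntenic()].
#' @param marked_by_group named list (by group) of `gint`s of regions that
#'   passed [mark_filter()]; groups without mark data should map to `NULL`
#'   (treated as all-marked for ranking, per the pass-through rule).
#' @param gene_go data.frame with `gene_id`, `go_term`.
#' @param cfg a [selection_config()].
#' @param go_species species whose gene id keys the GO lookup (default:
#'   first species of each set's `genes`).
#' @return data.frame, one row per retained set, ranked; with columns
#'   `set_id`, `rank`, per-group counts, `n_marked_groups`, `n_univocal`.
#' @export
prioritize <- function(sets, marked_by_group, gene_go,
                       cfg = selection_config(), go_species = NULL) {
  rows <- list()
  for (s in sets) {
    counts <- vapply(s$ecrs, nrow, 1L)
    if (any(counts > cfg$max_ecrs_per_group)) next
    gene <- if (is.null(go_species)) s$genes[[1]] else s$genes[[go_species]]
    terms <- gene_go$go_term[gene_go$gene_id == gene]
    if (length(terms) == 0L) {
      message("gene ", gene, " absent from GO table; set ", s$set_id,
              " dropped")
      next
    }
    if (!any(terms %in% cfg$go_terms)) next
    n_marked <- 0L
    for (g in names(s$ecrs)) {
      mk <- marked_by_group[[g]]
      if (is.null(mk)) { n_marked <- n_marked + 1L; next }  # no data: pass
      ov <- gi_overlaps(s$ecrs[[g]], mk)
      # marked means the identical region survived the mark filter
      same <- any(s$ecrs[[g]]$start[ov$query] == mk$start[ov$subject] &
                    s$ecrs[[g]]$end[ov$query] == mk$end[ov$subject])
      if (same) n_marked <- n_marked + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = s$set_id, t(counts), n_marked_groups = n_marked,
      n_univocal = sum(counts == 1L), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(-df$n_marked_groups, -df$n_univocal, df$set_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Per-stage cascade counts
#'
#' Convenience accounting of how many regions survive each filter stage,
#' mirroring the shrinking rows of a selection cascade table.
#'
#' @param ... named integer counts in stage order.
#' @return data.frame with `stage` and `count`; counts must be
#'   non-increasing.
#' @export
cascade_counts <- function(...) {
  v <- c(...)
  if (isTRUE(any(diff(v) > 0, na.rm = TRUE)))
    warning("cascade counts increase between stages")
  data.frame(stage = names(v), count = as.integer(v), stringsAsFactors = FALSE)
}
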
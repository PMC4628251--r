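#' Run the full candidate-enhancer cascade on a study bundle
#'
#' Convenience driver used by the examples and the acceptance suite:
#' fits a neutral model per group from the neutral-training alignment,
#' calls conserved regions with the two-state phylo-HMM, resolves heavy
#' overlaps, removes regions conserved between groups (alignment overlap,
#' then seed-and-extend homology search against the other references),
#' derives orthologous introns from exon matches, assembles syntenic sets
#' and prioritizes them by histone marks and GO terms.
#'
#' @param bundle a `study_bundle` from [generate_study()].
#' @param csm a [conserved_state_model()].
#' @param hcfg a [homology_config()].
#' @param scfg a [selection_config()].
#' @param pcfg a [projection_config()].
#' @param family substitution-model family for the neutral fit.
#' @param min_ecr_length minimum conserved-element length (bp).
#' @return list with per-stage results: `neutral`, `ecrs_raw`, `ecrs`,
#'   `removed`, `intron_sets`, `syntenic`, `marked`, `candidates`,
#'   `cascade` (per-group survivor counts by stage).
#' @export
run_pipeline <- function(bundle, csm = conserved_state_model(),
                         hcfg = homology_config(), scfg = selection_config(),
                         pcfg = projection_config(), family = "HKY85",
                         min_ecr_length = 10) {
  refs <- bundle$references            # named: group label -> reference species
  groups <- names(refs)

  neutral <- lapply(groups, function(g)
    fit_neutral(columns_from_maf(bundle$neutral_mafs[[g]]),
                bundle$cfg$groups[[match(g, groups)]]$tree, family = family))
  names(neutral) <- groups

  ecrs_raw <- lapply(groups, function(g) {
    seg <- segment_conserved(bundle$group_mafs[[g]], neutral[[g]], csm,
                             min_ecr_length = min_ecr_length, group = g)
    resolve_overlaps(seg$ecrs)
  })
  names(ecrs_raw) <- groups

  # cross-group removal: alignment overlap, then homology search
  ecrs <- list(); removed <- list()
  for (g in groups) {
    ref <- refs[[g]]
    alns <- list()
    for (nm in names(bundle$inter_alns)) {
      sps <- strsplit(nm, "_")[[1]]
      if (ref %in% sps)
        alns[[nm]] <- as_pairwise(bundle$inter_alns[[nm]], sps[1], sps[2])
    }
    step1 <- remove_aligned(ecrs_raw[[g]], alns)
    other <- lapply(refs[setdiff(groups, g)], function(sp)
      stats::setNames(bundle$genomes[sp], bundle$chrom))
    names(other) <- refs[setdiff(groups, g)]
    step2 <- homology_filter(step1$kept,
                             stats::setNames(bundle$genomes[ref], bundle$chrom),
                             other, hcfg)
    ecrs[[g]] <- step2$kept
    removed[[g]] <- rbind(step1$removed, step2$removed)
  }

  # orthologous introns: pivot = first group's reference
  pivot <- refs[[1]]
  matches <- list()
  for (g in groups[-1]) {
    ref <- refs[[g]]
    nm <- if (paste0(pivot, "_", ref) %in% names(bundle$inter_alns))
      paste0(pivot, "_", ref) else paste0(ref, "_", pivot)
    aln <- as_pairwise(bundle$inter_alns[[nm]], pivot, ref)
    matches[[ref]] <- match_exons(bundle$annotations[[pivot]],
                                  bundle$annotations[[ref]],
                                  bundle$orthologs, aln, pcfg)
  }
  intron_sets <- derive_introns(matches, bundle$annotations)

  syntenic <- group_syntenic(intron_sets, ecrs, refs)

  marked <- list()
  for (g in groups) {
    ref <- refs[[g]]
    mk <- bundle$marks[[ref]]
    if (is.null(mk)) { marked[[g]] <- NULL; next }
    marked[[g]] <- mark_filter(ecrs[[g]], mk$me1, mk$me3)$marked
  }

  candidates <- prioritize(syntenic, marked, bundle$go, scfg,
                           go_species = pivot)

  cascade <- lapply(groups, function(g) cascade_counts(
    conserved = nrow(ecrs_raw[[g]]),
    not_intergroup = nrow(ecrs[[g]]),
    in_complete_sets = sum(vapply(syntenic, function(s) nrow(s$ecrs[[g]]), 0L)),
    marked = if (is.null(marked[[g]])) NA_integer_ else nrow(marked[[g]])))
  names(cascade) <- groups

  list(neutral = neutral, ecrs_raw = ecrs_raw, ecrs = ecrs, removed = removed,
       intron_sets = intron_sets, syntenic = syntenic, marked = marked,
       candidates = candidates, cascade = cascade)
}
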
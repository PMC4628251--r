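#' The reporter-assay validation panel
#'
#' The package ships the coordinates and per-tissue expression
#' annotations of the zebrafish and mouse enhancer constructs that were
#' subjected to transgenic validation in zebrafish: 13 positive zebrafish
#' regions and the mouse regions from the orthologous introns (zebrafish
#' regions 10 and 11 are syntenic to a single mouse region; regions 3 and
#' 5 had no testable mouse construct).  Coordinates are 1-based inclusive
#' browser spans on danRer7/mm9 and are converted to the internal
#' convention on load.
#'
#' @return `validation_panel()`: data.frame with `ecr`, `species`,
#'   `assembly`, `status` and (for tested constructs) `chrom`, `start`,
#'   `end` plus `length_bp`, the inclusive span length.
#' @export
validation_panel <- function() {
  path <- system.file("extdata", "validation_panel.tsv", package = "sef")
  tab <- read_tsv(path)
  has_region <- tab$region != "."
  coords <- parse_region(tab$region[has_region])
  tab$chrom <- tab$start <- tab$end <- NA
  tab$chrom[has_region] <- coords$chrom
  tab$start[has_region] <- coords$start
  tab$end[has_region] <- coords$end
  tab$length_bp <- tab$end - tab$start
  tab$region <- NULL
  tab
}

#' @rdname validation_panel
#' @return `validation_expression()`: data.frame with `ecr`, `species`,
#'   `tissue`, `time` — the annotated positive (tissue, time point)
#'   expression calls of every construct (unioned over constructs when an
#'   enhancer had several).
#' @export
validation_expression <- function() {
  read_tsv(system.file("extdata", "validation_expression.tsv", package = "sef"))
}

#' Functionally homologous enhancers of the validation panel
#'
#' Runs the cross-species consistency logic over the shipped expression
#' annotations: for every enhancer with calls in both species, the shared
#' (tissue, time) set after synonym normalization; enhancers with a
#' non-empty intersection are functionally homologous.
#'
#' @param synonyms tissue synonym map (default
#'   [default_tissue_synonyms()]).
#' @return named list (by enhancer id) of shared-call data.frames,
#'   restricted to functionally homologous enhancers.
#' @export
functionally_homologous_ecrs <- function(synonyms = default_tissue_synonyms()) {
  expr <- validation_expression()
  out <- list()
  for (e in unique(expr$ecr)) {
    zf <- expr[expr$ecr == e & expr$species == "zf", , drop = FALSE]
    mm <- expr[expr$ecr == e & expr$species == "mm", , drop = FALSE]
    if (nrow(zf) == 0L || nrow(mm) == 0L) next
    shared <- cross_species_consistency(zf, mm, synonyms)
    if (attr(shared, "functionally_homologous"))
      out[[as.character(e)]] <- shared
  }
  out
}

#' Zebrafish-mouse length pairs of the syntenic enhancer sets
#'
#' For each functionally homologous enhancer, the inclusive lengths of
#' the zebrafish region and its syntenic mouse region — the `(m, n)`
#' inputs of the Karlin-Altschul chance-expectation calculus.
#'
#' @inheritParams functionally_homologous_ecrs
#' @return data.frame with `ecr`, `zf_length`, `mm_length`.
#' @export
syntenic_pair_lengths <- function(synonyms = default_tissue_synonyms()) {
  hom <- names(functionally_homologous_ecrs(synonyms))
  panel <- validation_panel()
  rows <- lapply(hom, function(e) {
    zf <- panel[panel$ecr == e & panel$species == "zf", , drop = FALSE]
    mm <- panel[panel$ecr == e & panel$species == "mm" &
                  panel$status == "positive", , drop = FALSE]
    data.frame(ecr = e, zf_length = zf$length_bp[1],
               mm_length = mm$length_bp[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
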
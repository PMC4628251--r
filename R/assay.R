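#' Reporter-assay scoring configuration
#'
#' A construct is positive in a (tissue, time point) when the adjusted
#' expressing proportion — expressing fish minus ectopic fish, over fish
#' alive, minus the empty-vector background proportion for that tissue and
#' time — reaches the threshold (default 15 %).
#'
#' @param threshold positivity threshold as a fraction (default 0.15).
#' @param background empty-vector expression table (same columns as the
#'   construct table), or `NULL` for zero background everywhere.
#' @export
assay_config <- function(threshold = 0.15, background = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(threshold = threshold, background = background),
            class = "assay_config")
}

validate_expression_table <- function(tab) {
  need <- c("construct", "time", "tissue", "n_expressing", "n_ectopic", "n_alive")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$n_expressing > tab$n_alive))
    stop("expression table: n_expressing exceeds n_alive")
  if (any(tab$n_ectopic > tab$n_expressing))
    stop("expression table: n_ectopic exceeds n_expressing")
  if (any(c(tab$n_expressing, tab$n_ectopic) < 0))
    stop("expression table: negative counts")
  if (!all(tab$time %in% c(24, 48)))
    stop("expression table: time points must be 24 or 48 hpf")
  tab
}

#' Call positive enhancer activity from an expression count table
#'
#' @param table expression table: one row per (construct, time, tissue)
#'   with counts of expressing, ectopic and alive fish.
#' @param cfg an [assay_config()]; missing background (tissue, time)
#'   combinations default to 0 with a notice.  Rows with no surviving
#'   fish are skipped with a warning.
#' @return data.frame of positive calls with the adjusted proportion.
#' @export
call_positive <- function(table, cfg = assay_config()) {
  table <- validate_expression_table(table)
  bg <- cfg$background
  if (!is.null(bg)) bg <- validate_expression_table(bg)
  bg_prop <- function(tissue, time) {
    if (is.null(bg)) return(0)
    r <- bg[bg$tissue == tissue & bg$time == time, , drop = FALSE]
    if (nrow(r) == 0L) {
      message("no background for (", tissue, ", ", time, " hpf): using 0")
      return(0)
    }
    sum(r$n_expressing - r$n_ectopic) / sum(r$n_alive)
  }
  out <- list()
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    if (r$n_alive == 0) {
      warning("construct ", r$construct, " (", r$tissue, ", ", r$time,
              " hpf): no fish alive; row skipped")
      next
    }
    adj <- (r$n_expressing - r$n_ectopic) / r$n_alive - bg_prop(r$tissue, r$time)
    if (adj >= cfg$threshold)
      out[[length(out) + 1L]] <- data.frame(
        construct = r$construct, tissue = r$tissue, time = r$time,
        adjusted = adj, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(construct = character(0), tissue = character(0),
                  time = numeric(0), adjusted = numeric(0),
                  stringsAsFactors = FALSE)
}

#' Default homologous-tissue synonym map
#'
#' The olfactory epithelium is the sensory component of the olfactory
#' bulb, so calls in either are treated as the same tissue when comparing
#' across species; user-extensible.
#'
#' @return data.frame with `from`, `to` canonical label pairs.
#' @export
default_tissue_synonyms <- function() {
  data.frame(from = "olfactory bulb", to = "olfactory epithelium",
             stringsAsFactors = FALSE)
}

normalize_tissue <- function(tissue, synonyms) {
  t <- tolower(trimws(tissue))
  if (!is.null(synonyms) && nrow(synonyms)) {
    m <- match(t, tolower(synonyms$from))
    t[!is.na(m)] <- tolower(synonyms$to[m[!is.na(m)]])
  }
  t
}

#' Shared expression calls between two species' constructs
#'
#' Intersects the (tissue, time) positive calls of two constructs after
#' tissue-synonym normalization; a syntenic region pair is functionally
#' homologous when the intersection is non-empty.  Symmetric in its two
#' arguments; unknown tissue labels are kept verbatim.
#'
#' @param calls_sp1,calls_sp2 outputs of [call_positive()] (or any frames
#'   with `tissue` and `time`).
#' @param synonyms synonym map as in [default_tissue_synonyms()], or `NULL`.
#' @return data.frame of shared `tissue` (canonical, lower case) and
#'   `time`; attribute `functionally_homologous` is TRUE when non-empty.
#' @export
cross_species_consistency <- function(calls_sp1, calls_sp2,
                                      synonyms = default_tissue_synonyms()) {
  k1 <- unique(data.frame(tissue = normalize_tissue(calls_sp1$tissue, synonyms),
                          time = calls_sp1$time, stringsAsFactors = FALSE))
  k2 <- unique(data.frame(tissue = normalize_tissue(calls_sp2$tissue, synonyms),
                          time = calls_sp2$time, stringsAsFactors = FALSE))
  shared <- merge(k1, k2, by = c("tissue", "time"))
  shared <- shared[order(shared$tissue, shared$time), , drop = FALSE]
  rownames(shared) <- NULL
  attr(shared, "functionally_homologous") <- nrow(shared) > 0
  shared
}
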
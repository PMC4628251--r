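#' Two-state conserved/neutral HMM parameters
#'
#' The conserved state is the neutral model with every branch length
#' multiplied by `rho` (0 < rho < 1, default 0.3).  Transition
#' probabilities follow the usual conservation-HMM parameterization:
#' leaving conserved with `mu = 1/expected_length` and entering it with
#' `nu = mu * coverage / (1 - coverage)`, so the stationary conserved
#' fraction equals `coverage`.
#'
#' @param rho branch scaling of the conserved state, in (0, 1).
#' @param expected_length expected conserved-element length in bp (default 45).
#' @param coverage stationary fraction of conserved bases (default 0.3).
#' @return an object of class `conserved_state_model`.
#' @export
conserved_state_model <- function(rho = 0.3, expected_length = 45,
                                  coverage = 0.3) {
  stopifnot(rho > 0, rho < 1, expected_length > 1, coverage > 0, coverage < 1)
  mu <- 1 / expected_length
  nu <- mu * coverage / (1 - coverage)
  stopifnot(mu > 0, mu < 1, nu > 0, nu < 1)
  structure(list(rho = rho, expected_length = expected_length,
                 coverage = coverage, mu = mu, nu = nu),
            class = "conserved_state_model")
}

# scaled forward-backward + Viterbi for the 2-state chain
# emis: matrix n x 2 of column likelihoods (neutral, conserved)
hmm_decode <- function(emis, csm) {
  n <- nrow(emis)
  A <- matrix(c(1 - csm$nu, csm$nu, csm$mu, 1 - csm$mu), 2, 2, byrow = TRUE)
  init <- c(1 - csm$coverage, csm$coverage)
  f <- matrix(0, n, 2); cscale <- numeric(n)
  f[1, ] <- init * emis[1, ]
  cscale[1] <- sum(f[1, ]); f[1, ] <- f[1, ] / cscale[1]
  if (n > 1) for (t in 2:n) {
    f[t, ] <- (f[t - 1, ] %*% A) * emis[t, ]
    cscale[t] <- sum(f[t, ]); f[t, ] <- f[t, ] / cscale[t]
  }
  b <- matrix(0, n, 2); b[n, ] <- 1
  if (n > 1) for (t in (n - 1):1)
    b[t, ] <- (A %*% (emis[t + 1, ] * b[t + 1, ])) / cscale[t + 1]
  post <- f * b
  post <- post / rowSums(post)
  # Viterbi in log space
  lA <- log(A); lE <- log(pmax(emis, 1e-300))
  v <- matrix(-Inf, n, 2); ptr <- matrix(0L, n, 2)
  v[1, ] <- log(init) + lE[1, ]
  if (n > 1) for (t in 2:n) for (s in 1:2) {
    cand <- v[t - 1, ] + lA[, s]
    ptr[t, s] <- which.max(cand)
    v[t, s] <- cand[ptr[t, s]] + lE[t, s]
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  list(posterior = post, viterbi = path, loglik = sum(log(cscale)))
}

# per-column emission likelihoods of a MAF block under neutral/conserved
block_emissions <- function(block, nm, rho) {
  chars <- do.call(rbind, strsplit(block$text, ""))
  rownames(chars) <- block$species
  key <- apply(chars, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  pats <- encode_bases(chars[, uniq, drop = FALSE])
  idx <- match(key, key[uniq])
  lik_n <- prune_patterns(pats, nm, 1)[idx]
  lik_c <- prune_patterns(pats, nm, rho)[idx]
  cbind(neutral = lik_n, conserved = lik_c)
}

#' Call evolutionarily conserved regions from a multiple alignment
#'
#' Runs the two-state phylogenetic HMM over every alignment block.  Column
#' emissions are pruning likelihoods under the neutral model and under the
#' conserved model (branch lengths x rho); gaps and Ns are marginalized.
#' Conserved elements (ECRs) are maximal runs of the Viterbi conserved
#' state projected onto the reference species' coordinates (columns where
#' the reference is gapped participate in the chain but contribute no
#' reference bases), kept when at least `min_ecr_length` reference bases
#' long.  The score of an element is the mean posterior probability of the
#' conserved state over its columns.
#'
#' @param aln a `maf_alignment`; rows must be leaves of the neutral tree.
#' @param neutral a `neutral_model`, or a named list of them keyed by
#'   chromosome class (with `chrom_class_map` naming each chromosome's
#'   class; unlisted chromosomes use `"autosome"`).
#' @param csm a `conserved_state_model`.
#' @param min_ecr_length minimum element length in reference bp (default 10).
#' @param chrom_class_map optional named character vector, chromosome ->
#'   class, to select between autosome and X neutral models.
#' @param group group label stamped on the output.
#' @return list with `ecrs` (a `gint` with `score`, `group`, `stage`
#'   columns) and `tracks` (per block: reference position, posterior,
#'   Viterbi state, and the block log-likelihood).
#' @export
segment_conserved <- function(aln, neutral, csm = conserved_state_model(),
                              min_ecr_length = 10, chrom_class_map = NULL,
                              group = "group") {
  if (length(aln$blocks) == 0L)
    return(list(ecrs = empty_ecrs(), tracks = list()))
  pick_model <- function(chrom) {
    if (inherits(neutral, "neutral_model")) return(neutral)
    cls <- if (!is.null(chrom_class_map) && chrom %in% names(chrom_class_map))
      chrom_class_map[[chrom]] else "autosome"
    neutral[[cls]]
  }
  ecrs <- list(); tracks <- list()
  for (bi in seq_along(aln$blocks)) {
    b <- aln$blocks[[bi]]
    ref <- match(aln$reference, b$species)
    if (is.na(ref)) stop("reference species ", aln$reference, " absent from block ", bi)
    if (b$strand[ref] != "+")
      stop("reference row must be forward-strand (block ", bi, ")")
    nm <- pick_model(b$chrom[ref])
    emis <- block_emissions(b, nm, csm$rho)
    dec <- hmm_decode(emis, csm)
    refchars <- strsplit(b$text[ref], "")[[1]]
    refgap <- refchars == "-"
    refpos <- b$start[ref] + cumsum(!refgap) - 1
    refpos[refgap] <- NA
    tracks[[bi]] <- list(chrom = b$chrom[ref], refpos = refpos,
                         posterior = dec$posterior[, 2], viterbi = dec$viterbi,
                         loglik = dec$loglik)
    r <- rle(dec$viterbi == 2L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      pos <- refpos[cols]; pos <- pos[!is.na(pos)]
      if (length(pos) == 0L) next
      s <- min(pos); e <- max(pos) + 1
      if (e - s < min_ecr_length) next
      ecrs[[length(ecrs) + 1L]] <- genomic_interval(
        aln$reference, b$chrom[ref], s, e, "+",
        score = mean(dec$posterior[cols, 2]), group = group, stage = "intronic")
    }
  }
  ecrs <- if (length(ecrs)) validate_gint(do.call(rbind, ecrs)) else empty_ecrs()
  list(ecrs = ecrs, tracks = tracks)
}

empty_ecrs <- function() {
  validate_gint(data.frame(assembly = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           strand = character(0), score = numeric(0),
                           group = character(0), stage = character(0),
                           stringsAsFactors = FALSE))
}

#' Resolve heavily overlapping conserved regions
#'
#' Whenever two regions overlap by more than `min_frac` of either region's
#' length, only the longer is retained (ties broken by higher score, then
#' leftmost start).  The rule is applied transitively until the set is
#' stable, and the result does not depend on input order.
#'
#' @param ecrs a `gint` of conserved regions on one assembly (with a
#'   `score` column; absent scores are treated as 0).
#' @param min_frac overlap fraction triggering resolution (default 0.9).
#' @return the retained subset, sorted by position.
#' @export
resolve_overlaps <- function(ecrs, min_frac = 0.9) {
  if (nrow(ecrs) == 0L) return(ecrs)
  score <- if (is.null(ecrs$score)) rep(0, nrow(ecrs)) else ecrs$score
  # canonical order: longer first, then higher score, then leftmost
  ord <- order(-(ecrs$end - ecrs$start), -score, ecrs$chrom, ecrs$start)
  x <- ecrs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(x))) {
      if (j == i || !keep[j]) next
      if (x$chrom[i] != x$chrom[j]) next
      ov <- min(x$end[i], x$end[j]) - max(x$start[i], x$start[j])
      if (ov <= 0) next
      wi <- x$end[i] - x$start[i]; wj <- x$end[j] - x$start[j]
      if (ov / wi > min_frac || ov / wj > min_frac) {
        # j comes later in canonical order: it is the shorter / lower-score
        if (j > i) keep[j] <- FALSE
      }
    }
  }
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract aligned columns from a MAF for model fitting
#'
#' @param maf a `maf_alignment`.
#' @param species leaf labels to keep (default: all species of the first
#'   block).
#' @return character matrix (species x columns) pooling all blocks;
#'   columns where any requested species is absent are dropped.
#' @export
columns_from_maf <- function(maf, species = NULL) {
  if (is.null(species)) species <- maf$blocks[[1]]$species
  mats <- list()
  for (b in maf$blocks) {
    if (!all(species %in% b$species)) next
    chars <- do.call(rbind, strsplit(b$text[match(species, b$species)], ""))
    rownames(chars) <- species
    mats[[length(mats) + 1L]] <- chars
  }
  if (length(mats) == 0L) stop("no blocks contain all requested species")
  do.call(cbind, mats)
}
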
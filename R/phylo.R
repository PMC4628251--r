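#' Nucleotide substitution models
#'
#' Reversible models with closed-form (JC69) or eigen-decomposed (HKY85)
#' transition probabilities.  Rate matrices are normalized to one expected
#' substitution per site per unit branch length, so branch lengths are in
#' substitutions/site.
#'
#' @param family `"JC69"` or `"HKY85"`.
#' @param pi equilibrium base frequencies in A, C, G, T order (sum 1);
#'   ignored for JC69.
#' @param kappa transition/transversion rate ratio (HKY85 only).
#' @return an object of class `subst_model`.
#' @examples
#' m <- subst_model("JC69")
#' prob_matrix(m, 0.2)
#' @export
subst_model <- function(family = c("JC69", "HKY85"),
                        pi = rep(0.25, 4), kappa = 2) {
  family <- match.arg(family)
  if (family == "JC69") pi <- rep(0.25, 4)
  stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-12, kappa > 0)
  names(pi) <- c("A", "C", "G", "T")
  obj <- list(family = family, pi = pi, kappa = kappa)
  if (family == "HKY85") {
    Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
    transit <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                      ncol = 2, byrow = TRUE)
    for (i in 1:4) for (j in 1:4) if (i != j) {
      is_ts <- any(transit[, 1] == names(pi)[i] & transit[, 2] == names(pi)[j])
      Q[i, j] <- ifelse(is_ts, kappa, 1) * pi[j]
    }
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(-diag(Q) * pi)         # 1 expected substitution/site/unit
    # symmetrize for a stable eigendecomposition (model is reversible)
    sq <- sqrt(pi)
    B <- diag(sq) %*% Q %*% diag(1 / sq)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    obj$eig <- list(vals = e$values,
                    right = diag(1 / sq) %*% e$vectors,
                    left = t(e$vectors) %*% diag(sq))
  }
  structure(obj, class = "subst_model")
}

#' @rdname subst_model
#' @param model a `subst_model`.
#' @param d branch length in substitutions/site (>= 0).
#' @return 4x4 transition probability matrix (rows: ancestral base).
#' @export
prob_matrix <- function(model, d) {
  stopifnot(d >= 0)
  if (model$family == "JC69") {
    same <- 0.25 + 0.75 * exp(-4 * d / 3)
    diff <- 0.25 - 0.25 * exp(-4 * d / 3)
    P <- matrix(diff, 4, 4, dimnames = list(names(model$pi), names(model$pi)))
    diag(P) <- same
  } else {
    P <- model$eig$right %*% diag(exp(model$eig$vals * d)) %*% model$eig$left
    P[P < 0] <- 0
    dimnames(P) <- list(names(model$pi), names(model$pi))
  }
  P
}

#' Neutral model: tree plus substitution model
#'
#' @param tree an `ape` phylo with branch lengths in substitutions/site.
#' @param model a `subst_model`.
#' @param chrom_class `"autosome"` or `"X"`; a run may carry separate
#'   neutral models per chromosome class (divergence is lower on X).
#' @return an object of class `neutral_model`.
#' @export
neutral_model <- function(tree, model, chrom_class = "autosome") {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= -1e-12))
  tree$edge.length <- pmax(tree$edge.length, 0)
  structure(list(tree = ape::reorder.phylo(tree, "postorder"), model = model,
                 chrom_class = chrom_class), class = "neutral_model")
}

BASES <- c("A", "C", "G", "T")

# Character matrix (leaves x sites) -> integer matrix 1..4 with NA for
# gaps/N/anything non-ACGT (missing data, marginalized in the pruning).
encode_bases <- function(chars) {
  m <- match(toupper(chars), BASES)
  dim(m) <- dim(chars)
  dimnames(m) <- dimnames(chars)
  m
}

# Felsenstein pruning over many site patterns at once.
# patterns: integer matrix (n_leaf x n_pat), rownames = leaf labels, NA missing.
# Returns numeric vector of site likelihoods.
prune_patterns <- function(patterns, nm, scale = 1) {
  tree <- nm$tree
  tips <- tree$tip.label
  if (!all(rownames(patterns) %in% tips))
    stop("unknown leaf label(s): ",
         paste(setdiff(rownames(patterns), tips), collapse = ", "))
  npat <- ncol(patterns)
  nnode <- max(tree$edge)
  partial <- vector("list", nnode)
  for (i in seq_along(tips)) {
    row <- match(tips[i], rownames(patterns))
    Lp <- matrix(1, 4, npat)
    if (!is.na(row)) {
      obs <- patterns[row, ]
      known <- !is.na(obs)
      if (any(known)) {
        Lp[, known] <- 0
        Lp[cbind(obs[known], which(known))] <- 1
      }
    }
    partial[[i]] <- Lp
  }
  edges <- tree$edge
  for (k in seq_len(nrow(edges))) {          # postorder guarantees children first
    child <- edges[k, 2]; parent <- edges[k, 1]
    P <- prob_matrix(nm$model, tree$edge.length[k] * scale)
    up <- P %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) up else partial[[parent]] * up
  }
  root <- edges[nrow(edges), 1]
  as.numeric(nm$model$pi %*% partial[[root]])
}

#' Phylogenetic likelihood of one alignment column
#'
#' Computes the probability of the observed leaf bases under the neutral
#' model (optionally with all branch lengths scaled, as in the conserved
#' HMM state) by Felsenstein's pruning algorithm.  Gaps and Ns are missing
#' data and are marginalized; a column with all leaves missing has
#' likelihood 1.
#'
#' @param column named character vector of observed bases (names are leaf
#'   labels; subset of the tree's leaves).
#' @param nm a `neutral_model`.
#' @param scale positive branch-length scaling (1 = neutral).
#' @return the column likelihood, a probability.
#' @examples
#' tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
#' nm <- neutral_model(tr, subst_model("JC69"))
#' prune_likelihood(c(a = "A", b = "A"), nm)
#' @export
prune_likelihood <- function(column, nm, scale = 1) {
  stopifnot(scale > 0 || all(nm$tree$edge.length == 0))
  chars <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  prune_patterns(encode_bases(chars), nm, scale)
}

# Compress aligned columns (leaves x sites character matrix) to unique
# patterns with counts.
compress_patterns <- function(chars) {
  pats <- encode_bases(chars)
  key <- apply(pats, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = pats[, first, drop = FALSE], counts = as.numeric(tab))
}

#' Fit a neutral model to putatively neutral alignment columns
#'
#' Branch lengths (and, for HKY85, the transition/transversion ratio; base
#' frequencies are taken as the empirical frequencies) are estimated by
#' maximizing the product of per-column pruning likelihoods with L-BFGS-B
#' from a fixed starting point (all branches 0.1, kappa 2), so the fit is
#' deterministic for fixed inputs.  The intended input is columns at sites
#' evolving neutrally, e.g. 4-fold degenerate coding positions.
#'
#' @param chars character matrix, rows = leaf labels, columns = sites.
#' @param tree fixed topology (`phylo`; branch lengths ignored).
#' @param family substitution model family.
#' @param min_columns minimum number of columns required (default 500).
#' @param chrom_class stored on the returned model.
#' @return a fitted `neutral_model` with `logLik` attribute.
#' @export
fit_neutral <- function(chars, tree, family = c("JC69", "HKY85"),
                        min_columns = 500, chrom_class = "autosome") {
  family <- match.arg(family)
  if (ncol(chars) < min_columns)
    stop("need >= ", min_columns, " columns to fit a neutral model, got ",
         ncol(chars))
  cp <- compress_patterns(chars)
  nedge <- nrow(tree$edge)
  base_counts <- table(factor(toupper(chars)[toupper(chars) %in% BASES],
                              levels = BASES))
  pi_hat <- as.numeric(base_counts) / sum(base_counts)
  if (any(pi_hat == 0)) pi_hat <- (as.numeric(base_counts) + 1) / (sum(base_counts) + 4)
  nll <- function(par) {
    bl <- exp(par[seq_len(nedge)])
    model <- if (family == "JC69") subst_model("JC69") else
      subst_model("HKY85", pi = pi_hat, kappa = exp(par[nedge + 1]))
    tr <- tree; tr$edge.length <- NULL
    tr <- ape::reorder.phylo(tr, "postorder")
    tr$edge.length <- bl
    nm <- structure(list(tree = tr, model = model, chrom_class = chrom_class),
                    class = "neutral_model")
    lik <- prune_patterns(cp$patterns, nm, 1)
    -sum(cp$counts * log(pmax(lik, 1e-300)))
  }
  start <- c(rep(log(0.1), nedge), if (family == "HKY85") log(2))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = rep(log(1e-8), length(start)),
                      upper = rep(log(20), length(start)),
                      control = list(maxit = 500))
  bl <- exp(fit$par[seq_len(nedge)])
  if (sum(bl) < 1e-5)
    warning("all-identical columns: branch lengths fit at the zero boundary")
  model <- if (family == "JC69") subst_model("JC69") else
    subst_model("HKY85", pi = pi_hat, kappa = exp(fit$par[nedge + 1]))
  tr <- tree; tr$edge.length <- NULL
  tr <- ape::reorder.phylo(tr, "postorder")
  tr$edge.length <- bl
  out <- neutral_model(tr, model, chrom_class)
  attr(out, "logLik") <- -fit$value
  out
}

#' Serialize a neutral model to a small text file
#'
#' Newick tree plus model parameters, the `.mod`-style sidecar used by the
#' conservation stage.
#'
#' @param nm a `neutral_model`.
#' @param path file path.
#' @export
write_neutral_model <- function(nm, path) {
  lines <- c(paste0("FAMILY: ", nm$model$family),
             paste0("PI: ", paste(format(nm$model$pi, digits = 10), collapse = " ")),
             paste0("KAPPA: ", format(nm$model$kappa, digits = 10)),
             paste0("CHROM_CLASS: ", nm$chrom_class),
             paste0("TREE: ", ape::write.tree(nm$tree)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_neutral_model
#' @export
read_neutral_model <- function(path) {
  lines <- readLines(path)
  get <- function(key) sub(paste0("^", key, ": "), "",
                           grep(paste0("^", key, ": "), lines, value = TRUE)[1])
  family <- get("FAMILY")
  pi <- as.numeric(strsplit(get("PI"), " +")[[1]])
  kappa <- as.numeric(get("KAPPA"))
  tree <- ape::read.tree(text = get("TREE"))
  neutral_model(tree, subst_model(family, pi = pi, kappa = kappa),
                chrom_class = get("CHROM_CLASS"))
}
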
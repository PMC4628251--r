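#' Species groups for simulation
#'
#' A group is a clade of closely related species with a known tree (branch
#' lengths in substitutions/site at neutral sites); the first tip listed is
#' the group's reference species.  The defaults emulate a rodent-like, a
#' bird-like and a fish-like clade with within-group neutral divergences in
#' the range where conservation scoring is informative, and between-group
#' divergence deep enough that non-exonic sequence is unalignable.
#'
#' @param label group label.
#' @param tree_text Newick string with branch lengths.
#' @param reference reference species (default: first tip).
#' @return an object of class `sim_group`.
#' @export
sim_group <- function(label, tree_text, reference = NULL) {
  tree <- ape::read.tree(text = tree_text)
  if (is.null(tree$edge.length)) stop("group tree needs branch lengths")
  stopifnot(all(tree$edge.length >= 0))
  if (is.null(reference)) reference <- tree$tip.label[1]
  stopifnot(reference %in% tree$tip.label)
  structure(list(label = label, tree = tree, species = tree$tip.label,
                 reference = reference), class = "sim_group")
}

#' @rdname sim_group
#' @export
default_groups <- function() {
  list(
    sim_group("rodent", "((mm:0.10,rn:0.10):0.08,(cp:0.14,oc:0.14):0.04);"),
    sim_group("bird", "((gg:0.12,mg:0.12):0.06,tg:0.20);", reference = "gg"),
    sim_group("fish", "((dr:0.15,ga:0.15):0.05,((fr:0.08,tn:0.08):0.07,ol:0.16):0.04);",
              reference = "dr"))
}

#' Simulation configuration
#'
#' The default parameterization is the package's stated world: three groups
#' whose references carry orthologous genes with slowly evolving exons
#' (alignable between groups at ~80 % identity) and neutrally evolving
#' introns redrawn independently per group, with conserved elements planted
#' inside introns.  "True" elements evolve with branch scaling `ecr_rho`
#' within each group but have independently drawn sequences per group
#' except at planted motif positions, which carry identical n-mers (n >= 7)
#' in every group; "decoy" elements descend from one shared ancestor in all
#' groups and are therefore detectably conserved between groups.  An
#' outgroup annotation reference ("hs") is simulated as a close relative of
#' the first group's reference, giving a genome-wide pairwise alignment for
#' interval projection.
#'
#' @param groups list of `sim_group`s.
#' @param n_genes,exons_per_gene,exon_length,intron_length,intergenic_length
#'   gene architecture (bp).
#' @param model a `subst_model` used on every branch.
#' @param exon_scale within-group branch scaling of exons (purifying
#'   selection); `exon_deep` is the group-ancestor divergence of exons from
#'   the common ancestor, per group, in substitutions/site.
#' @param ecr_length,ecr_rho planted conserved-element length and
#'   within-group branch scaling (mirrors the conserved-state scaling 0.3).
#' @param n_true,n_decoy numbers of planted true/decoy elements, placed in
#'   distinct introns.
#' @param decoy_deep per-group divergence of decoy elements from their
#'   shared ancestor.
#' @param motif_pool n-mer strings (n >= 7) planted into true elements; two
#'   per element, identical across groups, strand randomized per insertion.
#' @param outgroup_divergence divergence of the "hs" outgroup reference
#'   from the first group's reference.
#' @param me1_fraction,me3_fraction fraction of true elements covered by an
#'   H3K4me1 peak / additionally by an H3K4me3 peak, in the species with
#'   mark data (first and last group's references; the bird-like group has
#'   none, as in real data).
#' @param activity_rate,background_rate,ectopic_rate,n_embryos reporter
#'   assay simulation: per-tissue expression rates and injected embryo
#'   count per construct.
#' @param indel_rate per-site deletion rate passed to the evolver (0 = off;
#'   the conservation HMM treats gaps as missing data).
#' @param seed integer seed; all outputs are pure functions of the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(groups = default_groups(),
                              n_genes = 6, exons_per_gene = 4,
                              exon_length = 150, intron_length = 1500,
                              intergenic_length = 400,
                              model = subst_model("HKY85",
                                                  pi = c(0.3, 0.2, 0.2, 0.3),
                                                  kappa = 3),
                              exon_scale = 0.2, exon_deep = 0.07,
                              ecr_length = 200, ecr_rho = 0.3,
                              n_true = 10, n_decoy = 3, decoy_deep = 0.03,
                              motif_pool = c("GATTACAG", "ACGCTTGT",
                                             "TTGACGCA", "CCATAGTC",
                                             "TGCAATCG", "AGTCCGTA"),
                              outgroup_divergence = 0.06,
                              me1_fraction = 0.7, me3_fraction = 0.1,
                              activity_rate = 0.30, background_rate = 0.02,
                              ectopic_rate = 0.08, n_embryos = 100,
                              indel_rate = 0, seed = 42) {
  stopifnot(all(nchar(motif_pool) >= 7), n_genes >= 1, exons_per_gene >= 2,
            ecr_length < intron_length, ecr_rho > 0, ecr_rho < 1,
            me1_fraction >= 0, me1_fraction <= 1,
            me3_fraction >= 0, me3_fraction <= 1)
  n_introns <- n_genes * (exons_per_gene - 1)
  if (n_true + n_decoy > n_introns)
    stop("more planted elements than introns: ", n_true + n_decoy, " > ", n_introns)
  structure(as.list(environment()), class = "simulation_config")
}

random_dna <- function(n, pi = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = pi), collapse = "")
}

# substitute (and optionally delete) along one branch; state vector coding:
# 1..4 = A,C,G,T, 0 = deleted.  masked positions are immutable.
mutate_branch <- function(states, d, model, masked = integer(0), indel_rate = 0) {
  out <- states
  live <- which(out > 0L)
  if (length(masked)) live <- setdiff(live, masked)
  if (length(live) && d > 0) {
    P <- prob_matrix(model, d)
    cum <- t(apply(P, 1, cumsum))
    s <- out[live]
    u <- stats::runif(length(live))
    out[live] <- 1L + (u > cum[cbind(s, 1)]) + (u > cum[cbind(s, 2)]) +
      (u > cum[cbind(s, 3)])
  }
  if (indel_rate > 0 && d > 0) {
    n_events <- stats::rpois(1, indel_rate * d * length(states))
    for (k in seq_len(n_events)) {
      len <- 1L + stats::rgeom(1, 0.3)
      at <- sample.int(length(states), 1)
      idx <- at:min(at + len - 1L, length(states))
      idx <- setdiff(idx, masked)
      out[idx] <- 0L
    }
  }
  out
}

#' Evolve a sequence along a tree
#'
#' Substitutions are applied per branch with expected substitutions/site
#' equal to branch length x `scale`; positions listed in `masked` never
#' mutate (used to keep planted motifs intact).  The optional indel process
#' is deletion-only: a deletion becomes a gap inherited by all descendants,
#' so the true alignment stays in root coordinates without bookkeeping.
#'
#' @param root_seq root nucleotide string (non-empty).
#' @param tree `phylo` with branch lengths.
#' @param model a `subst_model`.
#' @param scale positive branch-length scaling.
#' @param masked integer positions (1-based in the root sequence) exempt
#'   from mutation and deletion.
#' @param indel_rate per-site deletion event rate per substitution unit.
#' @return list with `leaves` (named character vector of ungapped leaf
#'   sequences) and `alignment` (named character vector of gapped rows in
#'   root coordinates; gapless when `indel_rate = 0`).
#' @export
evolve_on_tree <- function(root_seq, tree, model, scale = 1,
                           masked = integer(0), indel_rate = 0) {
  if (!nchar(root_seq)) stop("empty root sequence")
  stopifnot(scale >= 0)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root_states <- match(strsplit(toupper(root_seq), "")[[1]], BASES)
  if (anyNA(root_states)) stop("root sequence must be ACGT only")
  nnode <- max(tree$edge)
  states <- vector("list", nnode)
  root <- tree$edge[nrow(tree$edge), 1]
  states[[root]] <- root_states
  for (k in rev(seq_len(nrow(tree$edge)))) {   # preorder: parents before children
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    states[[child]] <- mutate_branch(states[[parent]],
                                     tree$edge.length[k] * scale, model,
                                     masked, indel_rate)
  }
  rows <- vapply(seq_len(ntip), function(i) {
    ch <- c("-", BASES)[states[[i]] + 1L]
    paste(ch, collapse = "")
  }, "")
  names(rows) <- tree$tip.label
  leaves <- gsub("-", "", rows)
  names(leaves) <- tree$tip.label
  list(leaves = leaves, alignment = rows)
}

# layout of one chromosome shared by every simulated species:
# spacer [exon intron]... exon spacer per gene
genome_layout <- function(cfg) {
  feats <- list(); pos <- 0
  add <- function(gene, type, idx, len) {
    feats[[length(feats) + 1L]] <<- data.frame(
      gene = gene, type = type, idx = idx, start = pos, end = pos + len,
      stringsAsFactors = FALSE)
    pos <<- pos + len
  }
  add(NA, "spacer", 0L, cfg$intergenic_length)
  for (g in seq_len(cfg$n_genes)) {
    gene <- paste0("g", g)
    for (e in seq_len(cfg$exons_per_gene)) {
      add(gene, "exon", e, cfg$exon_length)
      if (e < cfg$exons_per_gene) add(gene, "intron", e, cfg$intron_length)
    }
    add(NA, "spacer", g, cfg$intergenic_length)
  }
  out <- do.call(rbind, feats)
  out$feature <- ifelse(is.na(out$gene), paste0("spacer", out$idx),
                        paste0(out$gene, ".", out$type, out$idx))
  out
}

# default placement of planted elements: distinct introns, deterministic
# offsets inside the intron
place_elements <- function(cfg, layout) {
  introns <- layout[layout$type == "intron", , drop = FALSE]
  n <- cfg$n_true + cfg$n_decoy
  rows <- introns[sample.int(nrow(introns), n), , drop = FALSE]
  off <- 200 + (seq_len(n) %% 7) * 120
  off <- pmax(pmin(off, (rows$end - rows$start) - cfg$ecr_length - 50), 1)
  data.frame(ecr_id = paste0("ecr", seq_len(n)),
             kind = rep(c("true", "decoy"), c(cfg$n_true, cfg$n_decoy)),
             gene = rows$gene, intron_idx = rows$idx,
             start = rows$start + off, end = rows$start + off + cfg$ecr_length,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study bundle
#'
#' Produces, deterministically from the configuration seed, the full input
#' universe of the pipeline: per-species genomes, exon annotations for the
#' reference species and the outgroup, within-group multiple alignments
#' (per exon/intron feature), a neutral-training alignment per group (from
#' intergenic spacers, the stand-in for 4-fold degenerate sites),
#' between-reference pairwise alignments covering exons and decoy elements
#' only, a genome-wide pairwise alignment of the first group's reference to
#' the outgroup, histone-mark peak tracks, an ortholog table, a gene-to-GO
#' table, reporter-assay count tables, and a truth table of everything
#' planted.
#'
#' @param cfg a `simulation_config`.
#' @param dir optional directory; when given, all outputs are written as
#'   plain-text files (FASTA/GFF3/MAF/BED/TSV) plus `truth/*.tsv`.
#' @return a `study_bundle` list; see the vignette for the slot inventory.
#' @export
generate_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$indel_rate > 0)
    stop("generate_study requires indel_rate = 0 (coordinates must be shared)")
  set.seed(cfg$seed)
  layout <- genome_layout(cfg)
  elements <- place_elements(cfg, layout)
  chrom <- "chr1"
  glen <- max(layout$end)
  pi <- cfg$model$pi

  # assign motifs: two per true element, from the pool, round-robin
  motif_assign <- list()
  for (i in which(elements$kind == "true")) {
    ms <- cfg$motif_pool[((2 * (i - 1)) %% length(cfg$motif_pool)) + c(1, 2)]
    motif_assign[[elements$ecr_id[i]]] <- ms
  }

  # ancestral sequences shared across groups
  anc_exon <- lapply(seq_len(nrow(layout)), function(i)
    if (layout$type[i] == "exon")
      random_dna(layout$end[i] - layout$start[i], pi) else NULL)
  anc_decoy <- lapply(seq_len(nrow(elements)), function(i)
    if (elements$kind[i] == "decoy") random_dna(cfg$ecr_length, pi) else NULL)

  genomes <- list()            # species -> string
  group_mafs <- list()         # group label -> maf_alignment (exons+introns)
  neutral_mafs <- list()       # group label -> maf_alignment (spacers)
  truth_motifs <- list()
  motif_positions <- list()    # per group: genome positions masked

  for (gr in cfg$groups) {
    per_feature <- list()      # feature -> named char vector of leaf strings
    mask_pos <- integer(0)
    for (fi in seq_len(nrow(layout))) {
      f <- layout[fi, ]
      len <- f$end - f$start
      el <- if (f$type == "intron")
        elements[elements$gene == f$gene & elements$intron_idx == f$idx, ,
                 drop = FALSE]
      else elements[0, , drop = FALSE]
      if (f$type == "exon") {
        anc <- evolve_on_tree(anc_exon[[fi]],
                              two_tip_tree(cfg$exon_deep), cfg$model)$leaves[["x"]]
        ev <- evolve_on_tree(anc, gr$tree, cfg$model, scale = cfg$exon_scale)
        per_feature[[fi]] <- ev$leaves
      } else if (nrow(el) == 0L) {
        seqs <- evolve_on_tree(random_dna(len, pi), gr$tree, cfg$model)$leaves
        per_feature[[fi]] <- seqs
      } else {                 # intron containing a planted element
        stopifnot(nrow(el) == 1L)
        rel_s <- el$start - f$start; rel_e <- el$end - f$start
        left <- random_dna(rel_s, pi)
        right <- random_dna(len - rel_e, pi)
        if (el$kind == "true") {
          core <- random_dna(cfg$ecr_length, pi)   # per-group redraw
          ms <- motif_assign[[el$ecr_id]]
          mpos <- integer(0)
          slots <- floor(seq(10, cfg$ecr_length - max(nchar(ms)) - 10,
                             length.out = length(ms) + 1))
          for (mi in seq_along(ms)) {
            mstr <- ms[mi]
            at <- slots[mi] + sample.int(max(slots[mi + 1] - slots[mi] -
                                               nchar(mstr), 1), 1)
            strand <- sample(c("+", "-"), 1)
            ins <- if (strand == "+") mstr else revcomp(mstr)
            substr(core, at, at + nchar(mstr) - 1) <- ins
            mpos <- c(mpos, at:(at + nchar(mstr) - 1))
            truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
              ecr_id = el$ecr_id, group = gr$label, motif = mstr,
              chrom = chrom, start = el$start + at - 1,
              end = el$start + at - 1 + nchar(mstr), strand = strand,
              stringsAsFactors = FALSE)
          }
          ecr_leaves <- evolve_on_tree(core, gr$tree, cfg$model,
                                       scale = cfg$ecr_rho,
                                       masked = mpos)$leaves
          mask_pos <- c(mask_pos, el$start + mpos - 1)
        } else {
          anc <- evolve_on_tree(anc_decoy[[match(el$ecr_id, elements$ecr_id)]],
                                two_tip_tree(cfg$decoy_deep),
                                cfg$model)$leaves[["x"]]
          ecr_leaves <- evolve_on_tree(anc, gr$tree, cfg$model,
                                       scale = cfg$ecr_rho)$leaves
        }
        flank_l <- evolve_on_tree(left, gr$tree, cfg$model)$leaves
        flank_r <- evolve_on_tree(right, gr$tree, cfg$model)$leaves
        per_feature[[fi]] <- paste0(flank_l[gr$species],
                                    ecr_leaves[gr$species],
                                    flank_r[gr$species])
        names(per_feature[[fi]]) <- gr$species
      }
    }
    for (sp in gr$species)
      genomes[[sp]] <- paste(vapply(per_feature, function(v) v[[sp]], ""),
                             collapse = "")
    motif_positions[[gr$label]] <- sort(unique(mask_pos + 1L))  # 1-based
    make_blocks <- function(rows_idx) {
      blocks <- lapply(rows_idx, function(fi) {
        f <- layout[fi, ]
        data.frame(species = gr$species, chrom = chrom, start = f$start,
                   size = f$end - f$start, strand = "+", src_size = glen,
                   text = vapply(per_feature[[fi]][gr$species], identity, ""),
                   stringsAsFactors = FALSE)
      })
      structure(list(blocks = blocks, reference = gr$reference),
                class = "maf_alignment")
    }
    group_mafs[[gr$label]] <- make_blocks(which(layout$type %in% c("exon", "intron")))
    neutral_mafs[[gr$label]] <- make_blocks(which(layout$type == "spacer"))
  }

  # outgroup annotation reference: close relative of the first group's reference
  g1 <- cfg$groups[[1]]
  ref1 <- g1$reference
  hs <- evolve_on_tree(genomes[[ref1]], two_tip_tree(cfg$outgroup_divergence),
                       cfg$model, masked = motif_positions[[g1$label]])
  genomes[["hs"]] <- hs$leaves[["x"]]

  refs <- vapply(cfg$groups, function(g) g$reference, "")
  glabels <- vapply(cfg$groups, function(g) g$label, "")

  # annotations for references + outgroup
  annots <- list()
  ex <- layout[layout$type == "exon", , drop = FALSE]
  for (sp in c(refs, "hs")) {
    annots[[sp]] <- validate_gint(data.frame(
      assembly = sp, chrom = chrom, start = ex$start, end = ex$end,
      strand = "+", gene_id = paste0(ex$gene, ".", sp), exon_rank = ex$idx,
      stringsAsFactors = FALSE))
  }

  # between-reference pairwise alignments: exon blocks + decoy blocks only
  aln_block <- function(spA, spB, s, e) {
    data.frame(species = c(spA, spB), chrom = chrom, start = s, size = e - s,
               strand = "+", src_size = glen,
               text = c(substr(genomes[[spA]], s + 1, e),
                        substr(genomes[[spB]], s + 1, e)),
               stringsAsFactors = FALSE)
  }
  inter_alns <- list()
  pairs <- utils::combn(refs, 2)
  for (p in seq_len(ncol(pairs))) {
    spA <- pairs[1, p]; spB <- pairs[2, p]
    blocks <- c(lapply(seq_len(nrow(ex)), function(i)
                  aln_block(spA, spB, ex$start[i], ex$end[i])),
                lapply(which(elements$kind == "decoy"), function(i)
                  aln_block(spA, spB, elements$start[i], elements$end[i])))
    maf <- structure(list(blocks = blocks, reference = spA),
                     class = "maf_alignment")
    inter_alns[[paste0(spA, "_", spB)]] <- maf
  }
  # genome-wide reference-to-outgroup alignment (one block)
  hs_maf <- structure(list(blocks = list(aln_block(ref1, "hs", 0, glen)),
                           reference = ref1), class = "maf_alignment")

  # ortholog and GO tables
  genes <- paste0("g", seq_len(cfg$n_genes))
  ortho <- do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(cluster = i, species = c(refs, "hs"),
               gene_id = paste0(genes[i], ".", c(refs, "hs")),
               stringsAsFactors = FALSE)))
  dev_genes <- unique(elements$gene[elements$kind == "true"])
  go <- do.call(rbind, lapply(genes, function(g) {
    terms <- if (g %in% dev_genes)
      c("developmental process", "anatomical structure development")
    else "metabolic process"
    data.frame(gene_id = paste0(g, ".", rep(c(refs, "hs"), each = length(terms))),
               go_term = rep(terms, length(refs) + 1), stringsAsFactors = FALSE)
  }))

  # histone marks for the first and last group's references
  true_el <- elements[elements$kind == "true", , drop = FALSE]
  n_me1 <- round(cfg$me1_fraction * nrow(true_el))
  n_me3 <- round(cfg$me3_fraction * nrow(true_el))
  marks <- list()
  for (sp in c(refs[1], refs[length(refs)])) {
    me1_idx <- sort(sample.int(nrow(true_el), n_me1))
    me3_idx <- if (n_me3 > 0) sort(sample(me1_idx, min(n_me3, length(me1_idx))))
               else integer(0)
    prom <- layout[layout$type == "exon" & layout$idx == 1, , drop = FALSE]
    me1 <- genomic_interval(sp, chrom, true_el$start[me1_idx] - 50,
                            true_el$end[me1_idx] + 50)
    me3 <- genomic_interval(sp, chrom,
                            c(true_el$start[me3_idx] - 20, prom$start - 100),
                            c(true_el$end[me3_idx] + 20, prom$start + 100))
    marks[[sp]] <- list(me1 = me1, me3 = me3,
                        me1_ecrs = true_el$ecr_id[me1_idx],
                        me3_ecrs = true_el$ecr_id[me3_idx])
  }

  # reporter assay simulation for true elements
  tissues <- c("Epidermis", "Otic vesicle", "Somitic muscle", "Hindbrain",
               "Olfactory epithelium", "Spinal cord", "Notochord", "Heart")
  zf_sp <- refs[length(refs)]; mm_sp <- refs[1]
  assay_rows <- list(); assay_truth <- list()
  for (i in seq_len(nrow(true_el))) {
    shared <- sample(tissues, 2)
    for (sp in c(zf_sp, mm_sp)) {
      own <- sample(setdiff(tissues, shared), 1)
      construct <- paste0(true_el$ecr_id[i], ".", sp)
      for (tp in c(24, 48)) for (ts in tissues) {
        active <- ts %in% c(shared, own)
        rate <- cfg$background_rate + if (active) cfg$activity_rate else 0
        alive <- stats::rbinom(1, cfg$n_embryos, 0.9)
        expr <- stats::rbinom(1, alive, rate)
        ecto <- stats::rbinom(1, expr, cfg$ectopic_rate)
        assay_rows[[length(assay_rows) + 1L]] <- data.frame(
          construct = construct, time = tp, tissue = ts, n_expressing = expr,
          n_ectopic = ecto, n_alive = alive, stringsAsFactors = FALSE)
        if (active) assay_truth[[length(assay_truth) + 1L]] <- data.frame(
          construct = construct, species = sp, ecr_id = true_el$ecr_id[i],
          tissue = ts, time = tp, shared = ts %in% shared,
          stringsAsFactors = FALSE)
      }
    }
  }
  background <- do.call(rbind, lapply(c(24, 48), function(tp)
    data.frame(construct = "empty", time = tp, tissue = tissues,
               n_expressing = stats::rbinom(length(tissues), cfg$n_embryos,
                                            cfg$background_rate),
               n_ectopic = 0, n_alive = cfg$n_embryos,
               stringsAsFactors = FALSE)))

  truth <- list(
    elements = cbind(elements, chrom = chrom,
                     enhancer = elements$kind == "true"),
    introns = do.call(rbind, lapply(c(refs, "hs"), function(sp) {
      intr <- layout[layout$type == "intron", , drop = FALSE]
      data.frame(species = sp, gene_id = paste0(intr$gene, ".", sp),
                 intron_idx = intr$idx, chrom = chrom, start = intr$start,
                 end = intr$end, stringsAsFactors = FALSE)
    })),
    motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else NULL,
    marks = marks,
    assay = do.call(rbind, assay_truth))

  bundle <- structure(list(
    cfg = cfg, layout = layout, chrom = chrom, genome_length = glen,
    genomes = genomes, annotations = annots,
    group_mafs = group_mafs, neutral_mafs = neutral_mafs,
    inter_alns = inter_alns, hs_maf = hs_maf,
    orthologs = ortho, go = go, marks = marks,
    assay = do.call(rbind, assay_rows), background = background,
    truth = truth, references = stats::setNames(refs, glabels)),
    class = "study_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

two_tip_tree <- function(d) {
  tr <- ape::read.tree(text = sprintf("(x:%f,y:0);", d))
  tr
}

#' @rdname generate_study
#' @param bundle a `study_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (sp in names(bundle$genomes))
    write_fasta(stats::setNames(bundle$genomes[[sp]], bundle$chrom),
                file.path(dir, paste0(sp, ".fa")))
  for (sp in names(bundle$annotations))
    write_annotation(bundle$annotations[[sp]],
                     file.path(dir, paste0(sp, ".gff3")))
  for (g in names(bundle$group_mafs)) {
    write_maf(bundle$group_mafs[[g]], file.path(dir, paste0(g, ".maf")))
    write_maf(bundle$neutral_mafs[[g]],
              file.path(dir, paste0(g, "_neutral.maf")))
  }
  for (nm in names(bundle$inter_alns))
    write_maf(bundle$inter_alns[[nm]], file.path(dir, paste0(nm, ".maf")))
  write_maf(bundle$hs_maf, file.path(dir, "ref_hs.maf"))
  for (sp in names(bundle$marks)) {
    write_bed(bundle$marks[[sp]]$me1, file.path(dir, paste0(sp, "_h3k4me1.bed")))
    write_bed(bundle$marks[[sp]]$me3, file.path(dir, paste0(sp, "_h3k4me3.bed")))
  }
  write_tsv(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  write_tsv(bundle$go, file.path(dir, "gene2go.tsv"))
  write_tsv(bundle$assay, file.path(dir, "assay_counts.tsv"))
  write_tsv(bundle$background, file.path(dir, "assay_background.tsv"))
  write_tsv(bundle$truth$elements, file.path(dir, "truth", "elements.tsv"))
  write_tsv(bundle$truth$introns, file.path(dir, "truth", "introns.tsv"))
  if (!is.null(bundle$truth$motifs))
    write_tsv(bundle$truth$motifs, file.path(dir, "truth", "motifs.tsv"))
  write_tsv(bundle$truth$assay, file.path(dir, "truth", "assay.tsv"))
  invisible(dir)
}
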
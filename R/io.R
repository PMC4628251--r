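#' Read a MAF multiple alignment
#'
#' MAF `s` lines carry 0-based starts in strand coordinates; rows on the
#' minus strand are normalized to forward-strand intervals at parse time
#' (`start_fwd = src_size - start - size`) with the original strand retained
#' as metadata and the text left in alignment orientation.  The species
#' label is the part of `src` before the first dot and doubles as the
#' assembly label; the chromosome is the remainder.
#'
#' @param path path to a MAF file with at least one alignment block.
#' @param reference reference species label; defaults to the species of the
#'   first row of the first block.
#' @return an object of class `maf_alignment`: a list with `blocks` (each a
#'   data.frame with columns `species`, `chrom`, `start`, `size`, `strand`,
#'   `src_size`, `text`; `start` is forward-strand 0-based) and `reference`.
#' @export
read_maf <- function(path, reference = NULL) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || nrow(cur) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L)
      stop("MAF format error: unequal row lengths in block ending near line ",
           cur$line[nrow(cur)])
    cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^a($|[ \t])", ln)) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- data.frame(species = character(0), chrom = character(0),
                        start = numeric(0), size = numeric(0),
                        strand = character(0), src_size = numeric(0),
                        text = character(0), line = integer(0),
                        stringsAsFactors = FALSE)
    } else if (grepl("^s[ \t]", ln)) {
      if (is.null(cur)) stop("MAF parse error at line ", i, ": 's' line before 'a'")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L) stop("MAF parse error at line ", i, ": expected 7 fields")
      src <- f[2]; st <- suppressWarnings(as.numeric(f[3]))
      sz <- suppressWarnings(as.numeric(f[4])); strand <- f[5]
      ssz <- suppressWarnings(as.numeric(f[6])); text <- f[7]
      if (is.na(st) || is.na(sz) || is.na(ssz) || !strand %in% c("+", "-"))
        stop("MAF parse error at line ", i, ": bad numeric field or strand")
      ungapped <- nchar(gsub("-", "", text))
      if (ungapped != sz)
        stop("MAF format error at line ", i, ": size ", sz,
             " does not match ungapped text length ", ungapped)
      if (sz <= 0) stop("MAF format error at line ", i, ": non-positive size")
      species <- sub("\\..*$", "", src)
      chrom <- ifelse(grepl("\\.", src), sub("^[^.]*\\.", "", src), "chr1")
      start_fwd <- if (strand == "+") st else ssz - st - sz
      cur <- rbind(cur, data.frame(species = species, chrom = chrom,
                                   start = start_fwd, size = sz, strand = strand,
                                   src_size = ssz, text = text, line = i,
                                   stringsAsFactors = FALSE))
    }
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  if (length(blocks) == 0L) stop("MAF parse error: no alignment blocks in ", path)
  blocks <- lapply(blocks, function(b) { b$line <- NULL; b })
  if (is.null(reference)) reference <- blocks[[1]]$species[1]
  structure(list(blocks = blocks, reference = reference), class = "maf_alignment")
}

#' @rdname read_maf
#' @param maf a `maf_alignment`.
#' @export
write_maf <- function(maf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in maf$blocks) {
    writeLines("a score=0", con)
    for (i in seq_len(nrow(b))) {
      st <- if (b$strand[i] == "+") b$start[i] else b$src_size[i] - b$start[i] - b$size[i]
      writeLines(sprintf("s %s.%s %d %d %s %d %s", b$species[i], b$chrom[i],
                         as.integer(st), as.integer(b$size[i]), b$strand[i],
                         as.integer(b$src_size[i]), b$text[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.maf_alignment <- function(x, ...) {
  cat("maf_alignment:", length(x$blocks), "block(s), reference", x$reference, "\n")
  invisible(x)
}

#' Pairwise alignment between two assemblies
#'
#' A thin container over ordered alignment blocks: per block a query and a
#' target interval with their gapped texts.  Built directly or extracted
#' from a two-species MAF.
#'
#' @param maf a `maf_alignment` whose blocks contain both species.
#' @param query,target species/assembly labels.
#' @return a `pairwise_alignment`: list with `blocks` (each a list with
#'   `query`/`target` single-row `gint`s and `qtext`/`ttext`) plus
#'   `query_assembly`, `target_assembly`.
#' @export
as_pairwise <- function(maf, query, target) {
  blocks <- list()
  for (b in maf$blocks) {
    qi <- match(query, b$species); ti <- match(target, b$species)
    if (is.na(qi) || is.na(ti)) next
    blocks[[length(blocks) + 1L]] <- list(
      query = genomic_interval(query, b$chrom[qi], b$start[qi],
                               b$start[qi] + b$size[qi], b$strand[qi]),
      target = genomic_interval(target, b$chrom[ti], b$start[ti],
                                b$start[ti] + b$size[ti], b$strand[ti]),
      qtext = b$text[qi], ttext = b$text[ti])
  }
  if (length(blocks) == 0L)
    stop("no blocks contain both ", query, " and ", target)
  ord <- order(vapply(blocks, function(b) b$query$chrom, ""),
               vapply(blocks, function(b) b$query$start, 0))
  structure(list(blocks = blocks[ord], query_assembly = query,
                 target_assembly = target), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment:", x$query_assembly, "->", x$target_assembly,
      ",", length(x$blocks), "block(s)\n")
  invisible(x)
}

# Per-column coordinate table of one pairwise block restricted to query
# interval [s, e): data.frame(qpos, tpos, qchar, tchar) over columns where
# the query is ungapped and inside the span.  tpos is NA where the target is
# gapped.  Query rows must be forward-strand.
block_columns <- function(block, s, e) {
  if (block$query$strand != "+")
    stop("query rows of a pairwise alignment must be forward-strand")
  qc <- strsplit(block$qtext, "")[[1]]
  tc <- strsplit(block$ttext, "")[[1]]
  qgap <- qc == "-"; tgap <- tc == "-"
  qpos <- block$query$start + cumsum(!qgap) - 1
  qpos[qgap] <- NA
  if (block$target$strand == "+") {
    tpos <- block$target$start + cumsum(!tgap) - 1
  } else {
    tpos <- block$target$start + block$target$end - block$target$start - cumsum(!tgap)
  }
  tpos[tgap] <- NA
  keep <- !qgap & qpos >= s & qpos < e
  data.frame(qpos = qpos[keep], tpos = tpos[keep],
             qchar = qc[keep], tchar = tc[keep], stringsAsFactors = FALSE)
}

#' Map an interval through a pairwise alignment
#'
#' Returns the target-assembly span of the alignment columns covering the
#' query interval, excluding columns where the target is gapped.  If fewer
#' than `min_mapped_fraction` of the query bases map, the interval is
#' considered unmappable and `NULL` is returned (as it is when the interval
#' lies outside every block).
#'
#' @param iv single-row `gint` on the alignment's query assembly.
#' @param aln a `pairwise_alignment`.
#' @param min_mapped_fraction minimum fraction of query bases with an
#'   ungapped target counterpart (default 0.5).
#' @return a single-row `gint` on the target assembly, or `NULL`.
#' @export
map_interval <- function(iv, aln, min_mapped_fraction = 0.5) {
  stopifnot(nrow(iv) == 1L)
  if (iv$assembly != aln$query_assembly)
    stop("interval assembly ", iv$assembly, " does not match alignment query ",
         aln$query_assembly)
  tpos <- numeric(0); tstrand <- character(0); tchrom <- character(0)
  for (b in aln$blocks) {
    if (b$query$chrom != iv$chrom) next
    if (b$query$end <= iv$start || b$query$start >= iv$end) next
    cols <- block_columns(b, iv$start, iv$end)
    ok <- !is.na(cols$tpos)
    if (any(ok)) {
      tpos <- c(tpos, cols$tpos[ok])
      tstrand <- c(tstrand, rep(b$target$strand, sum(ok)))
      tchrom <- c(tchrom, rep(b$target$chrom, sum(ok)))
    }
  }
  if (length(tpos) / gi_width(iv) < min_mapped_fraction) return(NULL)
  chrom <- names(sort(table(tchrom), decreasing = TRUE))[1]
  keep <- tchrom == chrom
  genomic_interval(aln$target_assembly, chrom, min(tpos[keep]),
                   max(tpos[keep]) + 1,
                   names(sort(table(tstrand[keep]), decreasing = TRUE))[1])
}

# Matched/total aligned columns of iv through aln (columns where both rows
# are ungapped), in query order; used for exon identity confirmation.
aligned_matches <- function(iv, aln) {
  out <- logical(0)
  for (b in aln$blocks) {
    if (b$query$chrom != iv$chrom) next
    if (b$query$end <= iv$start || b$query$start >= iv$end) next
    cols <- block_columns(b, iv$start, iv$end)
    ok <- !is.na(cols$tpos)
    out <- c(out, toupper(cols$qchar[ok]) == toupper(cols$tchar[ok]))
  }
  out
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors, the representation used by the string-matching stages (which
#' rely on lower-case soft masking Biostrings would not preserve).
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  structure(as.character(ss), names = names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' Reading goes through rtracklayer; coordinate violations are rejected.
#'
#' @param path file path.
#' @param assembly assembly label to attach.
#' @return a `gint` data.frame with `name` and `score` columns when present.
#' @export
read_bed <- function(path, assembly = "NA") {
  gr <- rtracklayer::import(path, format = "bed")
  gi <- granges_to_gi(gr, assembly)
  if (!is.null(gr$name)) gi$name <- gr$name
  if (!is.null(gr$score)) gi$score <- gr$score
  gi
}

#' @rdname read_bed
#' @param x a `gint` data.frame; `name`/`score` columns are written if present.
#' @export
write_bed <- function(x, path) {
  name <- if (is.null(x$name)) rep(".", nrow(x)) else x$name
  score <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   name, score, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write exon annotations (GFF3)
#'
#' Gene models are reduced to their exon rows; 1-based inclusive GFF3
#' coordinates are converted to the internal convention.  Exon rank is
#' assigned along the gene's strand.
#'
#' @param path GFF3 file.
#' @param assembly assembly/species label.
#' @return a `gint` data.frame with `gene_id` and `exon_rank` columns.
#' @export
read_annotation <- function(path, assembly = "NA") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  gi <- granges_to_gi(gr, assembly)
  gi$gene_id <- sub("^gene:", "", parent)
  annotate_exon_rank(gi)
}

annotate_exon_rank <- function(annot) {
  annot <- annot[order(annot$gene_id, annot$start), , drop = FALSE]
  n_in_gene <- stats::ave(annot$start, annot$gene_id, FUN = seq_along)
  tot <- stats::ave(annot$start, annot$gene_id, FUN = length)
  annot$exon_rank <- ifelse(annot$strand == "+", n_in_gene, tot - n_in_gene + 1)
  rownames(annot) <- NULL
  validate_gint(annot)
}

#' @rdname read_annotation
#' @param annot exon annotation `gint` with `gene_id` (and optionally
#'   `exon_rank`) columns.
#' @export
write_annotation <- function(annot, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(annot$gene_id)) {
    ex <- annot[annot$gene_id == g, , drop = FALSE]
    writeLines(sprintf("%s\tsef\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       ex$chrom[1], as.integer(min(ex$start) + 1),
                       as.integer(max(ex$end)), ex$strand[1], g), con)
    for (i in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tsef\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         ex$chrom[i], as.integer(ex$start[i] + 1),
                         as.integer(ex$end[i]), ex$strand[i], g,
                         i, g), con)
  }
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' @param path MEME minimal file with `letter-probability matrix` sections.
#' @return list of motifs, each a list with `id`, `name`, and `matrix`
#'   (4 x width, rows A, C, G, T; columns sum to 1).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF", lines[i])) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      id <- f[2]; name <- if (length(f) >= 3) f[3] else f[2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) stop("MEME parse error: MOTIF ", id, " has no matrix")
      w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "[ \t]+")[[1]]),
                      numeric(4)))
      mat <- t(mat)                     # 4 x w, rows A C G T
      dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
      if (any(abs(colSums(mat) - 1) > 1e-3))
        stop("MEME parse error: columns of ", id, " do not sum to 1")
      out[[length(out) + 1L]] <- list(id = id, name = name, matrix = mat)
      i <- j + w
    }
    i <- i + 1L
  }
  if (length(out) == 0L) stop("no motifs found in ", path)
  out
}

#' @rdname read_meme
#' @param motifs list of motifs as returned by `read_meme`.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m$matrix)), con)
    for (j in seq_len(ncol(m$matrix)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$matrix[1, j], m$matrix[2, j],
                         m$matrix[3, j], m$matrix[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a plain TSV with a header
#'
#' @param path file path.
#' @return data.frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @param df data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement
#'
#' Case-preserving (soft masks survive), so it is safe on masked sequences.
#' @param s character vector of nucleotide strings.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}
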
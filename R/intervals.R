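#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open on the forward
#' strand, the BED convention.  Inputs in 1-based inclusive conventions
#' (GFF3, UCSC-browser-style `"chrN:a-b"` spans) are converted on ingest and
#' never afterwards, so a single convention flows through every stage.
#'
#' An interval set is a plain `data.frame` of class `"gint"` with columns
#' `assembly`, `chrom`, `start`, `end`, `strand` (plus any extra columns a
#' stage attaches, e.g. conservation scores).  `start < end` is enforced:
#' zero-length intervals are rejected rather than clamped.
#'
#' @param assembly assembly label, e.g. `"mm9"`.
#' @param chrom sequence (chromosome) name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"` or `"-"`; interval coordinates are always forward-strand.
#' @param ... further equal-length columns carried along.
#' @return a `gint` data.frame with one row per interval.
#' @examples
#' genomic_interval("mm9", "chr1", 100, 200)
#' @export
genomic_interval <- function(assembly, chrom, start, end, strand = "+", ...) {
  df <- data.frame(assembly = as.character(assembly),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   ..., stringsAsFactors = FALSE)
  validate_gint(df)
}

validate_gint <- function(df) {
  stopifnot(all(c("assembly", "chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval must satisfy start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- unique(c("gint", class(df)))
  df
}

#' @rdname genomic_interval
#' @param x a `gint` data.frame.
#' @export
gi_width <- function(x) x$end - x$start

#' Parse browser-style region strings
#'
#' Spans like `"chr2:39,790,777-39,791,782"` are 1-based inclusive; they are
#' converted to the internal 0-based half-open convention (the inclusive
#' length `end - start + 1` equals the half-open width).
#'
#' @param region character vector of `"chrom:start-end"` spans; thousands
#'   separators and en-dashes are tolerated.
#' @param assembly assembly label attached to the result.
#' @return a `gint` data.frame.
#' @examples
#' parse_region("chr2:39,790,777-39,791,782", "danRer7")
#' @export
parse_region <- function(region, assembly = "NA") {
  region <- gsub(",", "", region)
  region <- gsub("–|—", "-", region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region string: ", region[bad][1])
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(vapply(m, `[`, "", 3L))
  e1 <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(s1 > e1)) stop("region start exceeds end: ", region[s1 > e1][1])
  genomic_interval(assembly, chrom, s1 - 1, e1)
}

#' Convert between gint frames and GRanges
#'
#' `GRanges` (1-based closed) is used internally for overlap queries; the
#' half-open gint convention is restored on the way back.
#'
#' @param x a `gint` data.frame / a `GRanges`.
#' @param assembly assembly label to attach when converting from `GRanges`.
#' @return a `GRanges` / a `gint` data.frame.
#' @export
gi_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end),
                         strand = x$strand)
}

#' @rdname gi_to_granges
#' @export
granges_to_gi <- function(x, assembly = "NA") {
  strand <- as.character(BiocGenerics::strand(x))
  strand[strand == "*"] <- "+"
  genomic_interval(assembly,
                   as.character(GenomicRanges::seqnames(x)),
                   BiocGenerics::start(x) - 1, BiocGenerics::end(x),
                   strand)
}

#' Overlap hits between two interval sets
#'
#' @param query,subject `gint` data.frames on the same assembly.
#' @param min_bp minimum overlap in base pairs (default 1, the convention
#'   used throughout the cross-group and histone-mark filters).
#' @return a two-column data.frame of (query row, subject row) index pairs.
#' @export
gi_overlaps <- function(query, subject, min_bp = 1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(0), subject = integer(0)))
  h <- GenomicRanges::findOverlaps(gi_to_granges(query), gi_to_granges(subject),
                                   minoverlap = min_bp, ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

# pairwise overlap width in bp between single intervals a[i,] and b[j,] on the
# same chrom; vectorized over equal-length index vectors
overlap_width <- function(a, b) {
  w <- pmin(a$end, b$end) - pmax(a$start, b$start)
  w[a$chrom != b$chrom] <- 0
  pmax(w, 0)
}
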
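#' Genome build: ordered chromosomes with lengths
#'
#' A minimal description of a genome assembly: an ordered set of chromosome
#' names and lengths. Unplaced scaffolds (e.g. \code{"chrU"}) are ordinary
#' chromosomes. Used to validate intervals, place probes and size synthetic
#' genomes.
#'
#' @param name assembly name, e.g. \code{"UMD3"}.
#' @param chrom character vector of unique chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp (> 0).
#' @return An object of class \code{"genome_build"}: a data frame with
#'   columns \code{chrom} and \code{length} and a \code{name} attribute.
#' @examples
#' genome_build("toy", c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_build <- function(name, chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) == 0L) stop("a genome build needs at least one chromosome")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(out, "name") <- as.character(name)[1]
  class(out) <- c("genome_build", "data.frame")
  out
}

#' @export
print.genome_build <- function(x, ...) {
  cat("Genome build:", attr(x, "name"), "-", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a two-column chromosome-sizes file as a genome build
#'
#' @param path path to a tab-separated file with columns chrom, length.
#' @param name assembly name to attach (default: the file name).
#' @return A [genome_build()].
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_build(name, tab$chrom, tab$length)
}

#' Construct a validated table of genomic intervals
#'
#' Intervals are 0-based, half-open: a probe or event covering bases
#' \code{start .. end-1} has \code{span = end - start}. This is the BED
#' convention, and it is the convention in which a printed event of
#' Start 48,998,999 / End 49,016,999 has Length 18,000.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open bounds, \code{0 <= start < end}.
#' @param ... further equal-length columns carried along (e.g. \code{name},
#'   \code{log_r}).
#' @param build optional [genome_build()]; if given, chromosome names and
#'   upper bounds are validated against it.
#' @return A data frame of class \code{"gintervals"} with at least columns
#'   \code{chrom}, \code{start}, \code{end}.
#' @examples
#' gintervals("chr13", 48998999, 49016999)
#' @export
gintervals <- function(chrom, start, end, ..., build = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_gintervals(df, build = build)
}

validate_gintervals <- function(df, build = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0) {
    bad <- !is.finite(df$start) | !is.finite(df$end) |
      df$start < 0 | df$start >= df$end
    if (any(bad)) {
      stop("invalid interval(s) at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           ": need 0 <= start < end")
    }
    if (!is.null(build)) {
      m <- match(df$chrom, build$chrom)
      if (anyNA(m)) {
        stop("unknown chromosome(s): ",
             paste(unique(df$chrom[is.na(m)]), collapse = ", "))
      }
      over <- df$end > build$length[m]
      if (any(over)) {
        stop("interval(s) exceed chromosome length at row(s) ",
             paste(utils::head(which(over), 5), collapse = ", "))
      }
    }
  }
  if (!inherits(df, "gintervals")) class(df) <- c("gintervals", "data.frame")
  df
}

#' Span (width) of genomic intervals
#'
#' @param x a [gintervals()] table (or any data frame with \code{start},
#'   \code{end}).
#' @return Numeric vector \code{end - start}, one bp count per interval.
#' @examples
#' span(gintervals("chr25", 32362844, 32470747)) # 107903
#' @export
span <- function(x) {
  x$end - x$start
}

# internal: gintervals <-> GRanges (0-based half-open <-> 1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

granges_to_gintervals <- function(gr) {
  gintervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Pairwise interval overlap test
#'
#' Half-open semantics: two intervals overlap iff they are on the same
#' chromosome and share at least one base; abutting intervals
#' (\code{a$end == b$start}) do not overlap. With \code{max_gap > 0},
#' intervals separated by at most \code{max_gap} bp also count.
#'
#' @param a,b [gintervals()] tables, recycled row-wise to a common length.
#' @param max_gap maximum separation in bp still treated as "nearby"
#'   (default 0: plain overlap).
#' @return Logical vector.
#' @examples
#' interval_overlaps(gintervals("chr1", 0, 10), gintervals("chr1", 10, 20))
#' @export
interval_overlaps <- function(a, b, max_gap = 0) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    a$start[ai] < b$end[bi] + max_gap &
    b$start[bi] < a$end[ai] + max_gap
}

#' Merge overlapping intervals into their union
#'
#' Returns the minimal set of maximal disjoint intervals covering the union
#' of the input, sorted by chromosome then start. Idempotent. Abutting
#' intervals (zero gap under half-open coordinates) are fused.
#'
#' @param x a [gintervals()] table.
#' @param max_gap fuse intervals separated by at most this many bp
#'   (default 0: only touching/overlapping intervals fuse).
#' @return A [gintervals()] table of disjoint intervals.
#' @examples
#' merge_intervals(gintervals("c", c(0, 5, 30), c(10, 20, 40)))
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (nrow(x) == 0) {
    return(gintervals(character(), numeric(), numeric()))
  }
  x <- validate_gintervals(x)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1L)
  out <- granges_to_gintervals(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read genomic intervals from a BED3+/BED6 file
#'
#' BED is 0-based half-open, matching the package's native convention, so
#' coordinates pass through unchanged. Comma thousand-separators in the
#' coordinate columns are tolerated (stripped before parsing).
#'
#' @param path path to a BED file (3 to 6 columns, no header; track/browser
#'   lines are skipped).
#' @return A [gintervals()] table; columns \code{name}, \code{score},
#'   \code{strand} are included when present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(gintervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(vapply(fields, length, 1L))
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(v) as.numeric(gsub(",", "", v, fixed = TRUE))
  out <- data.frame(chrom = get(1), start = num(get(2)), end = num(get(3)),
                    stringsAsFactors = FALSE)
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- num(get(5))
  if (ncol >= 6) out$strand <- get(6)
  validate_gintervals(out)
}

#' Write genomic intervals to a BED file
#'
#' Writes BED3 by default; BED6 when \code{name}/\code{score} columns are
#' present or supplied.
#'
#' @param x a [gintervals()] table.
#' @param path output path.
#' @param track_name optional BED track line name.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(x, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf("track name=\"%s\"", track_name), con)
  }
  fmt_num <- function(v) format(v, scientific = FALSE, trim = TRUE)
  if (!is.null(x$name) || !is.null(x$score)) {
    nm <- if (is.null(x$name)) rep(".", nrow(x)) else x$name
    sc <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
    st <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
    writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                     nm, fmt_num(sc), st, sep = "\t"), con)
  } else if (nrow(x) > 0) {
    writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end), sep = "\t"),
               con)
  }
  invisible(path)
}
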
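#' Read a UCSC chain file
#'
#' Parses block-structured pairwise alignments between two assemblies
#' ("chain" format): a header \code{chain score tName tSize tStrand tStart
#' tEnd qName qSize qStrand qStart qEnd id} followed by \code{size dt dq}
#' block lines and a final bare \code{size}. The first (t) genome is
#' treated as the source of a remap and the second (q) as the target,
#' which matches how assembly-migration chain files are oriented.
#'
#' @param path path to a chain file (or a character vector of its lines
#'   via \code{text}).
#' @param text optional character vector of chain lines, used instead of
#'   \code{path}.
#' @return A list of \code{"chain_alignment"} objects; each has the header
#'   fields (\code{score}, \code{source_chrom}, \code{source_size},
#'   \code{source_start}, \code{source_end}, \code{target_chrom},
#'   \code{target_size}, \code{target_strand}, \code{target_start},
#'   \code{target_end}, \code{id}) and \code{blocks}, a data frame of
#'   aligned blocks (\code{source_start}, \code{target_start} in
#'   strand-local coordinates, \code{size}).
#' @export
read_chain <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- sub("\\s+$", "", lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (f[1] != "chain" || !(length(f) %in% c(12L, 13L))) {
      stop("malformed chain header at line ", i, ": ", lines[i])
    }
    num <- suppressWarnings(as.numeric(f[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num)) stop("non-numeric field in chain header at line ", i)
    hd <- list(score = num[1],
               source_chrom = f[3], source_size = num[2],
               source_strand = f[5], source_start = num[3],
               source_end = num[4],
               target_chrom = f[8], target_size = num[5],
               target_strand = f[10], target_start = num[6],
               target_end = num[7],
               id = if (length(f) == 13L) f[13] else NA_character_)
    if (hd$source_strand != "+") {
      stop("source strand must be '+' in chain at line ", i)
    }
    if (!hd$target_strand %in% c("+", "-")) {
      stop("bad target strand in chain at line ", i)
    }
    # walk the block lines
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    j <- i + 1L
    repeat {
      if (j > length(lines) || !nzchar(lines[j])) {
        stop("chain starting at line ", i, " has no terminating block line")
      }
      b <- suppressWarnings(as.numeric(strsplit(lines[j], "\\s+")[[1]]))
      if (anyNA(b) || !(length(b) %in% c(1L, 3L))) {
        stop("malformed chain block at line ", j, ": ", lines[j])
      }
      sizes <- c(sizes, b[1])
      if (length(b) == 1L) { j <- j + 1L; break }
      dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
      j <- j + 1L
    }
    src <- hd$source_start + c(0, cumsum(sizes[-length(sizes)] + dts))
    tgt <- hd$target_start + c(0, cumsum(sizes[-length(sizes)] + dqs))
    if (utils::tail(src + sizes, 1) != hd$source_end ||
        utils::tail(tgt + sizes, 1) != hd$target_end) {
      stop("chain starting at line ", i,
           " has blocks inconsistent with its header span")
    }
    if (hd$source_end > hd$source_size || hd$target_end > hd$target_size) {
      stop("chain starting at line ", i, " exceeds declared sequence size")
    }
    hd$blocks <- data.frame(source_start = src, target_start = tgt,
                            size = sizes)
    chains[[length(chains) + 1]] <- structure(hd,
                                              class = "chain_alignment")
    i <- j
  }
  chains
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf(
    "Chain %s (score %g): %s:%s-%s -> %s(%s):%s-%s, %d block(s)\n",
    ifelse(is.na(x$id), "", x$id), x$score, x$source_chrom,
    format(x$source_start, scientific = FALSE),
    format(x$source_end, scientific = FALSE),
    x$target_chrom, x$target_strand,
    format(x$target_start, scientific = FALSE),
    format(x$target_end, scientific = FALSE), nrow(x$blocks)))
  invisible(x)
}

#' Invert a chain alignment
#'
#' Swaps the source and target assemblies, producing the chain that maps
#' target coordinates back to source coordinates. Whenever a forward remap
#' succeeds with \code{min_match = 1}, remapping the result through the
#' inverted chain returns the original interval.
#'
#' @param chain a \code{chain_alignment}.
#' @return The inverted \code{chain_alignment}.
#' @export
invert_chain <- function(chain) {
  b <- chain$blocks
  if (chain$target_strand == "+") {
    out <- chain
    out$source_chrom <- chain$target_chrom
    out$source_size <- chain$target_size
    out$source_start <- chain$target_start
    out$source_end <- chain$target_end
    out$target_chrom <- chain$source_chrom
    out$target_size <- chain$source_size
    out$target_strand <- "+"
    out$target_start <- chain$source_start
    out$target_end <- chain$source_end
    out$blocks <- data.frame(source_start = b$target_start,
                             target_start = b$source_start,
                             size = b$size)
    return(out)
  }
  # '-' target: new source blocks are old target blocks on the plus
  # strand (reversed order); the old source becomes a '-' strand target
  Tsz <- chain$target_size
  Ssz <- chain$source_size
  n <- nrow(b)
  ord <- n:1
  out <- chain
  out$source_chrom <- chain$target_chrom
  out$source_size <- Tsz
  out$source_start <- Tsz - chain$target_end
  out$source_end <- Tsz - chain$target_start
  out$target_chrom <- chain$source_chrom
  out$target_size <- Ssz
  out$target_strand <- "-"
  out$target_start <- Ssz - chain$source_end
  out$target_end <- Ssz - chain$source_start
  out$blocks <- data.frame(
    source_start = (Tsz - b$target_start - b$size)[ord],
    target_start = (Ssz - b$source_start - b$size)[ord],
    size = b$size[ord])
  out
}

#' Remap a genomic interval between assemblies through chain alignments
#'
#' Maps an interval from source to target coordinates via the best-scoring
#' chain that aligns at least \code{min_match} of its bases. The remapped
#' interval spans from the target position of the first aligned base to
#' that of the last (internal indels change its length accordingly);
#' negative-strand chains are flipped to target plus-strand coordinates.
#' Failures are reported with distinct reasons: \code{"unmapped"} (no
#' chain touches the interval), \code{"deleted_in_target"} (one chain
#' covers it but too much of it falls in unaligned gaps), \code{"split"}
#' (only partial coverage spread over several chains).
#'
#' @param chains a list of \code{chain_alignment}s (from [read_chain()]).
#' @param interval a single-row [gintervals()] table.
#' @param min_match minimum aligned fraction of interval bases
#'   (default 0.95, the canonical assembly-migration default).
#' @return A list: \code{status} (\code{"mapped"} or a failure reason),
#'   \code{interval} (remapped [gintervals()], or \code{NULL}),
#'   \code{matched_fraction}, \code{chain_id}.
#' @export
remap_interval <- function(chains, interval, min_match = 0.95) {
  interval <- validate_gintervals(as.data.frame(interval))
  stopifnot(nrow(interval) == 1)
  s0 <- interval$start; e0 <- interval$end
  w <- e0 - s0
  cand <- list()
  for (ch in chains) {
    if (ch$source_chrom != interval$chrom) next
    if (ch$source_end <= s0 || ch$source_start >= e0) next
    b <- ch$blocks
    ov_lo <- pmax(b$source_start, s0)
    ov_hi <- pmin(b$source_start + b$size, e0)
    hit <- which(ov_hi > ov_lo)
    if (!length(hit)) {
      # the chain spans the interval but aligns none of its bases
      cand[[length(cand) + 1]] <- list(frac = 0, score = ch$score,
                                       id = ch$id, mapped = NULL)
      next
    }
    covered <- sum(ov_hi[hit] - ov_lo[hit])
    first <- hit[1]; last <- hit[length(hit)]
    q_lo <- b$target_start[first] + (ov_lo[first] - b$source_start[first])
    q_hi <- b$target_start[last] + (ov_hi[last] - b$source_start[last])
    if (ch$target_strand == "-") {
      t_start <- ch$target_size - q_hi
      t_end <- ch$target_size - q_lo
    } else {
      t_start <- q_lo
      t_end <- q_hi
    }
    cand[[length(cand) + 1]] <- list(
      frac = covered / w, score = ch$score, id = ch$id,
      mapped = gintervals(ch$target_chrom, t_start, t_end))
  }
  if (!length(cand)) {
    return(list(status = "unmapped", interval = NULL,
                matched_fraction = 0, chain_id = NA_character_))
  }
  fracs <- vapply(cand, `[[`, 0, "frac")
  scores <- vapply(cand, `[[`, 0, "score")
  ok <- which(fracs >= min_match)
  if (length(ok)) {
    pick <- ok[which.max(scores[ok])]
    return(list(status = "mapped", interval = cand[[pick]]$mapped,
                matched_fraction = fracs[pick],
                chain_id = cand[[pick]]$id))
  }
  status <- if (length(cand) > 1) "split" else "deleted_in_target"
  list(status = status, interval = NULL,
       matched_fraction = max(fracs), chain_id = NA_character_)
}

#' Batch-remap a BED file of intervals through a chain file
#'
#' @param chains chain list from [read_chain()].
#' @param intervals a [gintervals()] table (e.g. from [read_bed()]).
#' @param min_match see [remap_interval()].
#' @return A list: \code{mapped} ([gintervals()] with a \code{name} column
#'   carrying the source locus) and \code{unmapped} (data frame of source
#'   intervals with a \code{reason} column).
#' @export
remap_intervals <- function(chains, intervals, min_match = 0.95) {
  mapped <- list(); unmapped <- list()
  for (i in seq_len(nrow(intervals))) {
    r <- remap_interval(chains, intervals[i, , drop = FALSE], min_match)
    src_name <- sprintf("%s:%s-%s", intervals$chrom[i],
                        format(intervals$start[i], scientific = FALSE),
                        format(intervals$end[i], scientific = FALSE))
    if (r$status == "mapped") {
      m <- r$interval
      m$name <- src_name
      mapped[[length(mapped) + 1]] <- m
    } else {
      u <- as.data.frame(intervals[i, c("chrom", "start", "end")])
      u$reason <- r$status
      unmapped[[length(unmapped) + 1]] <- u
    }
  }
  list(
    mapped = if (length(mapped)) do.call(rbind, mapped) else
      gintervals(character(), numeric(), numeric()),
    unmapped = if (length(unmapped)) do.call(rbind, unmapped) else
      data.frame(chrom = character(), start = numeric(),
                 end = numeric(), reason = character())
  )
}
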
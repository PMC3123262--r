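#' GC fraction of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T), case-insensitive; N and other ambiguity
#' codes are excluded from both numerator and denominator. A sequence with
#' no unambiguous base has no defined GC fraction and raises an error.
#'
#' @param seq a character string, \code{Biostrings::DNAString}, or
#'   character vector (vectorized over elements).
#' @return Numeric GC fraction(s) in \[0, 1\].
#' @examples
#' gc_fraction("ACGT")  # 0.5
#' @export
gc_fraction <- function(seq) {
  if (inherits(seq, "DNAString")) {
    seq <- Biostrings::DNAStringSet(seq)
  } else if (is.character(seq)) {
    if (any(!nzchar(seq))) stop("empty sequence")
    seq <- Biostrings::DNAStringSet(toupper(seq))
  }
  freq <- Biostrings::letterFrequency(seq, letters = c("G", "C", "A", "T"))
  tot <- rowSums(freq)
  if (any(tot == 0)) {
    stop("GC fraction undefined: sequence contains no unambiguous base")
  }
  unname((freq[, "G"] + freq[, "C"]) / tot)
}

#' Windowed GC profile of a sequence
#'
#' Scores non-overlapping (tiling) windows of \code{window} bp with
#' [gc_fraction()]; a trailing partial window is scored over its actual
#' length. A 5 bp window reproduces a browser-style "GC percent in 5-base
#' windows" track. Set \code{step < window} for a smoother sliding
#' profile.
#'
#' @param seq a character string or \code{Biostrings::DNAString}.
#' @param window window width in bp (>= 1, <= sequence length).
#' @param step step between window starts (default \code{window}: tiling).
#' @return A data frame of class \code{"gc_profile"}: \code{start} (0-based
#'   window start), \code{end}, \code{gc}.
#' @examples
#' windowed_gc("GGGGGAAAAA", 5)$gc  # 1.0 0.0
#' @export
windowed_gc <- function(seq, window = 5, step = window) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  L <- length(seq)
  stopifnot(window >= 1, window <= L, step >= 1)
  starts <- seq.int(1L, L, by = step)
  ends <- pmin(starts + window - 1L, L)
  v <- Biostrings::Views(seq, start = starts, end = ends)
  freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
  tot <- rowSums(freq)
  gc <- ifelse(tot > 0, (freq[, "G"] + freq[, "C"]) / tot, NA_real_)
  out <- data.frame(start = starts - 1L, end = ends, gc = unname(gc))
  class(out) <- c("gc_profile", "data.frame")
  out
}

#' GC context of called events versus the genome average
#'
#' For each event, the GC fraction of its genomic sequence and its excess
#' over the genome-wide average — the comparison used to argue that
#' recurrent calls are GC-wave artifacts rather than true copy-number
#' differences. The genome average is always computed from the supplied
#' sequences, never hard-coded.
#'
#' @param events a [gintervals()] table of events.
#' @param genome a \code{synthetic_genome}, or a named
#'   \code{Biostrings::DNAStringSet} of chromosome sequences.
#' @return A data frame with one row per event: \code{chrom},
#'   \code{start}, \code{end}, \code{region_gc}, \code{genome_gc},
#'   \code{excess}; attribute \code{n_positive_excess} counts events with
#'   \code{excess > 0}.
#' @export
region_vs_genome <- function(events, genome) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$seq else genome
  stopifnot(inherits(seqs, "DNAStringSet"))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  events <- validate_gintervals(as.data.frame(events))
  m <- match(events$chrom, names(seqs))
  if (anyNA(m)) {
    stop("event chromosome(s) absent from genome: ",
         paste(unique(events$chrom[is.na(m)]), collapse = ", "))
  }
  if (any(events$end > lens[m])) {
    stop("event(s) exceed chromosome bounds")
  }
  freq <- Biostrings::letterFrequency(seqs, letters = c("G", "C", "A", "T"))
  genome_gc <- sum(freq[, "G"] + freq[, "C"]) / sum(freq)
  region_gc <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    sub <- Biostrings::subseq(seqs[[m[i]]], start = events$start[i] + 1,
                              end = events$end[i])
    region_gc[i] <- gc_fraction(sub)
  }
  out <- data.frame(chrom = events$chrom, start = events$start,
                    end = events$end, region_gc = region_gc,
                    genome_gc = genome_gc,
                    excess = region_gc - genome_gc,
                    stringsAsFactors = FALSE)
  attr(out, "n_positive_excess") <- sum(out$excess > 0)
  out
}

#' Write a GC profile as bedGraph
#'
#' @param profile a [windowed_gc()] result.
#' @param chrom chromosome name for the bedGraph lines.
#' @param path output path.
#' @param track_name optional track line name.
#' @return Invisibly, \code{path}.
#' @export
write_gc_bedgraph <- function(profile, chrom, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  }
  writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom, profile$start,
                     profile$end, profile$gc), con)
  invisible(path)
}
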
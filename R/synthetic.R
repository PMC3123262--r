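#' Generate a synthetic genome with a structured GC landscape
#'
#' Simulates chromosome sequences whose local GC propensity is an AT-richer
#' smooth baseline punctuated by localized GC-rich "bumps" (Gaussian humps of
#' configurable height and width). This emulates the feature of real
#' mammalian genomes that matters for array-CGH artifact analysis: isolated
#' GC-rich islands against a lower-GC background, which can drive
#' GC-correlated baseline waves and hence recurrent false calls. The
#' baseline level is normalized so that the expected genome-wide GC fraction
#' equals \code{gc_target}; the realized fraction lands within about
#' \eqn{\pm 0.02} of it for Mb-scale genomes.
#'
#' @param sizes named numeric vector of chromosome lengths in bp, or a
#'   [genome_build()].
#' @param gc_target genome-wide GC fraction to aim for (default 0.417, the
#'   documented average of the cattle reference genome).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param bump_rate expected GC bumps per bp (default 1 per 200 kb).
#' @param bump_height GC-propensity excess at a bump's peak (default 0.25).
#' @param bump_sd Gaussian width of a bump in bp (default 4000), which also
#'   sets the landscape's correlation length.
#' @return An object of class \code{"synthetic_genome"}: list with elements
#'   \code{build}, \code{seq} (a \code{Biostrings::DNAStringSet}),
#'   \code{gc_target}, \code{gc_realized}, \code{bumps} (per-chromosome bump
#'   centers), \code{base_level}, \code{params} and \code{seed}.
#' @examples
#' g <- make_genome(c(chr1 = 2e5, chr2 = 1e5), seed = 1)
#' g$gc_realized
#' @export
make_genome <- function(sizes, gc_target = 0.417, seed = 1,
                        bump_rate = 1 / 2e5, bump_height = 0.25,
                        bump_sd = 4000) {
  if (inherits(sizes, "genome_build")) {
    build <- sizes
  } else {
    if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
      names(sizes) <- paste0("chr", seq_along(sizes))
    }
    build <- genome_build("synthetic", names(sizes), sizes)
  }
  if (any(build$length < 1)) stop("chromosome sizes must be >= 1 bp")
  if (!(gc_target > 0 && gc_target < 1)) stop("gc_target must be in (0, 1)")

  rs <- local_rng(seed)
  bumps <- vector("list", nrow(build))
  names(bumps) <- build$chrom
  prop <- vector("list", nrow(build))
  for (i in seq_len(nrow(build))) {
    L <- build$length[i]
    n_bump <- rs$rpois(1, L * bump_rate)
    centers <- sort(rs$runif(n_bump, 1, L))
    bumps[[i]] <- centers
    prop[[i]] <- bump_profile(L, centers, bump_height, bump_sd)
  }
  # shift the baseline so the expected genome-wide GC equals the target
  tot <- sum(build$length)
  mean_bump <- sum(vapply(prop, sum, 0)) / tot
  base <- gc_target - mean_bump
  seqs <- character(nrow(build))
  gc_count <- 0
  for (i in seq_len(nrow(build))) {
    p <- pmin(0.95, pmax(0.05, base + prop[[i]]))
    L <- build$length[i]
    is_gc <- rs$runif(L) < p
    strong <- rs$runif(L) < 0.5
    code <- ifelse(is_gc, ifelse(strong, 71L, 67L),  # G / C
                   ifelse(strong, 65L, 84L))         # A / T
    seqs[i] <- intToUtf8(code)
    gc_count <- gc_count + sum(is_gc)
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- build$chrom
  structure(list(
    build = build, seq = dna, gc_target = gc_target,
    gc_realized = gc_count / tot, bumps = bumps, base_level = base,
    params = list(bump_rate = bump_rate, bump_height = bump_height,
                  bump_sd = bump_sd),
    seed = seed
  ), class = "synthetic_genome")
}

# sum of Gaussian bumps evaluated at 1..L
bump_profile <- function(L, centers, height, sd) {
  out <- numeric(L)
  for (c0 in centers) {
    lo <- max(1, floor(c0 - 5 * sd))
    hi <- min(L, ceiling(c0 + 5 * sd))
    x <- lo:hi
    out[x] <- out[x] + height * exp(-((x - c0)^2) / (2 * sd^2))
  }
  out
}

# isolated RNG stream so package simulations do not disturb the caller's
# .Random.seed and are reproducible given an integer seed
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  wrap <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      }
      if (!is.null(env$state)) assign(".Random.seed", env$state, globalenv())
      else set.seed(seed)
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        else rm(".Random.seed", envir = globalenv())
      })
      fn(...)
    }
  }
  list(runif = wrap(stats::runif), rnorm = wrap(stats::rnorm),
       rpois = wrap(stats::rpois), sample_int = wrap(sample.int))
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome: %d chromosome(s), %s bp, GC target %.3f (realized %.3f)\n",
    nrow(x$build), format(sum(x$build$length), big.mark = ","),
    x$gc_target, x$gc_realized))
  invisible(x)
}

#' GC propensity of the synthetic landscape at given positions
#'
#' Evaluates the smooth generating GC landscape (baseline + bumps) of a
#' [make_genome()] object, as distinct from the realized sequence GC.
#'
#' @param genome a \code{synthetic_genome}.
#' @param chrom chromosome name.
#' @param pos positions (1-based bp).
#' @return Numeric vector of propensities.
#' @export
gc_propensity <- function(genome, chrom, pos) {
  centers <- genome$bumps[[chrom]]
  if (is.null(centers)) stop("unknown chromosome: ", chrom)
  p <- rep(genome$base_level, length(pos))
  h <- genome$params$bump_height
  s <- genome$params$bump_sd
  for (c0 in centers) {
    p <- p + h * exp(-((pos - c0)^2) / (2 * s^2))
  }
  pmin(0.95, pmax(0.05, p))
}

#' Lay out an array probe map over a genome
#'
#' Places non-overlapping probes at jittered regular spacing along every
#' chromosome. Probe start positions sit on a regular grid of pitch
#' \code{mean_spacing} with uniform jitter of at most
#' \code{(mean_spacing - probe_length) / 2}, which guarantees sorted,
#' non-overlapping probes and a realized mean spacing within 5% of the
#' request.
#'
#' @param genome a \code{synthetic_genome} or [genome_build()] (only
#'   chromosome sizes are needed).
#' @param mean_spacing target mean probe pitch in bp (default 1200,
#'   the high-density design this package models).
#' @param probe_length probe length in bp (default 50).
#' @param seed integer seed for the jitter.
#' @return An object of class \code{"probe_map"}: a data frame with columns
#'   \code{probe_id}, \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and attributes \code{mean_spacing} (realized),
#'   \code{requested_spacing} and \code{seed}.
#' @examples
#' b <- genome_build("toy", "chr1", 1e6)
#' pm <- make_probe_map(b, 1200, seed = 1)
#' nrow(pm)  # about 833
#' @export
make_probe_map <- function(genome, mean_spacing = 1200, probe_length = 50,
                           seed = 1) {
  build <- if (inherits(genome, "synthetic_genome")) genome$build else genome
  stopifnot(inherits(build, "genome_build"))
  if (mean_spacing < probe_length) {
    stop("mean_spacing must be >= probe_length")
  }
  rs <- local_rng(seed + 101L)
  res <- vector("list", nrow(build))
  for (i in seq_len(nrow(build))) {
    L <- build$length[i]
    if (L < probe_length) {
      stop("chromosome ", build$chrom[i], " shorter than one probe")
    }
    n <- max(1L, floor(L / mean_spacing))
    grid <- (seq_len(n) - 1) * mean_spacing
    amp <- floor((mean_spacing - probe_length) / 2)
    jit <- if (amp > 0) floor(rs$runif(n, 0, amp + 1)) else 0
    start <- pmin(grid + jit, L - probe_length)
    res[[i]] <- data.frame(
      probe_id = sprintf("%s_P%06d", build$chrom[i], seq_len(n)),
      chrom = build$chrom[i], start = start, end = start + probe_length,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, res)
  rownames(map) <- NULL
  gaps <- unlist(lapply(split(map$start, map$chrom), diff), use.names = FALSE)
  attr(map, "mean_spacing") <- if (length(gaps)) mean(gaps) else NA_real_
  attr(map, "requested_spacing") <- mean_spacing
  attr(map, "probe_length") <- probe_length
  attr(map, "seed") <- seed
  class(map) <- c("probe_map", "data.frame")
  map
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("Probe map: %d probes on %d chromosome(s), mean spacing %.0f bp\n",
              nrow(x), length(unique(x$chrom)), attr(x, "mean_spacing")))
  invisible(x)
}

#' Per-probe local GC fraction
#'
#' GC fraction of a window centered on each probe midpoint, clipped at
#' chromosome ends. Neighborhood GC (rather than probe-sequence GC alone) is
#' what drives GC-correlated hybridization artifacts, so the default window
#' (500 bp) extends well beyond the probe itself.
#'
#' @param genome a \code{synthetic_genome}.
#' @param map a [make_probe_map()] probe map on the same genome.
#' @param window centered window width in bp (default 500).
#' @return Numeric vector of GC fractions, one per probe.
#' @export
probe_gc <- function(genome, map, window = 500) {
  stopifnot(inherits(genome, "synthetic_genome"))
  out <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    L <- genome$build$length[match(ch, genome$build$chrom)]
    mid <- (map$start[idx] + map$end[idx]) / 2
    lo <- pmax(1, round(mid - window / 2))
    hi <- pmin(L, round(mid + window / 2))
    v <- Biostrings::Views(genome$seq[[ch]], start = lo, end = hi)
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
    out[idx] <- (freq[, "G"] + freq[, "C"]) / rowSums(freq)
  }
  out
}

#' Describe a set of true (planted) copy-number variants
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param log2_shift signed log2-ratio shift of each CNV; the kind
#'   (gain/loss) is its sign.
#' @return A [gintervals()] table with columns \code{log2_shift} and
#'   \code{kind}, class \code{"truth_cnvs"}.
#' @export
truth_cnvs <- function(chrom, start, end, log2_shift) {
  if (any(log2_shift == 0)) stop("log2_shift must be non-zero")
  x <- gintervals(chrom, start, end,
                  log2_shift = as.numeric(log2_shift),
                  kind = ifelse(log2_shift > 0, "gain", "loss"))
  class(x) <- c("truth_cnvs", class(x))
  x
}

#' Simulate one array-CGH hybridization over a probe map
#'
#' Per-probe log2 ratio = \code{dye_bias} +
#' \code{wave_coefficient * (local GC - genome GC)} + sum of planted CNV
#' shifts covering the probe + Gaussian noise. Self hybridizations (test =
#' reference) carry no true CNVs by definition, so \code{role = "self"}
#' requires an empty truth set.
#'
#' @param map a [make_probe_map()] probe map.
#' @param genome the \code{synthetic_genome} the map was built on; may be
#'   \code{NULL} when \code{wave_coefficient = 0} (the sequence is consulted
#'   only for the GC wave term).
#' @param truth a [truth_cnvs()] table of planted CNVs (default none).
#'   Overlapping truth CNVs are rejected.
#' @param role hybridization role: \code{"self"} (null control),
#'   \code{"high"} or \code{"low"} (comparative).
#' @param noise_sd per-probe Gaussian noise, log2 units (default 0.2).
#' @param wave_coefficient log2 units per unit of GC-fraction deviation
#'   (default 0: no genomic wave).
#' @param dye_bias global log2 offset (default 0).
#' @param gc_window window for local GC, bp (default 500).
#' @param seed integer seed.
#' @param hyb_id track identifier.
#' @return A \code{"ratio_track"}: list with \code{map}, \code{value}
#'   (per-probe log2 ratios), \code{hyb_id}, \code{role}, \code{truth}, and
#'   \code{meta} (seed and simulation parameters; normalization steps are
#'   appended here by the preprocessing functions).
#' @examples
#' b <- genome_build("toy", "chr1", 2e5)
#' pm <- make_probe_map(b, 1200, seed = 1)
#' tr <- simulate_hybridization(pm, role = "self", noise_sd = 0.1, seed = 2)
#' @export
simulate_hybridization <- function(map, genome = NULL, truth = NULL,
                                   role = c("self", "high", "low"),
                                   noise_sd = 0.2, wave_coefficient = 0,
                                   dye_bias = 0, gc_window = 500,
                                   seed = 1, hyb_id = role) {
  role <- match.arg(role)
  if (role == "self" && !is.null(truth) && nrow(truth) > 0) {
    stop("self hybridizations must carry no true CNVs")
  }
  if (wave_coefficient != 0 && is.null(genome)) {
    stop("a genome is required when wave_coefficient != 0")
  }
  hyb_id <- as.character(hyb_id)[1]
  n <- nrow(map)
  value <- rep(dye_bias, n)
  gc <- NULL
  if (wave_coefficient != 0) {
    gc <- probe_gc(genome, map, window = gc_window)
    value <- value + wave_coefficient * (gc - genome$gc_realized)
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    truth <- validate_gintervals(truth,
      build = if (!is.null(genome)) genome$build else NULL)
    if (any_self_overlap(truth)) {
      stop("overlapping truth CNVs on one track are not allowed")
    }
    for (k in seq_len(nrow(truth))) {
      hit <- map$chrom == truth$chrom[k] &
        map$start < truth$end[k] & truth$start[k] < map$end
      value[hit] <- value[hit] + truth$log2_shift[k]
    }
  }
  if (noise_sd > 0) {
    rs <- local_rng(seed + 202L)
    value <- value + rs$rnorm(n, 0, noise_sd)
  }
  structure(list(
    map = map, value = value, hyb_id = hyb_id, role = role,
    truth = truth, probe_gc = gc,
    meta = list(seed = seed, noise_sd = noise_sd,
                wave_coefficient = wave_coefficient, dye_bias = dye_bias,
                steps = character())
  ), class = "ratio_track")
}

any_self_overlap <- function(x) {
  if (nrow(x) < 2) return(FALSE)
  o <- order(x$chrom, x$start)
  s <- x[o, ]
  any(s$chrom[-1] == s$chrom[-nrow(s)] & s$start[-1] < s$end[-nrow(s)])
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("Ratio track '%s' (%s): %d probes, median %.4f, sd %.4f\n",
              x$hyb_id, x$role, length(x$value),
              stats::median(x$value, na.rm = TRUE),
              stats::sd(x$value, na.rm = TRUE)))
  if (length(x$meta$steps)) {
    cat("  steps:", paste(x$meta$steps, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Write a synthetic genome to FASTA
#'
#' @param genome a \code{synthetic_genome}.
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, filepath = path)
  invisible(path)
}
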
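#' Event-calling criterion: minimum log2 shift over minimum probe run
#'
#' The calling rule at the heart of the pipeline: a segment is reported as a
#' copy-number event only if its mean absolute log2 ratio reaches
#' \code{min_abs_shift} over at least \code{min_probes} consecutive observed
#' probes. The package default (0.5 log2 units over 5 probes) is the
#' criterion selected by calibration against self-self hybridizations; see
#' [calibration_sweep()].
#'
#' @param min_abs_shift minimum absolute segment mean, log2 units (> 0).
#' @param min_probes minimum consecutive probe count (>= 2).
#' @return An object of class \code{"cgh_criterion"}.
#' @examples
#' cgh_criterion(0.5, 5)
#' @export
cgh_criterion <- function(min_abs_shift = 0.5, min_probes = 5) {
  if (!(min_abs_shift > 0)) stop("min_abs_shift must be > 0")
  if (min_probes < 2) stop("min_probes must be >= 2")
  structure(list(min_abs_shift = as.numeric(min_abs_shift),
                 min_probes = as.integer(min_probes)),
            class = "cgh_criterion")
}

#' @export
print.cgh_criterion <- function(x, ...) {
  cat(sprintf("Calling criterion: |log2 ratio| >= %.3g over >= %d probes\n",
              x$min_abs_shift, x$min_probes))
  invisible(x)
}

#' Genomic resolution implied by a calling criterion
#'
#' The smallest genomic span that \code{min_probes} consecutive probes can
#' cover at the array's average pitch: \code{(min_probes - 1) *
#' mean_spacing}. At the default criterion (5 probes) and a 1.2 kb pitch
#' this is 4.8 kb.
#'
#' @param criterion a [cgh_criterion()].
#' @param mean_spacing mean probe spacing in bp (> 0).
#' @return Resolution in bp.
#' @examples
#' resolution(cgh_criterion(0.5, 5), 1200)  # 4800
#' @export
resolution <- function(criterion, mean_spacing) {
  stopifnot(inherits(criterion, "cgh_criterion"), mean_spacing > 0)
  (criterion$min_probes - 1) * mean_spacing
}

#' Penalized least-squares segmentation of a ratio track
#'
#' Partitions the probe-ordered log2 ratios of each chromosome into
#' contiguous constant-mean segments, approximately minimizing total
#' within-segment squared error plus \code{penalty} per change point. The
#' search recursively carves out the best sub-interval of every current
#' segment (candidate intervals from a geometric window ladder, boundaries
#' then refined by exact coordinate-wise search), accepting a carve only if
#' its exact SSE reduction exceeds \code{penalty} times the number of new
#' change points. Interval carving detects short CNVs embedded in long
#' chromosomes, which a single-split search cannot. The procedure is fully
#' deterministic; ties are broken toward fewer segments, then the leftmost
#' boundary. Missing (masked) probe values split the track: masked
#' stretches form their own segments with \code{NA} mean and are never
#' fused across.
#'
#' @param track a \code{ratio_track}.
#' @param penalty per-change-point penalty in squared log2 units; default
#'   \code{NULL} uses \eqn{z^2 \hat\sigma^2 / 2} with \eqn{z = 4.5} and
#'   \eqn{\hat\sigma} the robust difference-based noise estimate
#'   \code{mad(diff(y)) / sqrt(2)}, i.e. spurious carves are controlled at
#'   roughly the 4.5-sigma level genome-wide.
#' @return A data frame of class \code{"cgh_segments"}, one row per
#'   segment: \code{chrom}, \code{istart}/\code{iend} (1-based inclusive
#'   probe indices into the track's map), \code{n_probes}, \code{mean}
#'   (\code{NA} for masked stretches). Attributes: \code{penalty},
#'   \code{sigma}. Segments tile the probes of each chromosome without gaps
#'   or overlap.
#' @export
segment_track <- function(track, penalty = NULL) {
  stopifnot(inherits(track, "ratio_track"))
  y <- track$value
  map <- track$map
  sigma <- estimate_noise_sd(y, map$chrom)
  if (is.null(penalty)) penalty <- (4.5^2 / 2) * sigma^2
  if (!is.finite(penalty) || penalty < 0) stop("penalty must be >= 0")
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    yc <- y[idx]
    # split into runs of observed probes; masked stretches kept as NA rows
    obs <- is.finite(yc)
    r <- rle(obs)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, istart = idx[starts[j]], iend = idx[ends[j]],
          n_probes = r$lengths[j], mean = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      run <- yc[starts[j]:ends[j]]
      bounds <- carve_segments(run, penalty)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        istart = idx[starts[j] + bounds$from - 1],
        iend = idx[starts[j] + bounds$to - 1],
        n_probes = bounds$to - bounds$from + 1,
        mean = bounds$mean, stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  attr(seg, "penalty") <- penalty
  attr(seg, "sigma") <- sigma
  class(seg) <- c("cgh_segments", "data.frame")
  seg
}

# robust per-probe noise SD from within-chromosome first differences
estimate_noise_sd <- function(y, chrom) {
  d <- unlist(lapply(split(y, chrom), diff), use.names = FALSE)
  d <- d[is.finite(d)]
  if (length(d) < 2) return(0)
  stats::mad(d) / sqrt(2)
}

# recursive interval carving of one gap-free numeric run; returns a
# data.frame(from, to, mean) of segments in order (1-based, inclusive)
carve_segments <- function(y, penalty) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cuts <- carve_recurse(1L, n, cs, penalty)
  from <- c(1L, cuts + 1L)
  to <- c(cuts, n)
  data.frame(from = from, to = to,
             mean = (cs[to + 1] - cs[from]) / (to - from + 1))
}

# returns sorted interior cut positions c (segment boundary after probe c)
carve_recurse <- function(lo, hi, cs, penalty) {
  n <- hi - lo + 1L
  if (n < 2L) return(integer(0))
  best <- best_carve(lo, hi, cs, penalty)
  if (is.null(best)) return(integer(0))
  a <- best$a; b <- best$b
  cuts <- integer(0)
  if (a > lo) {
    cuts <- c(cuts, carve_recurse(lo, a - 1L, cs, penalty), a - 1L)
  }
  cuts <- c(cuts, carve_recurse(a, b, cs, penalty))
  if (b < hi) {
    cuts <- c(cuts, b, carve_recurse(b + 1L, hi, cs, penalty))
  }
  sort(cuts)
}

# exact SSE gain of carving [a, b] out of [lo, hi] minus change-point cost
carve_net_gain_b <- function(a_vec, b, lo, hi, cs, penalty) {
  n <- hi - lo + 1L
  S <- cs[hi + 1] - cs[lo]
  k <- b - a_vec + 1
  s <- cs[b + 1] - cs[a_vec]
  full <- k == n
  k[full] <- n - 1  # placeholder, overwritten below
  gain <- s^2 / k + (S - s)^2 / pmax(n - k, 1) - S^2 / n
  gain[full] <- -Inf
  gain - penalty * ((a_vec > lo) + (b < hi))
}

best_carve <- function(lo, hi, cs, penalty) {
  n <- hi - lo + 1L
  S <- cs[hi + 1] - cs[lo]
  mu <- S / n
  # candidate intervals: best position for each geometric width
  widths <- unique(pmin(2^(0:floor(log2(max(n - 1, 1)))), n - 1L))
  cand_a <- integer(0); cand_w <- integer(0); cand_stat <- numeric(0)
  for (w in widths) {
    a <- lo:(hi - w + 1L)
    s <- cs[a + w] - cs[a]
    d <- s / w - mu
    stat <- w * d^2 * n / (n - w)
    i <- which.max(stat)
    cand_a <- c(cand_a, a[i]); cand_w <- c(cand_w, w)
    cand_stat <- c(cand_stat, stat[i])
  }
  # refine the strongest candidates only; on small segments refine all
  keep <- order(-cand_stat)
  if (n > 4096L) keep <- keep[seq_len(min(5L, length(keep)))]
  best <- NULL
  for (j in keep) {
    ref <- refine_interval(cand_a[j], cand_a[j] + cand_w[j] - 1L,
                           lo, hi, cs, penalty, width = cand_w[j])
    if (is.null(best) || ref$net > best$net + 1e-12) best <- ref
  }
  if (is.null(best) || best$net <= 1e-9) return(NULL)
  best
}

# coordinate-wise exact refinement of an interval's boundaries; on large
# segments each scan is restricted to a window around the current
# boundary (small segments get exhaustive scans)
refine_interval <- function(a, b, lo, hi, cs, penalty, width = b - a + 1L) {
  n <- hi - lo + 1L
  S <- cs[hi + 1] - cs[lo]
  win <- if (n <= 4096L) n else max(4L * width, 256L)
  for (iter in 1:12) {
    a_cand <- max(lo, a - win):min(b, a + win)
    net_a <- carve_net_gain_b(a_cand, b, lo, hi, cs, penalty)
    a_new <- a_cand[which.max(net_a)]
    # optimize b given a
    b_cand <- max(a_new, b - win):min(hi, b + win)
    k <- b_cand - a_new + 1
    s <- cs[b_cand + 1] - cs[a_new]
    gain <- s^2 / k + (S - s)^2 / pmax(n - k, 1) - S^2 / n
    gain[k == n] <- -Inf
    net_b <- gain - penalty * ((a_new > lo) + (b_cand < hi))
    b_new <- b_cand[which.max(net_b)]
    if (a_new == a && b_new == b) break
    a <- a_new; b <- b_new
  }
  list(a = a, b = b, net = max(net_b))
}

#' Call copy-number events from a segmentation
#'
#' Applies a [cgh_criterion()] to segment means: segments with
#' \code{|mean| >= min_abs_shift} spanning \code{>= min_probes} observed
#' probes qualify; adjacent qualifying segments of the same sign are fused
#' into a single event (pooled mean). Events carry genomic intervals from
#' the start of their first probe to the end of their last probe.
#'
#' @param segments a [segment_track()] result.
#' @param track the \code{ratio_track} that was segmented.
#' @param criterion a [cgh_criterion()].
#' @return A data frame of class \code{c("cnv_events", "gintervals")}:
#'   \code{chrom}, \code{start}, \code{end}, \code{kind} (gain/loss),
#'   \code{log_r} (event mean log2 ratio), \code{n_probes}, \code{hyb_id},
#'   \code{istart}, \code{iend}.
#' @export
call_events <- function(segments, track, criterion = cgh_criterion()) {
  stopifnot(inherits(segments, "cgh_segments"),
            inherits(track, "ratio_track"),
            inherits(criterion, "cgh_criterion"))
  q <- !is.na(segments$mean) &
    abs(segments$mean) >= criterion$min_abs_shift &
    segments$n_probes >= criterion$min_probes
  empty <- empty_events()
  if (!any(q)) return(empty)
  s <- segments[q, , drop = FALSE]
  sgn <- sign(s$mean)
  # fuse runs of adjacent qualifying same-sign segments
  new_run <- c(TRUE, !(s$chrom[-1] == s$chrom[-nrow(s)] &
                       s$istart[-1] == s$iend[-nrow(s)] + 1L &
                       sgn[-1] == sgn[-nrow(s)]))
  grp <- cumsum(new_run)
  map <- track$map
  rows <- lapply(split(seq_len(nrow(s)), grp), function(i) {
    istart <- s$istart[i[1]]
    iend <- s$iend[i[length(i)]]
    np <- sum(s$n_probes[i])
    m <- sum(s$mean[i] * s$n_probes[i]) / np
    data.frame(chrom = s$chrom[i[1]], start = map$start[istart],
               end = map$end[iend],
               kind = if (m > 0) "gain" else "loss",
               log_r = m, n_probes = np, hyb_id = track$hyb_id,
               istart = istart, iend = iend, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(match(ev$chrom, unique(map$chrom)), ev$start), ]
  rownames(ev) <- NULL
  class(ev) <- c("cnv_events", "gintervals", "data.frame")
  ev
}

empty_events <- function() {
  ev <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   kind = character(), log_r = numeric(),
                   n_probes = integer(), hyb_id = character(),
                   istart = integer(), iend = integer(),
                   stringsAsFactors = FALSE)
  class(ev) <- c("cnv_events", "gintervals", "data.frame")
  ev
}

#' Segment a track and call CNV events
#'
#' The package's central fitting function: segments a log2-ratio track
#' ([segment_track()]) and calls copy-number events under a calling
#' criterion ([call_events()]). Returns a fitted-model object with the
#' usual accessor methods (\code{print}, \code{summary}, \code{coef},
#' \code{fitted}, \code{residuals}, \code{plot}).
#'
#' @param track a \code{ratio_track} (normalize first, e.g. with
#'   [median_center()], if a dye bias may be present).
#' @param criterion a [cgh_criterion()] (default 0.5 log2 over 5 probes).
#' @param penalty segmentation penalty; see [segment_track()].
#' @return An object of class \code{"cgh_fit"} with components
#'   \code{track}, \code{segments}, \code{events}, \code{criterion},
#'   \code{penalty}, \code{sigma}.
#' @examples
#' b <- genome_build("toy", "chr1", 3e5)
#' pm <- make_probe_map(b, 1200, seed = 1)
#' tc <- truth_cnvs("chr1", 100000, 120000, 0.8)
#' tr <- simulate_hybridization(pm, truth = tc, role = "high",
#'                              noise_sd = 0.2, seed = 7)
#' fit <- cgh_call(median_center(tr))
#' fit$events
#' @export
cgh_call <- function(track, criterion = cgh_criterion(), penalty = NULL) {
  segments <- segment_track(track, penalty = penalty)
  events <- call_events(segments, track, criterion)
  structure(list(track = track, segments = segments, events = events,
                 criterion = criterion,
                 penalty = attr(segments, "penalty"),
                 sigma = attr(segments, "sigma")),
            class = "cgh_fit")
}

#' @export
print.cgh_fit <- function(x, ...) {
  cat(sprintf("CGH fit of track '%s' (%s): %d probes, %d segments, %d event(s)\n",
              x$track$hyb_id, x$track$role, length(x$track$value),
              nrow(x$segments), nrow(x$events)))
  print(x$criterion)
  cat(sprintf("Segmentation penalty %.4g (noise sd estimate %.4g)\n",
              x$penalty, x$sigma))
  invisible(x)
}

#' @export
summary.cgh_fit <- function(object, ...) {
  ev <- object$events
  cat(sprintf("Track '%s' (%s)\n", object$track$hyb_id, object$track$role))
  cat(sprintf("  probes: %d  segments: %d  noise sd: %.4g\n",
              length(object$track$value), nrow(object$segments),
              object$sigma))
  cat(sprintf("  events: %d (%d gain, %d loss), total span %s bp\n",
              nrow(ev), sum(ev$kind == "gain"), sum(ev$kind == "loss"),
              format(sum(span(ev)), big.mark = ",")))
  if (nrow(ev)) print.data.frame(ev[c("chrom", "start", "end", "kind",
                                      "log_r", "n_probes")])
  invisible(ev)
}

#' @export
coef.cgh_fit <- function(object, ...) {
  object$segments$mean
}

#' @export
fitted.cgh_fit <- function(object, ...) {
  f <- rep(NA_real_, length(object$track$value))
  s <- object$segments
  for (i in seq_len(nrow(s))) f[s$istart[i]:s$iend[i]] <- s$mean[i]
  f
}

#' @export
residuals.cgh_fit <- function(object, ...) {
  object$track$value - fitted.cgh_fit(object)
}

#' @export
plot.cgh_fit <- function(x, chrom = NULL, ...) {
  map <- x$track$map
  chroms <- if (is.null(chrom)) unique(map$chrom) else chrom
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  f <- fitted.cgh_fit(x)
  for (ch in chroms) {
    i <- which(map$chrom == ch)
    pos <- (map$start[i] + map$end[i]) / 2
    graphics::plot(pos, x$track$value[i], pch = ".", col = "grey40",
                   xlab = "", ylab = "log2 ratio", main = ch, ...)
    graphics::lines(pos, f[i], col = "red", lwd = 2)
    graphics::abline(h = c(-x$criterion$min_abs_shift,
                           x$criterion$min_abs_shift), lty = 3)
    ev <- x$events[x$events$chrom == ch, ]
    if (nrow(ev)) {
      graphics::rect(ev$start, graphics::par("usr")[3], ev$end,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("orange", 0.2),
                     border = NA)
    }
  }
  invisible(x)
}
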
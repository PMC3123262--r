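#' Median-center a ratio track
#'
#' Removes the global dye-bias offset by subtracting the track median, the
#' generic normalization applied before event calling. Probe order, the
#' probe map and planted CNV contrasts are unchanged; the output median is 0.
#'
#' @param track a \code{ratio_track}.
#' @return The centered \code{ratio_track}, with \code{"median_center"}
#'   appended to its provenance steps.
#' @export
median_center <- function(track) {
  stopifnot(inherits(track, "ratio_track"))
  v <- track$value
  if (all(is.na(v))) stop("track has no observed values")
  track$value <- v - stats::median(v, na.rm = TRUE)
  track$meta$steps <- c(track$meta$steps, "median_center")
  track
}

#' Remove a GC-correlated genomic wave from a track
#'
#' Fits a smooth local-regression curve of log2 ratio on per-probe GC
#' fraction and subtracts it. The fit is locally linear with one
#' robustifying reweighting pass, so isolated true CNVs do not drag the
#' curve. Off by default in the calling pipeline: the reference analysis
#' flags GC-driven calls post hoc rather than correcting the signal; this
#' function exists to quantify how much of the shared-call artifact a wave
#' correction would remove.
#'
#' @param track a \code{ratio_track}.
#' @param probe_gc per-probe GC fractions aligned to the track's map; if
#'   missing, the values stored on the track at simulation time are used.
#' @param span local-regression span as a fraction of the probes
#'   (default 0.4).
#' @return The corrected \code{ratio_track}; its \code{meta$gc_fit} records
#'   the fitted values that were subtracted. If the GC vector is (near-)
#'   constant the track is returned unchanged with a warning.
#' @export
gc_wave_correct <- function(track, probe_gc = NULL, span = 0.4) {
  stopifnot(inherits(track, "ratio_track"))
  if (is.null(probe_gc)) probe_gc <- track$probe_gc
  if (is.null(probe_gc)) stop("per-probe GC fractions are required")
  if (length(probe_gc) != length(track$value)) {
    stop("probe_gc must align with the track's probes")
  }
  if (any(probe_gc < 0 | probe_gc > 1, na.rm = TRUE)) {
    stop("probe_gc values must lie in [0, 1]")
  }
  if (diff(range(probe_gc, na.rm = TRUE)) < 1e-6) {
    warning("GC vector is constant; no wave to remove")
    return(track)
  }
  ok <- is.finite(track$value) & is.finite(probe_gc)
  fit <- stats::loess(track$value[ok] ~ probe_gc[ok], degree = 1,
                      span = span, family = "symmetric",
                      control = stats::loess.control(
                        iterations = 2, surface = "direct"))
  adj <- rep(NA_real_, length(track$value))
  adj[ok] <- stats::predict(fit, newdata = probe_gc[ok])
  track$value[ok] <- track$value[ok] - adj[ok]
  track$meta$gc_fit <- adj
  track$meta$steps <- c(track$meta$steps, "gc_wave_correct")
  track
}
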
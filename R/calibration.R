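#' Sweep calling criteria over self-self (null) tracks
#'
#' Self-self hybridizations compare a sample against itself, so every called
#' event is a false positive by construction. This sweep segments each self
#' track once and then counts, for every (shift, probe-count) cell of a
#' criterion grid, the total number of events called across the tracks —
#' the empirical false-positive landscape from which a calling criterion is
#' chosen.
#'
#' Because tightening either threshold can only shrink the set of
#' qualifying segments, the counts are non-increasing along both grid axes;
#' this invariant is asserted after every sweep.
#'
#' @param self_tracks a \code{ratio_track} or list of them; all must have
#'   \code{role == "self"}.
#' @param shift_values numeric vector of minimum absolute log2 shifts
#'   (default \code{seq(0.3, 0.7, by = 0.1)}).
#' @param probe_counts integer vector of minimum probe counts
#'   (default \code{3:7}).
#' @param penalty segmentation penalty passed to [segment_track()].
#' @return An object of class \code{"calibration_grid"}: list with
#'   \code{fp} (matrix of false-positive counts, rows = shifts, cols =
#'   probe counts), \code{shift_values}, \code{probe_counts},
#'   \code{n_self_tracks}.
#' @export
calibration_sweep <- function(self_tracks,
                              shift_values = seq(0.3, 0.7, by = 0.1),
                              probe_counts = 3:7, penalty = NULL) {
  if (inherits(self_tracks, "ratio_track")) self_tracks <- list(self_tracks)
  stopifnot(length(self_tracks) > 0,
            length(shift_values) > 0, length(probe_counts) > 0)
  roles <- vapply(self_tracks, function(t) t$role, "")
  if (any(roles != "self")) {
    stop("calibration requires self-self tracks only; found role(s): ",
         paste(unique(roles[roles != "self"]), collapse = ", "))
  }
  shift_values <- sort(shift_values)
  probe_counts <- sort(as.integer(probe_counts))
  fp <- matrix(0L, length(shift_values), length(probe_counts),
               dimnames = list(shift = format(shift_values),
                               probes = probe_counts))
  for (tr in self_tracks) {
    seg <- segment_track(tr, penalty = penalty)
    for (i in seq_along(shift_values)) {
      for (j in seq_along(probe_counts)) {
        crit <- cgh_criterion(shift_values[i], probe_counts[j])
        fp[i, j] <- fp[i, j] + nrow(call_events(seg, tr, crit))
      }
    }
  }
  grid <- structure(list(fp = fp, shift_values = shift_values,
                         probe_counts = probe_counts,
                         n_self_tracks = length(self_tracks)),
                    class = "calibration_grid")
  assert_grid_monotone(grid)
  grid
}

#' Combine calibration grids from disjoint sets of self tracks
#'
#' Adds the false-positive counts of grids computed over the same
#' (shift, probe-count) axes, so large null cohorts can be swept in
#' batches.
#'
#' @param ... \code{calibration_grid} objects with identical axes.
#' @return A combined \code{calibration_grid}.
#' @export
combine_grids <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) &&
      !inherits(gs[[1]], "calibration_grid")) {
    gs <- gs[[1]]
  }
  stopifnot(length(gs) > 0)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    stopifnot(identical(g$shift_values, ref$shift_values),
              identical(g$probe_counts, ref$probe_counts))
    ref$fp <- ref$fp + g$fp
    ref$n_self_tracks <- ref$n_self_tracks + g$n_self_tracks
  }
  assert_grid_monotone(ref)
  ref
}

assert_grid_monotone <- function(grid) {
  fp <- grid$fp
  ok_rows <- nrow(fp) < 2 || all(fp[-1, , drop = FALSE] <=
                                   fp[-nrow(fp), , drop = FALSE])
  ok_cols <- ncol(fp) < 2 || all(fp[, -1, drop = FALSE] <=
                                   fp[, -ncol(fp), drop = FALSE])
  if (!(ok_rows && ok_cols)) {
    stop("calibration grid is not monotone non-increasing; ",
         "this indicates an event-fusion edge case worth inspecting")
  }
  invisible(grid)
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf(
    "Calibration grid over %d self track(s): false-positive event counts\n",
    x$n_self_tracks))
  print(x$fp)
  invisible(x)
}

#' Write a calibration grid as a TSV matrix
#'
#' @param grid a \code{calibration_grid}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_grid_tsv <- function(grid, path) {
  m <- grid$fp
  df <- data.frame(min_abs_shift = grid$shift_values, m,
                   check.names = FALSE)
  names(df) <- c("min_abs_shift", paste0("probes_", grid$probe_counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select a calling criterion from a calibration grid
#'
#' Returns the least-stringent criterion — smallest shift threshold first,
#' then smallest probe count — whose false-positive total over the self
#' tracks is at most \code{fp_budget}. If no cell meets the budget, the
#' global-minimum cell is returned (ties again broken toward least
#' stringent). Preferring the least-stringent qualifying cell keeps the
#' criterion at the resolution limit rather than the most conservative
#' corner of the grid.
#'
#' @param grid a [calibration_sweep()] result.
#' @param fp_budget maximum tolerated false-positive event count
#'   (default 0).
#' @return A [cgh_criterion()].
#' @export
select_criterion <- function(grid, fp_budget = 0) {
  stopifnot(inherits(grid, "calibration_grid"))
  fp <- grid$fp
  cells <- expand.grid(i = seq_along(grid$shift_values),
                       j = seq_along(grid$probe_counts))
  # least-stringent order: shift ascending, then probe count ascending
  cells <- cells[order(grid$shift_values[cells$i],
                       grid$probe_counts[cells$j]), ]
  counts <- fp[cbind(cells$i, cells$j)]
  ok <- which(counts <= fp_budget)
  pick <- if (length(ok)) ok[1] else which(counts == min(counts))[1]
  cgh_criterion(grid$shift_values[cells$i[pick]],
                grid$probe_counts[cells$j[pick]])
}

#' Empirical false-discovery proxy from self and comparative tracks
#'
#' Self-self tracks have no true events, so a false-discovery *rate* is
#' undefined on them alone; what is computable is a false-positive count,
#' and — when comparative tracks are available — the ratio of mean self
#' events to mean comparative events, a rough proxy for the fraction of
#' comparative calls explained by the null process.
#'
#' @param self_events integer vector of event counts on self tracks.
#' @param comparative_events integer vector of event counts on comparative
#'   tracks.
#' @return List with \code{mean_self}, \code{mean_comparative},
#'   \code{fdr_proxy}.
#' @export
fdr_proxy <- function(self_events, comparative_events) {
  ms <- mean(self_events)
  mc <- mean(comparative_events)
  list(mean_self = ms, mean_comparative = mc,
       fdr_proxy = if (mc > 0) ms / mc else NA_real_)
}
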
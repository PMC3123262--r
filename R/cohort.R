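#' Assemble called events from several hybridizations into a cohort
#'
#' @param events a data frame of events (columns \code{chrom},
#'   \code{start}, \code{end}, \code{hyb_id}; optionally \code{kind},
#'   \code{log_r}, ...), e.g. row-bound [call_events()] results, or a list
#'   of per-hybridization event tables.
#' @param roles optional named character vector mapping \code{hyb_id} to a
#'   role (\code{"self"}, \code{"high"}, \code{"low"}). If missing, roles
#'   are inferred from hybridization ids of the form \code{Self1},
#'   \code{High2}, \code{Low3}.
#' @return An object of class \code{"event_cohort"}: list with
#'   \code{events} (validated [gintervals()] with \code{hyb_id}) and
#'   \code{hybs} (data frame \code{hyb_id}, \code{role}).
#' @export
event_cohort <- function(events, roles = NULL) {
  if (is.list(events) && !is.data.frame(events)) {
    events <- do.call(rbind, events)
  }
  if (is.null(events) || nrow(events) == 0) {
    events <- empty_events()
  }
  stopifnot(all(c("chrom", "start", "end", "hyb_id") %in% names(events)))
  events <- validate_gintervals(as.data.frame(events))
  hyb_ids <- unique(events$hyb_id)
  if (is.null(roles)) {
    roles <- stats::setNames(tolower(sub("[0-9]+$", "", hyb_ids)), hyb_ids)
  }
  known <- roles[hyb_ids]
  known[is.na(known)] <- "unknown"
  structure(list(events = events,
                 hybs = data.frame(hyb_id = hyb_ids,
                                   role = unname(known),
                                   stringsAsFactors = FALSE)),
            class = "event_cohort")
}

#' @export
print.event_cohort <- function(x, ...) {
  cat(sprintf("Event cohort: %d events across %d hybridization(s)\n",
              nrow(x$events), nrow(x$hybs)))
  print(table(x$events$hyb_id))
  invisible(x)
}

#' Flag events shared across hybridizations
#'
#' An event is "shared" when it overlaps (within \code{max_gap} bp) at
#' least one event called in a *different* hybridization, regardless of
#' gain/loss sign. Recurrence of the same locus across independent
#' comparisons points to a systematic artifact (e.g. a GC-driven wave)
#' rather than a true copy-number difference. Sign agreement is reported
#' separately as \code{same_type}, because recurrent artifact loci can be
#' hit with either sign in different hybridizations.
#'
#' @param cohort an [event_cohort()].
#' @param max_gap tolerance in bp: events separated by fewer than
#'   \code{max_gap} bp still count as the same locus (default 0: they must
#'   share at least one base).
#' @return A data frame aligned with \code{cohort$events}: columns
#'   \code{shared} (logical), \code{partners} (comma-separated partner
#'   hybridization ids, \code{""} if none) and \code{same_type} (logical,
#'   \code{NA} for unshared events; \code{TRUE} iff all partners carry the
#'   same gain/loss kind as the event).
#' @export
classify_shared <- function(cohort, max_gap = 0) {
  stopifnot(inherits(cohort, "event_cohort"))
  ev <- cohort$events
  n <- nrow(ev)
  out <- data.frame(shared = logical(n),
                    partners = character(n),
                    same_type = rep(NA, n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  gr <- as_granges(ev)
  # our half-open separation s qualifies iff s < max_gap, which in IRanges
  # gap terms is maxgap = max_gap - 1 (-1 = plain overlap)
  hits <- GenomicRanges::findOverlaps(gr, maxgap = max_gap - 1,
                                      drop.self = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- ev$hyb_id[qh] != ev$hyb_id[sh]
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    part <- split(sh, qh)
    idx <- as.integer(names(part))
    out$shared[idx] <- TRUE
    out$partners[idx] <- vapply(part, function(p) {
      paste(sort(unique(ev$hyb_id[p])), collapse = ",")
    }, "")
    if (!is.null(ev$kind)) {
      out$same_type[idx] <- vapply(seq_along(part), function(k) {
        all(ev$kind[part[[k]]] == ev$kind[idx[k]])
      }, NA)
    }
  }
  out
}

#' Merge a cohort's events into unique loci
#'
#' Pools the events of all hybridizations and merges overlapping intervals
#' ([merge_intervals()]) into maximal disjoint loci; each locus records its
#' member events. The locus count is the number of unique variant regions
#' in the cohort.
#'
#' @param cohort an [event_cohort()].
#' @param max_gap merge events separated by at most this many bp
#'   (default 0).
#' @return A [gintervals()] table of loci with columns \code{n_members}
#'   and \code{members} (list of integer row indices into
#'   \code{cohort$events}), sorted by chromosome then start.
#' @export
unique_loci <- function(cohort, max_gap = 0) {
  stopifnot(inherits(cohort, "event_cohort"))
  ev <- cohort$events
  if (nrow(ev) == 0) {
    out <- gintervals(character(), numeric(), numeric())
    out$n_members <- integer(0)
    out$members <- list()
    return(out)
  }
  loci <- merge_intervals(ev, max_gap = max_gap)
  ov <- GenomicRanges::findOverlaps(as_granges(ev), as_granges(loci))
  memb <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  loci$n_members <- 0L
  loci$members <- vector("list", nrow(loci))
  idx <- as.integer(names(memb))
  loci$n_members[idx] <- lengths(memb)
  loci$members[idx] <- unname(memb)
  loci
}

#' Filter events by genomic span
#'
#' Keeps events strictly larger than \code{min_span} bp ("larger than
#' 10 kb" is a strict inequality: a 10,000 bp event is dropped, a
#' 10,001 bp event kept). Input order is preserved.
#'
#' @param events a [gintervals()] table of events.
#' @param min_span span threshold in bp (default 10000).
#' @return The filtered events.
#' @export
size_filter <- function(events, min_span = 10000) {
  events[span(events) > min_span, , drop = FALSE]
}

#' Summarize a cohort of called events
#'
#' @param cohort an [event_cohort()].
#' @param shared optional [classify_shared()] result for the cohort; if
#'   supplied, shared fractions are included.
#' @param min_span span threshold for the large-event subset (default
#'   10000 bp).
#' @return A list: \code{per_hyb} (data frame \code{hyb_id}, \code{role},
#'   \code{n_events}), \code{total}, \code{by_role} (min/max/mean event
#'   count per role subset), and — when \code{shared} is given —
#'   \code{shared_fraction} and \code{shared_fraction_large}.
#' @export
summarize_cohort <- function(cohort, shared = NULL, min_span = 10000) {
  stopifnot(inherits(cohort, "event_cohort"))
  ev <- cohort$events
  per_hyb <- cohort$hybs
  per_hyb$n_events <- vapply(per_hyb$hyb_id,
                             function(h) sum(ev$hyb_id == h), 0L)
  by_role <- lapply(split(per_hyb$n_events, per_hyb$role), function(v) {
    list(n = length(v), min = min(v), max = max(v), mean = mean(v))
  })
  out <- list(per_hyb = per_hyb, total = nrow(ev), by_role = by_role)
  if (!is.null(shared)) {
    stopifnot(nrow(shared) == nrow(ev))
    out$shared_fraction <- mean(shared$shared)
    big <- span(ev) > min_span
    out$shared_fraction_large <-
      if (any(big)) mean(shared$shared[big]) else NA_real_
  }
  out
}

#' Summary statistics of per-hybridization event counts
#'
#' Works on a plain count table (e.g. a hybridization plan with an
#' \code{events} column) rather than on called events.
#'
#' @param counts data frame with columns \code{hyb_id} (or \code{type}),
#'   \code{role}, \code{events}.
#' @param roles optional subset of roles (e.g. \code{c("high", "low")} for
#'   the comparative hybridizations).
#' @return List with \code{n}, \code{total}, \code{min}, \code{max},
#'   \code{mean}.
#' @export
summarize_counts <- function(counts, roles = NULL) {
  stopifnot(all(c("role", "events") %in% names(counts)))
  v <- if (is.null(roles)) counts$events else
    counts$events[counts$role %in% roles]
  list(n = length(v), total = sum(v), min = min(v), max = max(v),
       mean = mean(v))
}

#' Write a cohort summary as TSV
#'
#' @param summary a [summarize_cohort()] result.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort_summary <- function(summary, path) {
  utils::write.table(summary$per_hyb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
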
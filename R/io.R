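#' Write a ratio track as 5-column TSV
#'
#' Columns: probe_id, chrom, start, end, log2_ratio. Provenance (hyb id,
#' role, seed, normalization steps) is stored in \code{#key<TAB>value}
#' header comments so a track round-trips losslessly.
#'
#' @param track a \code{ratio_track}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(hyb_id = track$hyb_id, role = track$role,
            seed = as.character(track$meta$seed),
            noise_sd = as.character(track$meta$noise_sd),
            steps = paste(track$meta$steps, collapse = ","))
  writeLines(sprintf("#%s\t%s", names(meta), meta), con)
  writeLines("probe_id\tchrom\tstart\tend\tlog2_ratio", con)
  writeLines(sprintf("%s\t%s\t%d\t%d\t%.10g", track$map$probe_id,
                     track$map$chrom, as.integer(track$map$start),
                     as.integer(track$map$end), track$value), con)
  invisible(path)
}

#' Read a ratio track from 5-column TSV
#'
#' @param path path written by [write_track_tsv()].
#' @return A \code{ratio_track}.
#' @export
read_track_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "numeric"))
  map <- data.frame(probe_id = tab$probe_id, chrom = tab$chrom,
                    start = tab$start, end = tab$end,
                    stringsAsFactors = FALSE)
  gaps <- unlist(lapply(split(map$start, map$chrom), diff),
                 use.names = FALSE)
  attr(map, "mean_spacing") <- if (length(gaps)) mean(gaps) else NA_real_
  class(map) <- c("probe_map", "data.frame")
  steps <- if (is.null(meta$steps) || !nzchar(meta$steps)) character() else
    strsplit(meta$steps, ",", fixed = TRUE)[[1]]
  structure(list(
    map = map, value = tab$log2_ratio,
    hyb_id = if (is.null(meta$hyb_id)) "track" else meta$hyb_id,
    role = if (is.null(meta$role)) "self" else meta$role,
    truth = NULL, probe_gc = NULL,
    meta = list(seed = if (is.null(meta$seed)) NA else
                  as.integer(meta$seed),
                noise_sd = if (is.null(meta$noise_sd)) NA else
                  as.numeric(meta$noise_sd),
                steps = steps)
  ), class = "ratio_track")
}

#' Write a ratio track as bedGraph
#'
#' @param track a \code{ratio_track}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track$hyb_id), con)
  writeLines(sprintf("%s\t%d\t%d\t%.10g", track$map$chrom,
                     as.integer(track$map$start),
                     as.integer(track$map$end), track$value), con)
  invisible(path)
}

#' Write called events as BED6 and as an event table TSV
#'
#' BED6 uses name = hybridization id, score = 1000 x |log2 ratio| capped
#' at 1000, strand = "." (array CGH is strandless). The TSV mirrors a
#' publication-style event table: Type, Chr, Start, End, Length, Log R.
#'
#' @param events a [call_events()] result.
#' @param path output path (extension decides nothing; pick via
#'   \code{format}).
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_events <- function(events, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- events
    x$name <- events$hyb_id
    x$score <- pmin(1000, round(1000 * abs(events$log_r)))
    x$strand <- "."
    write_bed(x, path)
  } else {
    df <- data.frame(Type = events$hyb_id, Chr = events$chrom,
                     Start = events$start, End = events$end,
                     Length = events$end - events$start,
                     LogR = round(events$log_r, 4))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "cghintegrity")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

parse_printed_number <- function(x) {
  as.numeric(gsub(",", "", x, fixed = TRUE))
}

#' Load the packaged table of published large CNV events
#'
#' The packaged fixture transcribes a published table of 58 copy-number
#' events larger than 10 kb called across 10 hybridizations (4 self-self
#' controls and 6 comparative), with coordinates exactly as printed
#' (comma thousand-separators preserved in the file and stripped at
#' parse time). Loading verifies the transcription: 58 rows and
#' Length = End - Start on every row.
#'
#' @return An [event_cohort()] whose events carry \code{log_r},
#'   \code{kind} (sign of Log R) and \code{shared} (the printed Yes/No
#'   flag as logical).
#' @export
load_table2_fixture <- function() {
  tab <- utils::read.table(fixture_path("table2_events.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  ev <- data.frame(
    chrom = tab$chr,
    start = parse_printed_number(tab$start),
    end = parse_printed_number(tab$end),
    hyb_id = tab$type,
    log_r = as.numeric(tab$log_r),
    shared = tab$shared == "Yes",
    stringsAsFactors = FALSE)
  ev$kind <- ifelse(ev$log_r > 0, "gain", "loss")
  printed_len <- parse_printed_number(tab$length)
  if (nrow(ev) != 58 || any(ev$end - ev$start != printed_len)) {
    stop("event-table fixture failed its integrity check")
  }
  event_cohort(ev)
}

#' Load the packaged hybridization plan with event counts
#'
#' Ten hybridizations: for each, the test and reference cell lines, the
#' hybridization type (Self/High/Low + lineage number) and the number of
#' events called on it in the reference analysis.
#'
#' @return A data frame: \code{no}, \code{test}, \code{ref},
#'   \code{hyb_id}, \code{role} (self/high/low), \code{events}.
#' @export
load_table1_fixture <- function() {
  tab <- utils::read.table(fixture_path("table1_hybridizations.tsv"),
                           sep = "\t", header = TRUE,
                           colClasses = c("integer", "character",
                                          "character", "character",
                                          "integer"))
  out <- data.frame(no = tab$no, test = tab$test, ref = tab$ref,
                    hyb_id = tab$type,
                    role = tolower(sub("[0-9]+$", "", tab$type)),
                    events = tab$events, stringsAsFactors = FALSE)
  if (nrow(out) != 10) {
    stop("hybridization-plan fixture failed its integrity check")
  }
  out
}

#' Write a resolved-configuration snapshot next to pipeline outputs
#'
#' Every pipeline run should leave a machine-readable record of the exact
#' parameters and seeds used; this writes one as YAML.
#'
#' @param config a named list of resolved parameters.
#' @param path output path (conventionally \code{config_snapshot.yaml} in
#'   the output directory).
#' @return Invisibly, \code{path}.
#' @export
write_config_snapshot <- function(config, path) {
  config$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  config$package_version <-
    as.character(utils::packageVersion("cghintegrity"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration snapshot
#'
#' @param path YAML path written by [write_config_snapshot()].
#' @return Named list.
#' @export
read_config_snapshot <- function(path) {
  yaml::read_yaml(path)
}
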
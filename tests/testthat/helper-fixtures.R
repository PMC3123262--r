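# shared builders for the test suite; everything is generated in code

toy_build <- function(n_chrom = 1, size = 1e6) {
  genome_build("toy", paste0("chr", seq_len(n_chrom)),
               rep(size, n_chrom))
}

toy_map <- function(build = toy_build(), spacing = 1200, seed = 1) {
  make_probe_map(build, mean_spacing = spacing, seed = seed)
}

# a track with given per-probe values and no simulation noise
track_from_values <- function(values, map = NULL, role = "self",
                              hyb_id = "t") {
  if (is.null(map)) {
    map <- toy_map(toy_build(size = length(values) * 1200 + 1200))
    map <- map[seq_along(values), ]
    class(map) <- c("probe_map", "data.frame")
  }
  structure(list(map = map, value = values, hyb_id = hyb_id, role = role,
                 truth = NULL, probe_gc = NULL,
                 meta = list(seed = NA, noise_sd = NA, steps = character())),
            class = "ratio_track")
}

# brute-force interval union oracle (position-marking), small coords only
brute_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    hi <- max(d$end)
    cov <- logical(hi)
    for (i in seq_len(nrow(d))) {
      cov[(d$start[i] + 1):d$end[i]] <- TRUE
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = starts[keep] - 1, end = ends[keep],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# random small interval set for property checks
random_intervals <- function(n, n_chrom = 2, max_coord = 200) {
  start <- sample.int(max_coord - 2, n, replace = TRUE)
  width <- sample.int(20, n, replace = TRUE)
  gintervals(paste0("c", sample.int(n_chrom, n, replace = TRUE)),
             start, pmin(start + width, max_coord))
}

# hand-built chain text; sizes has n entries, dt/dq have n - 1
simple_chain_text <- function(score = 100, s_chrom = "chrA", s_size = 1e6,
                              s_start = 0, t_chrom = "chrB", t_size = 1e6,
                              t_strand = "+", t_start = 0,
                              sizes = 1e5, dt = numeric(0),
                              dq = numeric(0)) {
  n <- length(sizes)
  stopifnot(length(dt) == n - 1 || n == 1, length(dq) == length(dt))
  s_end <- s_start + sum(sizes) + sum(dt)
  t_end <- t_start + sum(sizes) + sum(dq)
  hdr <- sprintf("chain %d %s %d + %d %d %s %d %s %d %d 1",
                 score, s_chrom, s_size, s_start, s_end,
                 t_chrom, t_size, t_strand, t_start, t_end)
  body <- character(n)
  for (i in seq_len(n)) {
    body[i] <- if (i < n) {
      sprintf("%d %d %d", sizes[i], dt[i], dq[i])
    } else {
      sprintf("%d", sizes[i])
    }
  }
  c(hdr, body, "")
}
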
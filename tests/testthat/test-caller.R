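test_that("criterion and resolution arithmetic", {
  expect_error(cgh_criterion(0, 5), "min_abs_shift")
  expect_error(cgh_criterion(0.5, 1), "min_probes")
  expect_equal(resolution(cgh_criterion(0.5, 5), 1200), 4800)
  expect_equal(resolution(cgh_criterion(0.5, 2), 1000), 1000)
  expect_equal(resolution(cgh_criterion(0.5, 5), 1000), 4000)
})

test_that("noise-free segmentation is exact", {
  # constant track: a single segment, no events
  f <- cgh_call(track_from_values(rep(0.3, 40)))
  expect_equal(nrow(f$segments), 1)
  expect_equal(nrow(f$events), 0)
  # one 10-probe +0.8 block: exactly 3 segments with exact boundaries
  v <- rep(0, 60); v[21:30] <- 0.8
  f2 <- cgh_call(track_from_values(v))
  expect_equal(nrow(f2$segments), 3)
  expect_equal(f2$segments$istart, c(1, 21, 31))
  expect_equal(f2$segments$mean, c(0, 0.8, 0))
  expect_equal(nrow(f2$events), 1)
  expect_equal(f2$events$kind, "gain")
  expect_equal(c(f2$events$istart, f2$events$iend), c(21, 30))
})

test_that("calling enforces both criterion thresholds", {
  # all-zero track: nothing
  expect_equal(nrow(cgh_call(track_from_values(rep(0, 30)))$events), 0)
  # 4-probe block of +1.0 fails min_probes = 5
  v <- rep(0, 40); v[11:14] <- 1.0
  expect_equal(nrow(cgh_call(track_from_values(v),
                             cgh_criterion(0.5, 5))$events), 0)
  # but passes min_probes = 3
  ev <- cgh_call(track_from_values(v), cgh_criterion(0.5, 3))$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_probes, 4)
  # sub-threshold shift is ignored
  v2 <- rep(0, 40); v2[11:20] <- 0.4
  expect_equal(nrow(cgh_call(track_from_values(v2),
                             cgh_criterion(0.5, 5))$events), 0)
})

test_that("zero-noise planted CNVs are recovered exactly, and only them", {
  pm <- toy_map(toy_build(size = 2e6), spacing = 1200, seed = 3)
  sets <- list(
    list(i = 101:112, shift = 0.8),    # callable gain
    list(i = 301:310, shift = -0.6),   # callable loss
    list(i = 501:503, shift = 1.2),    # too few probes
    list(i = 701:720, shift = 0.3))    # too small a shift
  tc <- do.call(rbind, lapply(sets, function(s) {
    truth_cnvs("chr1", pm$start[s$i[1]], pm$end[s$i[length(s$i)]], s$shift)
  }))
  class(tc) <- class(truth_cnvs("chr1", 1, 2, 1))
  tr <- simulate_hybridization(pm, truth = tc, role = "low",
                               noise_sd = 0, seed = 1)
  ev <- cgh_call(tr, cgh_criterion(0.5, 5))$events
  expect_equal(nrow(ev), 2)
  expect_equal(ev$istart, c(101, 301))
  expect_equal(ev$iend, c(112, 310))
  expect_equal(ev$kind, c("gain", "loss"))
  expect_equal(ev$log_r, c(0.8, -0.6))
  expect_equal(ev$start, pm$start[c(101, 301)])
  expect_equal(ev$end, pm$end[c(112, 310)])
})

test_that("noisy boundaries are recovered within two probes", {
  ok <- 0
  for (s in 1:100) {
    v <- rnorm(2000, 0, 0.2)
    v[1001:1020] <- v[1001:1020] + 0.8
    ev <- cgh_call(track_from_values(v), cgh_criterion(0.5, 5))$events
    hit <- which(ev$kind == "gain" & abs(ev$istart - 1001) <= 2 &
                   abs(ev$iend - 1020) <= 2)
    if (length(hit) == 1 && nrow(ev) == 1) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("event counts are monotone in both criterion parameters", {
  set.seed(42)
  pm <- toy_map(toy_build(size = 2e6), spacing = 1200, seed = 4)
  starts <- seq(51, 1500, by = 110)
  tc <- do.call(rbind, lapply(seq_along(starts), function(k) {
    len <- 2 + (k %% 8)
    i <- starts[k]:(starts[k] + len)
    truth_cnvs("chr1", pm$start[i[1]], pm$end[i[length(i)]],
               sample(c(-1, 1), 1) * runif(1, 0.25, 1))
  }))
  class(tc) <- class(truth_cnvs("chr1", 1, 2, 1))
  for (s in 1:3) {
    tr <- simulate_hybridization(pm, truth = tc, role = "high",
                                 noise_sd = 0.2, seed = 600 + s)
    seg <- segment_track(tr)
    shifts <- seq(0.3, 0.7, 0.1)
    probes <- 3:7
    counts <- outer(shifts, probes, Vectorize(function(a, p) {
      nrow(call_events(seg, tr, cgh_criterion(a, p)))
    }))
    expect_true(all(counts[-1, ] <= counts[-length(shifts), ]))
    expect_true(all(counts[, -1] <= counts[, -length(probes)]))
  }
})

test_that("events never overlap within one hybridization", {
  g <- make_genome(c(chr1 = 2e6, chr2 = 2e6), seed = 31)
  pm <- make_probe_map(g, 1200, seed = 31)
  tr <- simulate_hybridization(pm, g, role = "self", noise_sd = 0.2,
                               wave_coefficient = 3, seed = 31)
  ev <- cgh_call(median_center(tr))$events
  expect_gt(nrow(ev), 0)  # the strong wave does create artifact calls
  if (nrow(ev) > 1) {
    o <- order(ev$chrom, ev$start)
    e <- ev[o, ]
    same <- e$chrom[-1] == e$chrom[-nrow(e)]
    expect_true(all(e$start[-1][same] >= e$end[-nrow(e)][same]))
  }
  expect_true(all(ev$kind == ifelse(ev$log_r > 0, "gain", "loss")))
})

test_that("masked probes split runs and shrink observed counts", {
  v <- rep(0, 60); v[21:30] <- 0.8
  v[25] <- NA  # breaks the 10-probe run into 4 + 5 observed probes
  tr <- track_from_values(v)
  seg <- segment_track(tr)
  # the masked probe forms its own NA segment
  expect_true(any(is.na(seg$mean) & seg$istart == 25))
  ev5 <- call_events(seg, tr, cgh_criterion(0.5, 5))
  expect_equal(nrow(ev5), 1)  # only the 5-probe half qualifies
  expect_equal(c(ev5$istart, ev5$iend), c(26, 30))
  ev4 <- call_events(seg, tr, cgh_criterion(0.5, 4))
  expect_equal(nrow(ev4), 2)  # runs are not fused across the mask
})

test_that("cgh_fit behaves like a fitted model object", {
  v <- rep(0, 50); v[11:20] <- 0.8
  v <- v + rnorm(50, 0, 0.01)
  fit <- cgh_call(track_from_values(v))
  expect_s3_class(fit, "cgh_fit")
  expect_equal(length(coef(fit)), nrow(fit$segments))
  expect_equal(fitted(fit) + residuals(fit), fit$track$value)
  expect_equal(as.vector(tapply(fitted(fit), rep(seq_len(nrow(fit$segments)),
               fit$segments$n_probes), unique)), fit$segments$mean)
  expect_output(print(fit), "CGH fit")
  expect_output(summary(fit), "events")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("sign convention matches the published event table", {
  t2 <- load_table2_fixture()
  expect_true(all(t2$events$kind ==
                    ifelse(t2$events$log_r > 0, "gain", "loss")))
  expect_true(all(abs(t2$events$log_r) >= 0.5))  # printed calls obey 0.5/5
})
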
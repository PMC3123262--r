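test_that("genome generation is deterministic and hits its GC target", {
  g1 <- make_genome(c(chr1 = 1e6, chr2 = 1e6), gc_target = 0.417, seed = 1)
  g2 <- make_genome(c(chr1 = 1e6, chr2 = 1e6), gc_target = 0.417, seed = 1)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_lt(abs(g1$gc_realized - 0.417), 0.02)
  g3 <- make_genome(c(chr1 = 1e6, chr2 = 1e6), gc_target = 0.417, seed = 2)
  expect_false(identical(as.character(g1$seq), as.character(g3$seq)))
  # a GC-rich scenario is honoured too
  gh <- make_genome(c(chr1 = 1e6), gc_target = 0.535, seed = 3)
  expect_lt(abs(gh$gc_realized - 0.535), 0.02)
  expect_error(make_genome(c(chr1 = 0)), "> 0")
  expect_error(make_genome(c(chr1 = 1e5), gc_target = 1.2), "gc_target")
})

test_that("probe maps are sorted, non-overlapping, at the requested pitch", {
  pm <- toy_map(toy_build(size = 1e6), spacing = 1200, seed = 1)
  expect_true(abs(nrow(pm) - 1e6 / 1200) / (1e6 / 1200) < 0.05)
  expect_true(all(diff(pm$start) > 0))
  expect_true(all(pm$start[-1] >= pm$end[-nrow(pm)]))  # non-overlapping
  expect_lt(abs(attr(pm, "mean_spacing") - 1200) / 1200, 0.05)
  pm2 <- toy_map(toy_build(size = 1e6), spacing = 1200, seed = 1)
  expect_identical(pm, pm2)
  expect_error(make_probe_map(toy_build(), mean_spacing = 30,
                              probe_length = 50), "probe_length")
  expect_error(make_probe_map(genome_build("t", "c", 40), 1200), "shorter")
})

test_that("hybridization tracks follow the additive generative model", {
  pm <- toy_map(toy_build(size = 3e5), spacing = 1200, seed = 1)
  # pure null with no noise: all zeros
  t0 <- simulate_hybridization(pm, role = "self", noise_sd = 0, seed = 1)
  expect_equal(t0$value, rep(0, nrow(pm)))
  # dye bias alone: constant offset
  tb <- simulate_hybridization(pm, role = "self", noise_sd = 0,
                               dye_bias = 0.1, seed = 1)
  expect_equal(tb$value, rep(0.1, nrow(pm)))
  # one planted CNV covers exactly its probes
  tc <- truth_cnvs("chr1", pm$start[21], pm$end[30], 0.8)
  th <- simulate_hybridization(pm, truth = tc, role = "high",
                               noise_sd = 0, seed = 1)
  expect_equal(th$value[21:30], rep(0.8, 10))
  expect_equal(th$value[-(21:30)], rep(0, nrow(pm) - 10))
  # determinism of the noise stream
  n1 <- simulate_hybridization(pm, role = "self", seed = 5)
  n2 <- simulate_hybridization(pm, role = "self", seed = 5)
  expect_identical(n1$value, n2$value)
  # guardrails
  expect_error(simulate_hybridization(pm, truth = tc, role = "self"),
               "no true CNVs")
  expect_error(simulate_hybridization(pm, wave_coefficient = 1),
               "genome is required")
  bad <- truth_cnvs(c("chr1", "chr1"), c(0, 1000), c(2000, 3000),
                    c(0.8, 0.8))
  expect_error(simulate_hybridization(pm, truth = bad, role = "high"),
               "overlapping")
})

test_that("the GC wave couples track values to local GC, by design", {
  g <- make_genome(c(chr1 = 1e6, chr2 = 1e6), seed = 4)
  pm <- make_probe_map(g, 1200, seed = 4)
  gc <- probe_gc(g, pm)
  cors <- sapply(c(0.5, 2), function(w) {
    mean(sapply(1:3, function(s) {
      tr <- simulate_hybridization(pm, g, role = "self", noise_sd = 0.2,
                                   wave_coefficient = w, seed = s)
      cor(tr$value, gc)
    }))
  })
  expect_true(all(cors > 0))
  expect_lt(cors[1], cors[2])
})

test_that("quiet self tracks contain no callable 5-probe excursion", {
  pm <- toy_map(toy_build(size = 2e6), spacing = 1200, seed = 2)
  bad_seeds <- 0
  for (s in 1:20) {
    tr <- simulate_hybridization(pm, role = "self", noise_sd = 0.15,
                                 seed = 1000 + s)
    m5 <- stats::filter(tr$value, rep(1 / 5, 5), sides = 1)
    if (any(abs(m5) >= 0.5, na.rm = TRUE)) bad_seeds <- bad_seeds + 1
  }
  expect_lte(bad_seeds, 1)  # >= 95% of seeds clean
})

test_that("truth CNVs round-trip through the BED writer", {
  tc <- truth_cnvs(c("chr1", "chr2"), c(1000, 5000), c(3000, 20000),
                   c(0.8, -0.7))
  f <- tempfile(fileext = ".bed")
  x <- tc
  x$name <- tc$kind
  x$score <- tc$log2_shift
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(y$chrom, tc$chrom)
  expect_equal(y$start, tc$start)
  expect_equal(y$end, tc$end)
  expect_equal(y$name, tc$kind)
  expect_equal(y$score, tc$log2_shift)
})

test_that("FASTA export matches the in-memory genome", {
  g <- make_genome(c(chrA = 5e4), seed = 9)
  f <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_identical(as.character(back), as.character(g$seq))
})
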
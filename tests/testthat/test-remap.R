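test_that("chain parsing handles identity, gaps, and empty files", {
  ident <- read_chain(text = simple_chain_text(sizes = 1e6))
  expect_length(ident, 1)
  expect_equal(nrow(ident[[1]]$blocks), 1)
  expect_equal(ident[[1]]$source_end, 1e6)
  gap <- read_chain(text = simple_chain_text(sizes = c(5e4, 5e4),
                                             dt = 100, dq = 0))
  expect_equal(nrow(gap[[1]]$blocks), 2)
  expect_equal(gap[[1]]$blocks$source_start, c(0, 50100))
  expect_equal(gap[[1]]$blocks$target_start, c(0, 50000))
  f <- tempfile(); file.create(f)
  expect_length(read_chain(f), 0)
})

test_that("malformed chains are rejected with line numbers", {
  expect_error(read_chain(text = c("chainz 1 2 3", "10")), "line 1")
  expect_error(read_chain(text = c(
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 100 1", "50 x 0", "50")),
    "line 2")
  expect_error(read_chain(text =
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 100 1"),
    "terminating")
  # header span inconsistent with blocks
  expect_error(read_chain(text = c(
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 100 1", "90")),
    "inconsistent")
})

test_that("remapping through simple chains shifts coordinates exactly", {
  ident <- read_chain(text = simple_chain_text(sizes = 1e6))
  iv <- gintervals("chrA", 1000, 2000)
  r <- remap_interval(ident, iv)
  expect_equal(r$status, "mapped")
  expect_equal(as.data.frame(r$interval),
               as.data.frame(gintervals("chrB", 1000, 2000)))
  # +1000 shift
  shift <- read_chain(text = simple_chain_text(s_start = 0,
                                               t_start = 1000,
                                               sizes = 5e5))
  r2 <- remap_interval(shift, iv)
  expect_equal(r2$interval$start, 2000)
  expect_equal(r2$interval$end, 3000)
  expect_equal(r2$matched_fraction, 1)
})

test_that("failure reasons distinguish unmapped, deleted and split", {
  chains <- read_chain(text = simple_chain_text(sizes = c(1e4, 1e4),
                                                dt = 5e4, dq = 5e4))
  # falls wholly in the source gap
  del <- remap_interval(chains, gintervals("chrA", 20000, 30000))
  expect_equal(del$status, "deleted_in_target")
  expect_equal(del$matched_fraction, 0.0)
  # different chromosome: no chain at all
  un <- remap_interval(chains, gintervals("chrZ", 0, 100))
  expect_equal(un$status, "unmapped")
  # two chains each covering half
  two <- read_chain(text = c(
    simple_chain_text(score = 50, s_start = 0, t_start = 0, sizes = 1000),
    simple_chain_text(score = 60, s_start = 1000, t_start = 5000,
                      sizes = 1000)))
  sp <- remap_interval(two, gintervals("chrA", 500, 1500))
  expect_equal(sp$status, "split")
  expect_equal(sp$matched_fraction, 0.5)
})

test_that("partial overlap below min_match fails, above succeeds", {
  chains <- read_chain(text = simple_chain_text(sizes = c(900, 1000),
                                                dt = 100, dq = 100))
  # interval 0..1000: 900 aligned of 1000 = 0.9
  iv <- gintervals("chrA", 0, 1000)
  expect_equal(remap_interval(chains, iv, min_match = 0.95)$status,
               "deleted_in_target")
  ok <- remap_interval(chains, iv, min_match = 0.85)
  expect_equal(ok$status, "mapped")
  expect_equal(ok$matched_fraction, 0.9)
  # span never exceeds source span plus intersected target gaps
  expect_lte(span(ok$interval), span(iv) + 100)
})

test_that("negative-strand chains flip coordinates correctly", {
  neg <- read_chain(text = simple_chain_text(t_strand = "-", t_size = 1e6,
                                             sizes = 1e5))
  r <- remap_interval(neg, gintervals("chrA", 1000, 2000))
  expect_equal(r$status, "mapped")
  # strand-local [1000, 2000) -> plus strand [1e6-2000, 1e6-1000)
  expect_equal(r$interval$start, 998000)
  expect_equal(r$interval$end, 999000)
  expect_equal(span(r$interval), 1000)
})

test_that("inverse chains round-trip intervals exactly", {
  chains <- list(
    read_chain(text = simple_chain_text(s_start = 100, t_start = 5100,
                                        sizes = c(3e4, 2e4, 1e4),
                                        dt = c(500, 0),
                                        dq = c(0, 800)))[[1]],
    read_chain(text = simple_chain_text(t_strand = "-", t_size = 2e6,
                                        s_start = 0, t_start = 1e5,
                                        sizes = c(4e4, 4e4),
                                        dt = c(100), dq = c(200)))[[1]])
  set.seed(5)
  for (ch in chains) {
    inv <- invert_chain(ch)
    for (rep in 1:25) {
      s0 <- ch$source_start + sample.int(2e4, 1)
      iv <- gintervals("chrA", s0, s0 + sample.int(5000, 1))
      fwd <- remap_interval(list(ch), iv, min_match = 1)
      if (fwd$status != "mapped") next
      back <- remap_interval(list(inv), fwd$interval, min_match = 1)
      expect_equal(back$status, "mapped")
      expect_equal(as.data.frame(back$interval)[1:3],
                   as.data.frame(iv)[1:3])
    }
  }
})

test_that("batch remapping writes mapped and unmapped sets", {
  chains <- read_chain(text = simple_chain_text(sizes = c(1e4, 1e4),
                                                dt = 5e4, dq = 5e4))
  ivs <- gintervals("chrA", c(0, 20000, 60000), c(5000, 30000, 65000))
  res <- remap_intervals(chains, ivs)
  expect_equal(nrow(res$mapped), 2)
  expect_equal(res$mapped$name[1], "chrA:0-5000")
  expect_equal(nrow(res$unmapped), 1)
  expect_equal(res$unmapped$reason, "deleted_in_target")
})
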
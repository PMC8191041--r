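test_that("event segmentation recovers plateau boundaries", {
  # constant signal: a single event
  ev <- segment_events(rep(100, 100))
  expect_identical(nrow(ev), 1L)
  expect_identical(c(ev$start, ev$end), c(0L, 100L))
  # two plateaus differing by 10 pA: boundary within 2 samples of the step
  sig <- c(rep(90, 50), rep(100, 50))
  ev2 <- segment_events(sig)
  expect_identical(nrow(ev2), 2L)
  expect_lte(abs(ev2$start[2] - 50L), 2L)
  # events partition the signal
  expect_identical(ev2$start[2], ev2$end[1])
  expect_error(segment_events(numeric(1)), "at least 2 samples")
})

test_that("noise-free plateaus above threshold each become one event", {
  lev <- c(80, 100, 90, 70, 95)
  sig <- rep(lev, each = 10)
  ev <- segment_events(sig)
  expect_identical(nrow(ev), length(lev))
  expect_equal(ev$mean, lev)
  expect_identical(ev$start, seq(0L, 40L, by = 10L))
})

test_that("noise-free one-event-per-kmer reads align as the identity with zero skips", {
  pm <- pm_fixture
  ref <- random_contig(120, seed = 31)
  ev <- perfect_events(ref, pm)
  al <- align_events(ev, ref, pm)
  expect_identical(al$pairs$kmer, al$pairs$event)
  expect_length(al$skipped, 0)
})

test_that("a duplicated event is absorbed by an insert state", {
  pm <- pm_fixture
  ref <- random_contig(60, seed = 32)
  ev <- perfect_events(ref, pm)
  dup <- rbind(ev[1:10, ], ev[10, ], ev[11:nrow(ev), ])
  al <- align_events(dup, ref, pm)
  expect_identical(sum(al$pairs$kmer == 10), 2L)
  expect_identical(al$pairs$kmer, c(1:10, 10:(nrow(ev))))
  expect_length(al$skipped, 0)
})

test_that("banded Viterbi equals the exhaustive reference on random short reads", {
  pm <- pm_fixture
  contig <- random_contig(4000, seed = 33)
  for (i in 1:12) {
    len <- 100 + 30 * i
    start <- 50 * i
    rd <- simulate_read(contig, c(start, start + len),
                        sim_config(ifelse(i %% 2, 0, 0.5), seed = 400 + i), pm)
    ev <- segment_events(rd$signal)
    al <- align_events(ev, rd$sequence, pm)
    em <- reference_emissions(rd$sequence, pm)
    ref <- viterbi_reference(ev$mean, em$cands, em$sd)
    expect_equal(al$score, ref$score, tolerance = 1e-8)
    expect_identical(al$pairs$kmer, ref$assignment)
  }
})

test_that("alignment pairs are monotone on random noisy reads", {
  pm <- pm_fixture
  contig <- random_contig(8000, seed = 34)
  for (i in 1:4) {
    rd <- simulate_read(contig, c(100 * i, 100 * i + 1500),
                        sim_config(0.4, seed = 500 + i), pm)
    ev <- segment_events(rd$signal)
    al <- align_events(ev, rd$sequence, pm)
    expect_true(all(diff(al$pairs$event) >= 0))
    expect_true(all(diff(al$pairs$kmer) >= 0))
    expect_false(anyDuplicated(al$pairs$event) > 0)
    expect_true(all(al$pairs$kmer >= 1 & al$pairs$kmer <= al$n_kmers))
  }
})

test_that("input tensors have fixed shape, exclude overhanging windows and flag skips", {
  pm <- pm_fixture
  ref <- random_contig(200, seed = 35)
  ev <- perfect_events(ref, pm)
  al <- align_events(ev, ref, pm)
  t_pos <- which(strsplit(ref, "")[[1]] == "T") - 1L
  tb <- build_input_tensors(al, ev, ref, t_pos, pm)
  expect_identical(dim(tb$x)[2:3], c(15L, forktrace:::N_TENSOR_FEATURES))
  # edge thymidines (window overhang) are excluded and counted
  half <- 7L
  in_span <- t_pos + 1L - half >= 1L & t_pos + 1L + half <= al$n_kmers
  expect_identical(length(tb$positions), sum(in_span))
  expect_identical(tb$n_excluded, sum(!in_span))
  # a read with no thymidines yields an empty tensor list
  ref2 <- paste(rep("ACG", 30), collapse = "")
  ev2 <- perfect_events(ref2, pm)
  al2 <- align_events(ev2, ref2, pm)
  tb2 <- build_input_tensors(al2, ev2, ref2, integer(0), pm)
  expect_identical(dim(tb2$x)[1], 0L)
})

test_that("event-alignment debug dumps are deterministic TSV", {
  pm <- pm_fixture
  ref <- random_contig(80, seed = 37)
  ev <- perfect_events(ref, pm)
  al <- align_events(ev, ref, pm)
  f1 <- tempfile(); f2 <- tempfile()
  write_event_alignment(al, ev, f1)
  write_event_alignment(al, ev, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_identical(nrow(tab), nrow(al$pairs))
  expect_identical(tab$kmer, al$pairs$kmer)
})

test_that("the level-difference feature is zero without analogue and non-zero with it", {
  pm <- pm_fixture
  ref <- random_contig(150, seed = 36)
  t_pos <- which(strsplit(ref, "")[[1]] == "T") - 1L
  # noise-free events built from analogue-substituted levels for half the Ts
  mask <- seq_along(t_pos) %% 2 == 1
  ev <- perfect_events(ref, pm, brdu_mask = mask)
  al <- align_events(ev, ref, pm)
  tb <- build_input_tensors(al, ev, ref, t_pos, pm)
  kept_mask <- mask[match(tb$positions, t_pos)]
  diff_feat <- tb$x[, , 5]
  masked_pos <- t_pos[mask]
  for (i in seq_along(tb$positions)) {
    c0 <- tb$positions[i]
    if (kept_mask[i]) {
      # an analogue at the centre perturbs at least one window row
      expect_gt(max(abs(diff_feat[i, ])), 0)
    } else if (!any(masked_pos >= c0 - 7L & masked_pos <= c0 + 12L)) {
      # no analogue anywhere near the window: observed levels match the
      # canonical expectation exactly
      expect_equal(max(abs(diff_feat[i, ])), 0)
    }
  }
  # tensor shape identical across reads of one configuration
  tb2 <- build_input_tensors(al, ev, ref, t_pos[1:3], pm)
  expect_identical(dim(tb$x)[2:3], dim(tb2$x)[2:3])
})
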
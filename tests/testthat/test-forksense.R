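fake_track <- function(positions, p_left, p_right, read_id = "r1",
                       contig = "chr", ref_start = NULL, ref_end = NULL) {
  structure(list(read_id = read_id, contig = contig, strand = "+",
                 ref_start = ref_start %||% min(positions),
                 ref_end = ref_end %||% (max(positions) + 1L), mapq = 60L,
                 positions = as.integer(positions),
                 p_left = p_left, p_right = p_right),
            class = "fork_track")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fork-sense builds are deterministic and fully convolutional", {
  m1 <- build_forksense_model(seed = 9)
  m2 <- build_forksense_model(seed = 9)
  expect_identical(m1$par, m2$par)
  expect_false(identical(m1$par, build_forksense_model(seed = 10)$par))
  expect_error(build_forksense_model(kernel = 8), "odd")
  # any track length produces one output pair per position
  for (L in c(70L, 333L, 2000L)) {
    X <- cbind(runif(L), runif(L))
    out <- forktrace:::forksense_forward(m1, X)$P
    expect_identical(dim(out), c(L, 2L))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("fork segments are maximal runs closed over sub-tolerance gaps", {
  pos <- seq(0L, 30000L, by = 1L)
  p_r <- as.numeric(pos >= 10000 & pos < 20000)
  tr <- fake_track(pos, rep(0, length(pos)), p_r)
  segs <- call_fork_segments(tr, threshold = 0.5)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$kind, "fork_right")
  expect_identical(c(segs$start, segs$end), c(10000L, 20000L))
  # all-zero track: nothing
  tr0 <- fake_track(pos, rep(0, length(pos)), rep(0, length(pos)))
  expect_identical(nrow(call_fork_segments(tr0)), 0L)
  expect_error(call_fork_segments(tr, threshold = 0), "threshold")
})

test_that("run merging matches a brute-force oracle around the gap tolerance", {
  gap_tol <- 500L
  pos <- c(seq(0, 2000, by = 4), seq(2000 + gap_tol - 1, 4500, by = 4),
           seq(4500 + gap_tol + 50, 7000, by = 4))
  p <- rep(1, length(pos))
  tr <- fake_track(pos, p, rep(0, length(pos)))
  segs <- call_fork_segments(tr, threshold = 0.5, min_length_bp = 100,
                             gap_tolerance = gap_tol)
  oracle <- runs_bruteforce(pos, p, 0.5, gap_tol)
  expect_identical(nrow(segs), nrow(oracle))
  expect_equal(segs$start, oracle[, 1])
  expect_equal(segs$end, oracle[, 2])
  # the sub-tolerance gap merged the first two runs, the larger one did not
  expect_identical(nrow(segs), 2L)
  # randomised agreement with the oracle
  for (i in 1:5) {
    set.seed(600 + i)
    rpos <- sort(sample(0:5000, 400))
    rp <- runif(400)
    tr2 <- fake_track(rpos, rp, rep(0, 400))
    s2 <- call_fork_segments(tr2, 0.5, min_length_bp = 1, gap_tolerance = 200)
    o2 <- runs_bruteforce(rpos, rp, 0.5, 200)
    keep <- o2[, 2] - o2[, 1] >= 1
    expect_equal(unname(cbind(s2$start, s2$end)), unname(o2[keep, , drop = FALSE]))
  }
})

test_that("diverging forks call an origin and converging forks a termination", {
  seg <- function(kind, s, e) forktrace:::new_feature_call(kind, "chr", s, e, "r1", 1)
  div <- rbind(seg("fork_left", 0, 5000), seg("fork_right", 7000, 12000))
  out <- match_forks(div)
  expect_identical(out$kind, "origin")
  expect_identical(c(out$start, out$end), c(5000L, 7000L))
  conv <- rbind(seg("fork_right", 0, 5000), seg("fork_left", 7000, 12000))
  out2 <- match_forks(conv)
  expect_identical(out2$kind, "termination")
  expect_identical(c(out2$start, out2$end), c(5000L, 7000L))
  # a single fork yields nothing
  expect_identical(nrow(match_forks(seg("fork_right", 0, 5000))), 0L)
  # overlapping diverging segments: minimal interval at the overlap midpoint
  ovl <- rbind(seg("fork_left", 0, 6000), seg("fork_right", 5000, 12000))
  out3 <- match_forks(ovl)
  expect_identical(out3$kind, "origin")
  expect_identical(out3$end - out3$start, 2L)
  expect_true(out3$start >= 5000 - 1 && out3$end <= 6000 + 1)
})

test_that("the read filter applies inclusive length and MAPQ thresholds", {
  mk <- function(len, mapq) {
    forktrace:::new_detect_record("r", "chr", 0L, len,  "+",
                                  data.frame(position = integer(0),
                                             probability = numeric(0),
                                             sixmer = character(0)),
                                  mapq = mapq)
  }
  recs <- list(mk(19999L, 60L), mk(20000L, 20L), mk(25000L, 19L), mk(30000L, 60L))
  out <- filter_reads_for_calling(recs)
  lens <- vapply(out, function(r) r$ref_end - r$ref_start, integer(1))
  expect_identical(lens, c(20000L, 30000L))
  expect_identical(filter_reads_for_calling(list()), list())
})

test_that("fork-sense training validates labels", {
  m <- build_forksense_model(seed = 4)
  rows <- data.frame(position = seq(0L, 3980L, by = 4L),
                     probability = runif(996),
                     sixmer = rep("TAAAAA", 996), stringsAsFactors = FALSE)
  recs <- lapply(1:4, function(i) {
    forktrace:::new_detect_record(paste0("r", i), "chr", 0L, 4000L, "+", rows)
  })
  labs_none <- lapply(1:4, function(i) rep("none", 996))
  expect_error(train_forksense(m, recs, labs_none), "no positive fork labels")
  expect_error(train_forksense(m, recs, labs_none[1:2]), "differ in length")
})
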
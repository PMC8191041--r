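test_that("a single mid-molecule origin yields left/right flanks and a centred origin interval", {
  pm <- pm_fixture
  contig <- random_contig(30000, seed = 12)
  cfg <- sim_config(protocol = "g1_release", seed = 3)
  rd <- simulate_fork_footprints(contig, list(c(2000, 22000)), 12000, cfg, pm)[[1]]
  expect_identical(nrow(rd$truth_origins), 1L)
  expect_equal(as.numeric(rd$truth_origins[1, ]), c(11500, 12500))
  expect_equal(as.numeric(rd$truth_forks$left[1, ]), c(2000, 12000))
  expect_equal(as.numeric(rd$truth_forks$right[1, ]), c(12001, 22000))
  # fork-direction truth labels sit on the correct side of the origin
  lab <- truth_fork_labels(rd, rd$t_positions)
  expect_true(all(rd$t_positions[lab == "left"] < 12000))
  expect_true(all(rd$t_positions[lab == "right"] > 12000))
})

test_that("converging forks from two origins meet at the midpoint (pulse-chase)", {
  pm <- pm_fixture
  contig <- random_contig(90000, seed = 13)
  cfg <- sim_config(protocol = "pulse_chase", seed = 8)
  o1 <- 20000; o2 <- 60000                   # 40 kb apart, equal fork speeds
  rd <- simulate_fork_footprints(contig, list(c(0, 85000)), c(o1, o2), cfg, pm)[[1]]
  expect_identical(nrow(rd$truth_terms), 1L)
  mid <- floor((o1 + o2) / 2)
  expect_equal(as.numeric(rd$truth_terms[1, ]), c(mid - 500, mid + 500))
  expect_identical(nrow(rd$truth_origins), 2L)
  # pulse truth: fork labels cover the observable footprint (pulse plus the
  # detectable part of the chase tail)
  reach <- round(cfg$fork_speed * cfg$pulse_duration +
                   cfg$chase_decay_length * log(10))
  expect_equal(as.numeric(rd$truth_forks$right[1, ]), c(o1 + 1, o1 + 1 + reach))
})

test_that("pulse-chase substitution probability is non-increasing along the fork direction", {
  cfg <- sim_config(protocol = "pulse_chase", seed = 1)
  d <- seq(0, 40000, by = 100)
  p <- forktrace:::fork_substitution_profile(d, cfg)
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(p[1], cfg$p_max)
  # g1 release: uptake ramp, then a gentle pool-depletion decline that
  # orients the footprint; the peak sits at the end of the ramp
  cfg2 <- sim_config(protocol = "g1_release", seed = 1)
  p2 <- forktrace:::fork_substitution_profile(d, cfg2)
  ramp_end <- which(d >= cfg2$rise_length)[1]
  expect_true(all(diff(p2[1:ramp_end]) > 0))
  expect_true(all(diff(p2[ramp_end:length(p2)]) < 0))
  expect_equal(which.max(p2), ramp_end)
  expect_lte(max(p2), cfg2$p_max)
})

test_that("origins outside every molecule are rejected", {
  pm <- pm_fixture
  contig <- random_contig(30000, seed = 14)
  cfg <- sim_config(protocol = "g1_release", seed = 2)
  expect_error(simulate_fork_footprints(contig, list(c(0, 10000)), 20000, cfg, pm),
               "outside every molecule")
})

test_that("origin-free molecules carry a single unidirectional fork and no origin truth", {
  pm <- pm_fixture
  contig <- random_contig(40000, seed = 15)
  cfg <- sim_config(protocol = "g1_release", seed = 21)
  rd <- simulate_fork_footprints(contig, list(c(0, 30000)), integer(0), cfg, pm)[[1]]
  expect_identical(nrow(rd$truth_origins), 0L)
  expect_identical(nrow(rd$truth_terms), 0L)
  n_dir <- nrow(rd$truth_forks$left) + nrow(rd$truth_forks$right)
  expect_identical(n_dir, 1L)
})
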
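test_that("uniform substitution hits its target rate across the study rates", {
  pm <- pm_fixture
  contig <- random_contig(450000, seed = 5)
  for (rate in c(0, 0.26, 0.38, 0.49, 0.69, 0.80)) {
    rd <- simulate_read(contig, c(0, 430000), sim_config(rate, seed = 100 + rate * 100),
                        pm, emit_signal = FALSE)
    n <- length(rd$truth_brdu)
    expect_gt(n, 1e5)
    frac <- mean(rd$truth_brdu)
    tol <- 3 * sqrt(max(rate * (1 - rate), 1e-12) / n)
    expect_lte(abs(frac - rate), max(tol, 1e-12))
  }
})

test_that("seeded simulation is bit-reproducible and seed-sensitive", {
  pm <- pm_fixture
  contig <- random_contig(5000, seed = 6)
  r1 <- simulate_read(contig, c(100, 2100), sim_config(0.5, seed = 77), pm)
  r2 <- simulate_read(contig, c(100, 2100), sim_config(0.5, seed = 77), pm)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$truth_brdu, r2$truth_brdu)
  r3 <- simulate_read(contig, c(100, 2100), sim_config(0.5, seed = 78), pm)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("noise-free signal reproduces expected levels exactly with geometric dwell", {
  pm <- pm_fixture
  contig <- random_contig(3000, seed = 7)
  cfg <- sim_config(0.3, seed = 9, noise_sd_scale = 0)
  rd <- simulate_read(contig, c(0, 1000), cfg, pm)
  lev <- expected_levels(rd$sequence, rd$truth_brdu, pm)
  expect_identical(length(rd$signal), sum(rd$truth_dwell))
  expect_true(all(rd$truth_dwell >= 1L))
  # per-position samples equal the expected level exactly
  expect_identical(rd$signal, rep(lev$mean, rd$truth_dwell))
})

test_that("window and rate validation work", {
  pm <- pm_fixture
  contig <- random_contig(100, seed = 8)
  expect_error(simulate_read(contig, c(10, 14), sim_config(0, seed = 1), pm),
               "shorter than 6")
  expect_error(sim_config(substitution_rate = 1.2), "substitution_rate")
  expect_error(sim_config(fork_speed = -1), "fork_speed")
  expect_error(sim_config(dwell_mean = 0.5), "dwell_mean")
  rd <- simulate_read(contig, c(0, 100), sim_config(0, seed = 1), pm)
  expect_false(any(rd$truth_brdu))
})

test_that("primer-extension reads carry BrdU at construct positions 30 and 36 only", {
  pm <- pm_fixture
  reads <- simulate_primer_extension(5, sim_config(seed = 4), pm)
  expect_length(reads, 5)
  for (rd in reads) {
    expect_identical(sum(rd$truth_brdu), 2L)
    expect_identical(rd$t_positions[rd$truth_brdu], c(29L, 35L))
  }
  expect_error(simulate_primer_extension(0, sim_config(seed = 4), pm), "n_reads")
})
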
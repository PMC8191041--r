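test_that("bundled pore model is complete, positive-spread and reproducible", {
  pm <- pm_fixture
  idx <- forktrace:::pore_model_index()
  expect_true(all(is.finite(pm$mean[idx$canonical])))
  expect_true(all(pm$sd[idx$canonical] > 0))
  expect_true(all(is.finite(pm$mean[idx$variant])))
  # same table on every build
  pm2 <- default_pore_model()
  expect_identical(pm$mean, pm2$mean)
  expect_identical(pm$sd, pm2$sd)
  # a known canonical entry exists and is sane
  i <- forktrace:::kmer_index_one("AAAAAA")
  expect_true(is.finite(pm$mean[i]) && pm$sd[i] > 0)
  expect_true(pm$mean[i] >= 60 && pm$mean[i] <= 120)
})

test_that("every thymidine-containing 6-mer has a detectably shifted analogue variant", {
  pm <- pm_fixture
  idx <- forktrace:::pore_model_index()
  shift <- abs(pm$mean[idx$variant] - pm$mean[idx$counterpart_of_variant])
  expect_true(all(shift >= 1.5 - 1e-9))
  # every T-containing canonical k-mer is some variant's counterpart
  t_kmers <- idx$canonical[grepl("T", vapply(idx$canonical, forktrace:::decode_kmer,
                                             character(1)), fixed = TRUE)]
  expect_setequal(unique(idx$counterpart_of_variant), t_kmers)
})

test_that("pore model tables round-trip and validate on load", {
  pm <- pm_fixture
  path <- tempfile(fileext = ".tsv")
  write_pore_model(pm, path)
  pm2 <- load_pore_model(path)
  expect_equal(pm2$mean, pm$mean, tolerance = 1e-4)
  expect_equal(pm2$sd, pm$sd, tolerance = 1e-4)

  tab <- read.delim(path, stringsAsFactors = FALSE)
  # missing canonical k-mer is named in the error
  bad <- tab[tab$kmer != "TTTTTT", ]
  p1 <- tempfile(fileext = ".tsv")
  write.table(bad, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_pore_model(p1), "TTTTTT")
  # non-positive spread is rejected
  bad2 <- tab
  bad2$sd[5] <- 0
  p2 <- tempfile(fileext = ".tsv")
  write.table(bad2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_pore_model(p2), "non-positive sd")
})

test_that("expected_levels substitutes analogue levels only in windows covering a marked T", {
  pm <- pm_fixture
  seqc <- "ACGACTGCACG"                  # single T at position 6 (1-based)
  lev0 <- expected_levels(seqc, FALSE, pm)
  expect_equal(nrow(lev0), nchar(seqc) - 5)
  # unmasked: canonical levels
  for (i in seq_len(nrow(lev0))) {
    idx <- forktrace:::kmer_index_one(substr(seqc, i, i + 5))
    expect_equal(lev0$mean[i], pm$mean[idx])
  }
  lev1 <- expected_levels(seqc, TRUE, pm)
  changed <- which(lev1$mean != lev0$mean)
  # exactly the 6 overlapping windows covering position 6 change
  expect_identical(changed, 1:6)
})

test_that("expected_levels validates its inputs", {
  pm <- pm_fixture
  expect_error(expected_levels("ACGTNN", logical(1), pm), "invalid characters")
  expect_error(expected_levels("ACGTAC", logical(0), pm), "thymidines")
})
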
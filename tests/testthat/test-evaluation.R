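test_that("confusion counts follow the strict-threshold definition", {
  cc <- confusion_at_threshold(c(0.9, 0.2), c(TRUE, FALSE), 0.5)
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1L, 1L, 0L, 0L))
  cc1 <- confusion_at_threshold(runif(50), rep(c(TRUE, FALSE), 25), 1)
  expect_identical(cc1$TP + cc1$FP, 0L)
  expect_error(confusion_at_threshold(runif(3), c(TRUE, FALSE)), "length")
  # perfectly separated probabilities leave no errors at 0.5
  cc2 <- confusion_at_threshold(c(0.9, 0.95, 0.05, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE), 0.5)
  expect_identical(cc2$FP + cc2$FN, 0L)
})

test_that("balanced accuracy and specificity match hand computation and guard degenerate input", {
  cc <- structure(list(TP = 9L, FN = 1L, TN = 8L, FP = 2L),
                  class = "confusion_counts")
  expect_equal(balanced_accuracy(cc), 0.85)
  expect_equal(specificity(cc), 0.8)
  cc_perfect <- structure(list(TP = 5L, FN = 0L, TN = 7L, FP = 0L),
                          class = "confusion_counts")
  expect_equal(specificity(cc_perfect), 1)
  cc_deg <- structure(list(TP = 0L, FN = 0L, TN = 7L, FP = 0L),
                      class = "confusion_counts")
  expect_error(balanced_accuracy(cc_deg), "no positive truths")
  cc_deg2 <- structure(list(TP = 3L, FN = 1L, TN = 0L, FP = 0L),
                       class = "confusion_counts")
  expect_error(specificity(cc_deg2), "no negative truths")
})

test_that("confusion counting agrees with a brute-force recount on random instances", {
  for (i in 1:5) {
    set.seed(700 + i)
    n <- 500
    prob <- runif(n)
    truth <- runif(n) < 0.4
    th <- runif(1)
    cc <- confusion_at_threshold(prob, truth, th)
    bf <- confusion_bruteforce(prob, truth, th)
    expect_identical(cc$TP, bf$TP)
    expect_identical(cc$FP, bf$FP)
    expect_identical(cc$TN, bf$TN)
    expect_identical(cc$FN, bf$FN)
  }
})

test_that("ROC curves span (0,0) to (1,1), are monotone, and integrate sensibly", {
  set.seed(77)
  truth <- rep(c(TRUE, FALSE), 2500)
  # perfect classifier
  roc_p <- roc_curve(ifelse(truth, 0.9, 0.1), truth)
  expect_equal(attr(roc_p, "auc"), 1)
  # uninformative probabilities: area near one half
  roc_r <- roc_curve(runif(5000), truth)
  expect_lt(abs(attr(roc_r, "auc") - 0.5), 0.05)
  expect_true(all(diff(roc_r$threshold) > 0))
  # TPR and FPR are non-increasing in the threshold
  expect_true(all(diff(roc_r$TPR) <= 1e-12))
  expect_true(all(diff(roc_r$FPR) <= 1e-12))
  expect_equal(c(roc_r$FPR[1], roc_r$TPR[1]), c(1, 1))
  expect_equal(c(tail(roc_r$FPR, 1), tail(roc_r$TPR, 1)), c(0, 0))
  expect_error(roc_curve(runif(10), rep(TRUE, 10)), "both truth classes")
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  truth <- rep(c(TRUE, FALSE), 400)
  prob <- ifelse(truth, rbeta(800, 3, 2), rbeta(800, 2, 3))
  ours <- attr(roc_curve(prob, truth), "auc")
  theirs <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("the informative curve dominates a probability-shuffled control", {
  set.seed(78)
  n <- 4000
  truth <- rep(c(TRUE, FALSE), n / 2)
  prob <- ifelse(truth, rbeta(n, 4, 2), rbeta(n, 2, 4))
  roc_i <- roc_curve(prob, truth, n_thresholds = 41)
  roc_s <- roc_curve(sample(prob), truth, n_thresholds = 41)
  # compare TPR at matched FPR via interpolation
  fpr_grid <- seq(0.05, 0.95, by = 0.05)
  tpr_i <- approx(roc_i$FPR, roc_i$TPR, fpr_grid, ties = max)$y
  tpr_s <- approx(roc_s$FPR, roc_s$TPR, fpr_grid, ties = max)$y
  expect_true(all(tpr_i >= tpr_s - 0.02))
  expect_gt(attr(roc_i, "auc"), attr(roc_s, "auc") + 0.1)
})

test_that("median profiles reduce to the obvious answers for degenerate cohorts", {
  rows <- data.frame(position = c(3L, 13L, 29L), probability = c(0.1, 0.9, 0.4),
                     sixmer = rep("TAAAAA", 3), stringsAsFactors = FALSE)
  rec <- forktrace:::new_detect_record("p1", "primer_construct", 0L, 80L, "+", rows)
  prof1 <- median_profile(list(rec))
  expect_equal(prof1$median_probability, rows$probability)
  expect_identical(prof1$position, rows$position + 1L)  # 1-based report
  recs <- lapply(1:7, function(i) {
    forktrace:::new_detect_record(paste0("p", i), "primer_construct", 0L, 80L, "+", rows)
  })
  prof <- median_profile(recs)
  expect_equal(prof$median_probability, rows$probability)
  expect_identical(prof$n_reads, rep(7L, 3))
  expect_error(median_profile(list()), "empty cohort")
})

test_that("origin distances match an exhaustive nearest-neighbour scan", {
  known <- data.frame(contig = "chrI",
                      start = c(12000L, 40000L, 90000L),
                      end = c(12500L, 41000L, 90200L))
  calls <- forktrace:::new_feature_call("origin", "chrI",
                                        c(9000L, 12100L, 55000L),
                                        c(11000L, 12400L, 56000L),
                                        "r", 1)
  res <- origin_distance_distribution(calls, known)
  # midpoint 10000 vs [12000,12500): distance 2000 (to the left)
  expect_equal(abs(res$distances[1]), 2000)
  # overlapping call: zero
  expect_equal(res$distances[2], 0)
  # every distance agrees with the brute-force scan
  mids <- (calls$start + calls$end) / 2
  for (i in seq_along(mids)) {
    expect_equal(abs(res$distances[i]), nearest_origin_bruteforce(mids[i], known))
  }
  # unknown contig: warned and skipped
  calls2 <- forktrace:::new_feature_call("origin", "chrX", 0L, 100L, "r", 1)
  expect_warning(res2 <- origin_distance_distribution(calls2, known), "skipped")
  expect_identical(res2$n_skipped, 1L)
  expect_length(res2$distances, 0)
  # empty call set: empty distribution
  res3 <- origin_distance_distribution(calls[0, ], known)
  expect_length(res3$distances, 0)
})

test_that("pileups count interval-bin overlaps and locate planted loci", {
  calls <- forktrace:::new_feature_call("origin", "chr", 1500L, 2500L, "r", 1)
  pu <- pileup(calls, 5000, bin_bp = 1000)
  expect_identical(pu$count, c(0L, 1L, 1L, 0L, 0L))   # spans two bins
  expect_gte(sum(pu$count), nrow(calls))
  pu0 <- pileup(calls[0, ], 5000, bin_bp = 1000)
  expect_true(all(pu0$count == 0L))
  # three planted loci dominate the track (planted intervals sit fully
  # inside one bin so the argmax is unambiguous)
  set.seed(80)
  loci <- c(10000L, 50000L, 80000L)
  planted <- do.call(rbind, lapply(loci, function(o) {
    forktrace:::new_feature_call("origin", "chr",
                                 o + 200L + sample(-50:50, 20, TRUE),
                                 o + 1500L + sample(-50:50, 20, TRUE), "r", 1)
  }))
  noise <- forktrace:::new_feature_call("origin", "chr",
                                        sample(0:99000, 10), 99500L, "r", 1)
  pu3 <- pileup(rbind(planted, noise), 100000, bin_bp = 2000)
  top3 <- pu3$start[order(pu3$count, decreasing = TRUE)][1:3]
  expect_setequal(top3 %/% 2000L, loci %/% 2000L)
  expect_error(pileup(calls, 5000, bin_bp = 0), "bin_bp")
})
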
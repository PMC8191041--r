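test_that("model builds are deterministic and sized as specified", {
  m1 <- build_detect_model(seed = 11)
  m2 <- build_detect_model(seed = 11)
  expect_identical(m1$par, m2$par)
  m3 <- build_detect_model(seed = 12)
  expect_false(identical(m1$par, m3$par))
  # parameter count: stem + blocks(depthwise, pointwise, bias, BN) + head
  cfg <- m1$config
  expected <- cfg$features * cfg$channels + cfg$channels +
    cfg$blocks * (cfg$kernel * cfg$channels + cfg$channels^2 + 3 * cfg$channels) +
    cfg$window_W * cfg$channels * 2 + 2
  expect_identical(count_parameters(m1), as.integer(expected))
  expect_lt(count_parameters(m1), 500000)
  expect_error(build_detect_model(kernel = 4), "odd")
  expect_error(build_detect_model(blocks = 0), "invalid")
})

test_that("softmax output is a normalised pair for arbitrary tensors", {
  m <- build_detect_model(seed = 3)
  set.seed(41)
  x <- array(rnorm(20 * 15 * forktrace:::N_TENSOR_FEATURES, sd = 2),
             c(20, 15, forktrace:::N_TENSOR_FEATURES))
  fw <- forktrace:::detect_forward(m, x, train = FALSE)
  expect_equal(rowSums(fw$prob), rep(1, 20), tolerance = 1e-12)
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  # the folded inference path agrees with the reference forward pass
  expect_equal(predict_detect(m, x), fw$prob[, 2], tolerance = 1e-12)
  # an all-sentinel tensor still yields a probability in [0, 1]
  x0 <- array(0, c(1, 15, forktrace:::N_TENSOR_FEATURES))
  x0[1, , 6] <- 1
  p <- predict_detect(m, x0)
  expect_true(p >= 0 && p <= 1)
})

test_that("training requires both classes and beats chance on separable data", {
  m <- build_detect_model(blocks = 2, channels = 8, seed = 5)
  n <- 600
  set.seed(42)
  x <- array(rnorm(n * 15 * forktrace:::N_TENSOR_FEATURES, sd = 0.3),
             c(n, 15, forktrace:::N_TENSOR_FEATURES))
  y <- rep(0:1, length.out = n)
  x[y == 1, 8, 5] <- x[y == 1, 8, 5] + 3       # class signal in one feature
  expect_error(train_detect(m, x, rep(0L, n)), "single class")
  tr <- train_detect(m, x, y, epochs = 3, seed = 17)
  expect_gt(tail(tr$history$val_acc, 1), 0.5)
  expect_true(tr$trained)
})

test_that("training with permuted labels stays at chance", {
  m <- build_detect_model(blocks = 2, channels = 8, seed = 5)
  n <- 1200
  set.seed(43)
  x <- array(rnorm(n * 15 * forktrace:::N_TENSOR_FEATURES, sd = 0.3),
             c(n, 15, forktrace:::N_TENSOR_FEATURES))
  y <- rep(0:1, length.out = n)
  x[y == 1, 8, 5] <- x[y == 1, 8, 5] + 2
  y_perm <- sample(y)                           # break the association
  tr <- train_detect(m, x, y_perm, epochs = 3, seed = 19)
  expect_lt(abs(tail(tr$history$val_acc, 1) - 0.5), 0.15)
})

test_that("classification at a threshold follows the strict-inequality rule", {
  rows <- data.frame(position = c(10L, 20L, 30L),
                     probability = c(0.2, 0.7, 0.5),
                     sixmer = c("TAAAAA", "TCCCCC", "TGGGGG"),
                     stringsAsFactors = FALSE)
  rec <- forktrace:::new_detect_record("r1", "chr", 0L, 100L, "+", rows)
  expect_identical(classify_at_threshold(rec, 0.5), c(FALSE, TRUE, FALSE))
  expect_identical(classify_at_threshold(rec, 0), rep(TRUE, 3))
  expect_identical(classify_at_threshold(rec, 1), rep(FALSE, 3))
  expect_error(classify_at_threshold(rec, 1.5), "threshold")
})

test_that("detect records validate their invariants", {
  rows <- data.frame(position = c(10L, 5L), probability = c(0.2, 0.3),
                     sixmer = c("TAAAAA", "TCCCCC"), stringsAsFactors = FALSE)
  expect_error(forktrace:::new_detect_record("r", "c", 0L, 50L, "+", rows),
               "strictly increasing")
  rows2 <- data.frame(position = c(5L, 10L), probability = c(0.2, 1.3),
                      sixmer = c("TAAAAA", "TCCCCC"), stringsAsFactors = FALSE)
  expect_error(forktrace:::new_detect_record("r", "c", 0L, 50L, "+", rows2),
               "\\[0, 1\\]")
})

test_that("a read with no thymidines yields an empty record, not an error", {
  m <- build_detect_model(seed = 2)
  tb <- list(x = array(0, c(0, 15, forktrace:::N_TENSOR_FEATURES)),
             positions = integer(0), n_excluded = 0L)
  rec <- detect_read(m, tb, "r0", "chr", 0L, 60L, "+", random_contig(60, 1))
  expect_identical(nrow(rec$rows), 0L)
})
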
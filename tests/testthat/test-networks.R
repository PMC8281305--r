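test_that("network specs encode the task heads and losses", {
  s17 <- build_network("segment17")
  expect_equal(s17$n_out, 17L)
  expect_equal(s17$loss, "cross-entropy")
  expect_equal(s17$batch, 23L); expect_equal(s17$lr, 0.001)
  expect_equal(s17$epochs, 10L)
  reg <- build_network("uvc_regression")
  expect_equal(reg$n_out, 2L)
  expect_equal(reg$loss, "mae")
  expect_equal(reg$epochs, 15L)
  expect_equal(build_network("phi_classification")$n_out, 68L)
  expect_equal(build_network("epiendo")$n_out, 2L)
  expect_error(build_network("qrs_axis"), "unknown task")
})

make_toy_dataset <- function(n, n_class = 4, seed = 1) {
  # class-dependent low-rank patterns + noise: easily separable
  set.seed(seed)
  protos <- lapply(seq_len(n_class), function(k) matrix(rnorm(256), 16, 16))
  cls <- rep_len(seq_len(n_class), n)
  rows <- lapply(seq_len(n), function(i) {
    m <- protos[[cls[i]]] + 0.1 * matrix(rnorm(256), 16, 16)
    signal_matrix(m, "ecg")
  })
  structure(tibble::tibble(
    beat = seq_len(n), parent = seq_len(n), split = "train",
    seg17 = cls, seg68 = cls, wedge = cls,
    wall_class = ifelse(cls %% 2 == 0, "endo", "epi"),
    uvc_z = (cls - 1) / (n_class - 1), uvc_rho = rev(cls - 1) / (n_class - 1),
    ecg = rows, egm = rows
  ), class = c("vt_dataset", class(tibble::tibble())))
}

test_that("a small network memorizes a toy dataset (capacity sanity)", {
  ds <- make_toy_dataset(50)
  spec <- build_network("segment17", conv1 = 8, conv2 = 16, fc = 64, epochs = 200,
                        lr = 0.01)
  m <- train_network(spec, ds, "ecg", seed = 1)
  x <- dataset_tensors(ds, "ecg", "segment17")$x
  pred <- max.col(predict_proba(m, x))
  expect_equal(mean(pred == ds$seg17), 1)
  # loss decreased over training
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
})

test_that("randomly permuted labels yield chance-level generalization", {
  ds <- make_toy_dataset(240, n_class = 4, seed = 2)
  set.seed(3)
  ds$seg17 <- sample(ds$seg17)          # destroy the signal-label relation
  train_idx <- 1:180
  ds$split[-train_idx] <- "test"
  spec <- build_network("segment17", conv1 = 8, conv2 = 16, fc = 64, epochs = 10)
  m <- train_network(spec, ds, "ecg", seed = 4)
  xte <- dataset_tensors(ds, "ecg", "segment17", split = "test")$x
  yte <- ds$seg17[ds$split == "test"]
  acc <- mean(max.col(predict_proba(m, xte)) == yte)
  # only 4 of the 17 classes occur; chance is ~1/4 within binomial noise
  expect_lt(acc, 0.25 + 3 * sqrt(0.25 * 0.75 / length(yte)))
})

test_that("training is deterministic per seed", {
  ds <- make_toy_dataset(46)
  spec <- build_network("segment17", conv1 = 4, conv2 = 8, fc = 16, epochs = 2)
  m1 <- train_network(spec, ds, "ecg", seed = 7)
  m2 <- train_network(spec, ds, "ecg", seed = 7)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$weights$W1, m2$weights$W1)
  m3 <- train_network(spec, ds, "ecg", seed = 8)
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("probability outputs are simplex vectors, consistent across batching", {
  ds <- make_toy_dataset(46)
  spec <- build_network("segment17", conv1 = 4, conv2 = 8, fc = 16, epochs = 2)
  m <- train_network(spec, ds, "ecg", seed = 1)
  x <- dataset_tensors(ds, "ecg", "segment17")$x
  p <- predict_proba(m, x)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  # batch prediction equals per-item prediction
  p1 <- predict_proba(m, x[3, , drop = FALSE])
  expect_equal(as.numeric(p1), p[3, ], tolerance = 1e-12)
  # regression models refuse probability queries
  reg <- train_network(build_network("uvc_regression", conv1 = 4, conv2 = 8,
                                     fc = 16, epochs = 1), ds, "ecg", seed = 1)
  expect_error(predict_proba(reg, x), "classification")
})

test_that("UVC head combination clips coordinates and inverts wedges", {
  ds <- make_toy_dataset(46)
  reg <- train_network(build_network("uvc_regression", conv1 = 4, conv2 = 8,
                                     fc = 16, epochs = 1), ds, "ecg", seed = 1)
  cls <- train_network(build_network("phi_classification", conv1 = 4, conv2 = 8,
                                     fc = 16, epochs = 1), ds, "ecg", seed = 1)
  x <- dataset_tensors(ds, "ecg", "segment17")$x[1:5, ]
  out <- predict_uvc(reg, cls, x)
  expect_true(all(out$z >= 0 & out$z <= 1))
  expect_true(all(out$rho >= 0 & out$rho <= 1))
  expect_equal(out$phi, wedge_to_phi(out$wedge))
  # deterministic for fixed weights
  expect_identical(out, predict_uvc(reg, cls, x))

  egm_reg <- reg; egm_reg$modality <- "egm"
  expect_error(predict_uvc(egm_reg, cls, x), "modalities")
})

test_that("cross-validation folds group by parent beat", {
  ds <- make_toy_dataset(60)
  # two augmented copies per parent
  ds2 <- ds[rep(1:60, each = 2), ]
  ds2$beat <- 1:120
  spec <- build_network("segment17", conv1 = 4, conv2 = 8, fc = 16, epochs = 1)
  m <- train_network(spec, ds2, "ecg", seed = 2, cv_folds = 3)
  expect_equal(nrow(m$cv), 3L)
  expect_equal(sum(m$cv$n_holdout), 120L)
  # holdout counts are even because parents carry both copies together
  expect_true(all(m$cv$n_holdout %% 2 == 0))
})

test_that("tidiers summarise trained models", {
  ds <- make_toy_dataset(46)
  spec <- build_network("epiendo", conv1 = 4, conv2 = 8, fc = 16, epochs = 2)
  m <- train_network(spec, ds, "ecg", seed = 1)
  expect_equal(nrow(tidy(m)), 2L)
  gl <- glance(m)
  expect_equal(gl$task, "epiendo")
  expect_gt(gl$n_parameters, 0)
})
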
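test_that("CNN architecture has the specified shape and parameter count", {
  net <- build_cnn(model_spec("CNN", seed = 1))
  convs <- Filter(function(l) l$type == "conv", net$layers)
  expect_length(convs, 5)
  for (l in convs) expect_equal(dim(l$W)[c(1, 3)], c(9L, 4L))  # 3x3, 4 maps
  expect_length(Filter(function(l) l$type == "pool", net$layers), 2)
  expect_length(Filter(function(l) l$type == "dense", net$layers), 3)

  # hand-computed layer arithmetic:
  # conv1 1->4: 4*9+4 = 40; conv2..5 4->4: 4*4*9+4 = 148 each
  # BN per conv: 2*4 = 8 (x5); dense 4->32: 160; BN-32: 64
  # dense 32->32: 1056; dense 32->1: 33
  expected <- (1 * 4 * 9 + 4) + 4 * (4 * 4 * 9 + 4) + 5 * (2 * 4) +
    (4 * 32 + 32) + 2 * 32 + (32 * 32 + 32) + (32 * 1 + 1)
  expect_equal(vorofield:::n_params(net), expected)
  expect_equal(expected, 1985L)
})

test_that("forward passes yield probabilities and are deterministic in batches", {
  net <- build_cnn(model_spec("CNN", seed = 5))
  set.seed(8)
  X <- matrix(rnorm(3721 * 7), 3721, 7)
  s_batch <- vorofield:::predict_network(net, X)
  expect_true(all(s_batch > 0 & s_batch < 1))
  s_single <- vapply(1:7, function(i)
    vorofield:::predict_network(net, X[, i, drop = FALSE]), numeric(1))
  expect_equal(s_batch, s_single, tolerance = 1e-6)

  # same seed -> identical initial weights
  net2 <- build_cnn(model_spec("CNN", seed = 5))
  expect_identical(net$layers[[1]]$W, net2$layers[[1]]$W)
  net3 <- build_cnn(model_spec("CNN", seed = 6))
  expect_false(identical(net$layers[[1]]$W, net3$layers[[1]]$W))
})

test_that("flat NN uses L+2 input features and builds reproducibly", {
  g1 <- builtin_pattern("G1")
  feats <- vorofield:::nn_features(
    small_cohort(n_subjects = 2, visits = 1, seed = 2, pattern = g1)$records, g1)
  expect_equal(ncol(feats), g1$L + 2L)  # 59 deviations + MD + sLV

  nn1 <- build_nn(model_spec("NN", seed = 4), g1$L + 2L)
  nn2 <- build_nn(model_spec("NN", seed = 4), g1$L + 2L)
  expect_identical(nn1$layers[[1]]$W, nn2$layers[[1]]$W)
  s <- vorofield:::predict_network(nn1, matrix(rnorm(3 * 61), 3, 61))
  expect_true(all(s > 0 & s < 1))
  expect_error(predict(structure(list(network = nn1), class = "vf_model"),
                       matrix(0, 2, 10)), "features")
})

test_that("training on a separable cohort reaches perfect ranking and checkpoints by validation loss", {
  sep <- separable_images(160, seed = 12)
  tr_idx <- 1:128
  va_idx <- 129:160
  net <- build_cnn(model_spec("CNN", seed = 2))
  fit <- train_model(net,
                     train = list(x = sep$x[, tr_idx], y = sep$y[tr_idx],
                                  subjects = paste0("s", tr_idx)),
                     val = list(x = sep$x[, va_idx], y = sep$y[va_idx],
                                subjects = paste0("s", va_idx)),
                     epochs = 10, seed = 3)
  expect_s3_class(fit, "vf_model")
  expect_equal(fit$selected_epoch, which.min(fit$history$val_loss))
  tr_scores <- predict(fit, sep$x[, tr_idx])
  expect_equal(average_precision(tr_scores, sep$y[tr_idx]), 1.0)

  # monotone probe: deepening the scotoma must not lower the EG score
  eg_col <- which(sep$y == 1)[1]
  deeper <- sep$x[, eg_col]
  deeper[sep$scotoma] <- deeper[sep$scotoma] - 10
  expect_gte(predict(fit, matrix(deeper, ncol = 1)),
             predict(fit, sep$x[, eg_col, drop = FALSE]))

  # training is reproducible under fixed seeds
  fit2 <- train_model(build_cnn(model_spec("CNN", seed = 2)),
                      train = list(x = sep$x[, tr_idx], y = sep$y[tr_idx]),
                      val = list(x = sep$x[, va_idx], y = sep$y[va_idx]),
                      epochs = 10, seed = 3)
  expect_equal(fit$history, fit2$history)
  expect_identical(fit$network$layers, fit2$network$layers)
})

test_that("training rejects protocol violations", {
  sep <- separable_images(40, seed = 4)
  net <- build_nn(model_spec("NN", seed = 1), 3721L)
  expect_error(
    train_model(build_cnn(model_spec("CNN", seed = 1)),
                train = list(x = sep$x[, 1:30], y = sep$y[1:30],
                             subjects = rep(c("a", "b", "c"), 10)),
                val = list(x = sep$x[, 31:40], y = sep$y[31:40],
                           subjects = rep(c("c", "d"), 5)),
                epochs = 1),
    "both training and validation")
  expect_error(
    train_model(build_cnn(model_spec("CNN", seed = 1)),
                train = list(x = sep$x[, c(1, 3, 5)], y = rep(0, 3)),
                val = list(x = sep$x[, 31:40], y = sep$y[31:40]),
                epochs = 1),
    "both classes")
})

test_that("high-level fits accept VF tables end to end", {
  ds <- small_cohort(n_subjects = 8, visits = 2, seed = 19)
  p <- builtin_pattern("24-2")
  fit <- vf_cnn(ds$records, p, epochs = 4, seed = 2)
  expect_s3_class(fit, "vf_cnn")
  sc <- predict(fit, ds$records)
  expect_length(sc, nrow(ds$records))
  expect_true(all(sc > 0 & sc < 1))
  # validation subjects never overlap the training remainder by construction
  expect_true(all(fit$val_subjects %in% ds$records$subject_id))

  fit_nn <- vf_nn(ds$records, p, epochs = 4, seed = 2)
  expect_s3_class(fit_nn, "vf_nn")
  expect_length(predict(fit_nn, ds$records), nrow(ds$records))

  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(fit_nn, tmp)
  expect_true(file.exists(sub("rds$", "json", tmp)))
  back <- load_model(tmp)
  expect_equal(predict(back, ds$records), predict(fit_nn, ds$records))
})
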
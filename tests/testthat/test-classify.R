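# Classifier family, training, evaluation and last-layer transfer learning.

test_that("classifier specs honor the published deep layout and class width", {
  spec <- build_classifier("deep", 66, n_classes = 6)
  kinds <- vapply(spec$plan, function(l) l$kind, "")
  convs <- vapply(spec$plan[kinds == "conv"], function(l) l$n_filters, 0L)
  expect_identical(convs, c(512L, 128L, 64L, 32L, 16L, 8L))
  denses <- vapply(spec$plan[kinds == "dense"], function(l) l$units, 0L)
  expect_identical(denses, c(256L, 128L, 6L))
  expect_identical(spec$plan[[length(spec$plan)]]$kind, "softmax")
  # intermediate drops the 512 block, keeping 128-64-32-16
  ispec <- build_classifier("intermediate", 50, n_classes = 6)
  ikinds <- vapply(ispec$plan, function(l) l$kind, "")
  expect_identical(vapply(ispec$plan[ikinds == "conv"], function(l) l$n_filters, 0L),
                   c(128L, 64L, 32L, 16L))
  expect_error(build_classifier("deep", 64), "input_size")
})

test_that("the deep cascade is realizable on every supported input size", {
  for (s in c(66, 60, 56, 50, 46, 40, 36)) {
    spec <- build_classifier("deep", s, n_classes = 6)
    tr <- plan_shape_trace(spec$plan, c(s, s, 1))
    expect_true(all(tr$h >= 1 & tr$w >= 1), label = paste("size", s))
  }
})

test_that("training rejects folds that do not cover the class universe", {
  folds <- fx_class_folds()
  spec <- build_classifier("shallow", 36, n_classes = 6)
  bad <- list(train = folds$train[crop_labels(folds$train) != "RBC"])
  expect_error(train_classifier(spec, bad,
                                train_config(loss = "crossentropy", epochs = 1)),
               "6 classes")
})

test_that("a small classifier overfits a tiny subset to perfect training accuracy", {
  folds <- fx_class_folds()
  by_class <- split(folds$train, crop_labels(folds$train))
  tiny <- unlist(lapply(by_class, function(x) x[1:10]), recursive = FALSE)
  spec <- build_classifier("shallow", 36, n_classes = 6)
  clf <- train_classifier(spec, list(train = tiny),
                          train_config(loss = "crossentropy", epochs = 30,
                                       batch_size = 12, learning_rate = 2e-3,
                                       seed = 3))
  expect_identical(tail(clf$history$train_acc, 1), 1)
  probs <- predict_classifier(clf, tiny[1:5])
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
})

test_that("training with a fixed seed reproduces identical weights", {
  folds <- fx_class_folds()
  by_class <- split(folds$train, crop_labels(folds$train))
  tiny <- unlist(lapply(by_class, function(x) x[1:5]), recursive = FALSE)
  spec <- build_classifier("shallow", 36, n_classes = 6)
  cfg <- train_config(loss = "crossentropy", epochs = 2, batch_size = 10,
                      seed = 17)
  c1 <- train_classifier(spec, list(train = tiny), cfg)
  c2 <- train_classifier(spec, list(train = tiny), cfg)
  expect_identical(c1$model$layers[[1]]$W, c2$model$layers[[1]]$W)
  expect_identical(c1$history$loss, c2$history$loss)
})

test_that("evaluation of a perfect predictor yields a diagonal confusion matrix", {
  folds <- fx_class_folds()
  test <- folds$test[seq(1, length(folds$test), by = 6)]
  truth <- crop_labels(test)
  # stub classifier whose forward pass is replaced by the truth itself
  fake_eval <- metrics_table(truth, truth)
  expect_true(all(fake_eval$fp == 0) && all(fake_eval$fn == 0))
  expect_true(all(fake_eval$accuracy == 1))
  cm <- table(factor(truth), factor(truth))
  expect_true(all(cm[upper.tri(cm)] == 0) && all(cm[lower.tri(cm)] == 0))
})

test_that("last-layer transfer adds a class while freezing the backbone bit-exactly", {
  folds <- fx_class_folds()
  labels_tr <- crop_labels(folds$train)
  keep <- c("WBC", "MCF7", "BEAD20")
  new_cl <- "RBC"
  tiny <- function(fold, classes, n) {
    by_class <- split(fold, crop_labels(fold))
    unlist(lapply(by_class[classes], function(x) x[seq_len(n)]),
           recursive = FALSE)
  }
  train_old <- tiny(folds$train, keep, 30)
  spec <- build_classifier("shallow", 36, n_classes = 3)
  clf <- train_classifier(spec, list(train = train_old),
                          train_config(loss = "crossentropy", epochs = 12,
                                       batch_size = 16, learning_rate = 2e-3,
                                       seed = 5))
  test_mixed <- tiny(folds$test, c(keep, new_cl), 12)
  before <- evaluate_classifier(clf, test_mixed)
  # the unseen class cannot be predicted at all before transfer
  expect_identical(unname(before$confusion[new_cl, new_cl]), 0L)
  res <- transfer_learn(clf, transfer_config(new_cl, retrain_epochs = 12,
                                             seed = 7),
                        new_crops = tiny(folds$train, new_cl, 30),
                        old_crops = train_old,
                        test_crops = test_mixed,
                        train_cfg = train_config(loss = "crossentropy",
                                                 batch_size = 16,
                                                 learning_rate = 3e-3, seed = 7))
  expect_identical(unname(res$before$confusion[new_cl, new_cl]), 0L)
  # all non-last-layer parameters are bit-identical
  dense_idx <- which(vapply(clf$model$layers, function(l) l$kind == "dense", TRUE))
  last <- dense_idx[length(dense_idx)]
  for (i in seq_along(clf$model$layers)) {
    if (i == last || is.null(clf$model$layers[[i]]$W)) next
    expect_identical(res$model$model$layers[[i]]$W, clf$model$layers[[i]]$W)
    expect_identical(res$model$model$layers[[i]]$b, clf$model$layers[[i]]$b)
  }
  expect_identical(ncol(res$model$model$layers[[last]]$W),
                   ncol(clf$model$layers[[last]]$W) + 1L)
  expect_identical(res$model$classes, c(sort(keep), new_cl))
  # the widened model now recognizes the new class on held-out crops
  new_correct <- res$after$confusion[new_cl, new_cl] /
    sum(res$after$confusion[new_cl, ])
  expect_gt(new_correct, 0.5)
  expect_error(transfer_learn(clf, transfer_config("WBC"), list(), list()),
               "already")
})

test_that("classifiers round-trip through the JSON checkpoint", {
  folds <- fx_class_folds()
  by_class <- split(folds$train, crop_labels(folds$train))
  tiny <- unlist(lapply(by_class, function(x) x[1:3]), recursive = FALSE)
  spec <- build_classifier("shallow", 36, n_classes = 6)
  clf <- train_classifier(spec, list(train = tiny),
                          train_config(loss = "crossentropy", epochs = 1,
                                       seed = 2))
  path <- tempfile(fileext = ".json")
  write_nn(clf, path)
  back <- read_nn(path)
  p1 <- predict_classifier(clf, tiny[1:4])
  p2 <- predict_classifier(back, tiny[1:4])
  expect_equal(p1, p2, tolerance = 1e-12)
})
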
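#' Build a cell-type classifier specification
#'
#' Three members of one convolutional family, all ending in a dense stack and
#' a softmax over the class labels:
#' \describe{
#'   \item{deep}{conv512(3x3) - pool3 - conv128(3x3)+drop0.5 - pool2 -
#'     conv64(3x3)+drop0.2 - pool2 - conv32(3x3)+drop0.2 - pool3 -
#'     conv16(3x3) - pool3 - conv8(3x3) - pool3 - FC256 - FC128+drop0.2 -
#'     softmax.}
#'   \item{intermediate}{the deep model minus its leading 512-kernel block
#'     and one pooling stage (kernel counts 128-64-32-16).}
#'   \item{shallow}{conv32(3x3) - pool3 - conv16(3x3) - pool2 - FC64 -
#'     softmax, a light model for quick baselines.}
#' }
#' Pooling layers that would shrink a small input below one pixel are
#' skipped at build time with a notice, so the same family serves every
#' supported crop size.
#'
#' @param depth `"shallow"`, `"intermediate"` or `"deep"`.
#' @param input_size Crop side in pixels, one of 66, 60, 56, 50, 46, 40, 36.
#' @param n_classes Number of output classes.
#' @return List of class `classifier_spec` with `plan`, `depth`,
#'   `input_size`, `n_classes`.
#' @export
build_classifier <- function(depth = c("intermediate", "shallow", "deep"),
                             input_size = 50, n_classes = 6) {
  depth <- match.arg(depth)
  if (!input_size %in% c(66, 60, 56, 50, 46, 40, 36)) {
    stop("input_size must be one of 66, 60, 56, 50, 46, 40, 36")
  }
  conv <- function(f) list(kind = "conv", kernel = 3, n_filters = as.integer(f))
  relu <- list(kind = "activation", fun = "relu")
  pool <- function(k) list(kind = "pool", kernel = as.integer(k))
  drop <- function(r) list(kind = "dropout", rate = r)
  dense <- function(u) list(kind = "dense", units = as.integer(u))
  layers <- switch(depth,
    deep = list(conv(512), relu, pool(3),
                conv(128), relu, drop(0.5), pool(2),
                conv(64), relu, drop(0.2), pool(2),
                conv(32), relu, drop(0.2), pool(3),
                conv(16), relu, pool(3),
                conv(8), relu, pool(3),
                dense(256), relu, dense(128), relu, drop(0.2)),
    intermediate = list(conv(128), relu, drop(0.5), pool(2),
                        conv(64), relu, drop(0.2), pool(2),
                        conv(32), relu, drop(0.2), pool(3),
                        conv(16), relu, pool(3),
                        dense(256), relu, dense(128), relu, drop(0.2)),
    shallow = list(conv(32), relu, pool(3),
                   conv(16), relu, pool(2),
                   dense(64), relu)
  )
  layers <- c(layers, list(dense(n_classes), list(kind = "softmax")))
  plan <- conv_plan(layers)
  tr <- plan_shape_trace(plan, c(input_size, input_size, 1))
  if (any(tr$h < 1 | tr$w < 1)) {
    bad <- which(tr$h < 1 | tr$w < 1)[1]
    stop(sprintf("input %d too small for the cascade: layer %d (%s) yields %dx%d",
                 input_size, bad, tr$kind[bad], tr$h[bad], tr$w[bad]))
  }
  structure(list(plan = plan, depth = depth,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes)),
            class = "classifier_spec")
}

# Crops resized (center-cropped) to the spec input and stacked for the net.
crops_for_classifier <- function(crops, input_size) {
  crops_to_array(lapply(crops, center_crop, size = input_size))
}

#' Train a cell-type classifier
#'
#' Minibatch Adam under categorical cross-entropy, with per-epoch training
#' and validation accuracy/loss curves. Crops larger than the spec's input
#' size are center-cropped down.
#'
#' @param spec A [build_classifier()] spec.
#' @param folds List with `train` (required) and optionally `val` crop lists,
#'   e.g. from [split_dataset()].
#' @param cfg A [train_config()] (loss forced to `"crossentropy"`).
#' @param classes Class universe fixing output order; defaults to sorted
#'   labels of the training fold, all of which must be present.
#' @return List of class `classifier` with `model`, `classes`, `input_size`,
#'   `history` (epoch, loss, train_acc, val_loss, val_acc), `spec`.
#' @export
train_classifier <- function(spec, folds, cfg, classes = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  cfg$loss <- "crossentropy"
  labels <- crop_labels(folds$train)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) != spec$n_classes) {
    stop(sprintf("spec expects %d classes but training fold has %d",
                 spec$n_classes, length(classes)))
  }
  if (!all(classes %in% labels)) {
    stop("class(es) absent from the training fold: ",
         paste(setdiff(classes, labels), collapse = ", "))
  }
  x <- crops_for_classifier(folds$train, spec$input_size)
  y <- one_hot(labels, classes)
  xv <- yv <- NULL
  if (!is.null(folds$val) && length(folds$val)) {
    xv <- crops_for_classifier(folds$val, spec$input_size)
    yv <- one_hot(crop_labels(folds$val), classes)
  }
  model <- nn_build(spec$plan, c(spec$input_size, spec$input_size, 1L),
                    seed = cfg$seed)
  fit <- nn_train(model, x, y, cfg, x_val = xv, y_val = yv)
  structure(list(model = fit$model, classes = classes,
                 input_size = spec$input_size, history = fit$history,
                 spec = spec),
            class = "classifier")
}

#' Class-probability predictions for crops
#'
#' @param clf A `classifier`.
#' @param crops List of [cell_crop()].
#' @return Matrix (crops x classes) of softmax probabilities; every row sums
#'   to 1.
#' @export
predict_classifier <- function(clf, crops) {
  stopifnot(inherits(clf, "classifier"))
  p <- nn_predict(clf$model, crops_for_classifier(crops, clf$input_size))
  colnames(p) <- clf$classes
  p
}

#' Evaluate a classifier on a labelled fold
#'
#' @param clf A `classifier`.
#' @param test_crops Non-empty list of labelled [cell_crop()].
#' @return List of class `classifier_eval`: `accuracy`, `confusion` (table,
#'   rows = true classes, columns = predicted), `metrics` (per-class
#'   [metrics_table()]), `roc` (per-class [roc_auc()] results), `predicted`.
#' @export
evaluate_classifier <- function(clf, test_crops) {
  stopifnot(inherits(clf, "classifier"))
  if (length(test_crops) == 0) stop("test fold is empty")
  truth <- crop_labels(test_crops)
  unknown <- setdiff(unique(truth), clf$classes)
  prob <- predict_classifier(clf, test_crops)
  pred <- clf$classes[max.col(prob)]
  universe <- c(clf$classes, unknown)
  confusion <- table(factor(truth, levels = universe),
                     factor(pred, levels = universe))
  roc <- tryCatch(roc_set(prob, truth), error = function(e) NULL)
  structure(
    list(accuracy = mean(pred == truth), confusion = confusion,
         metrics = metrics_table(truth, pred, classes = universe),
         roc = roc, predicted = pred),
    class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("accuracy %.4f over %d samples\n", x$accuracy,
              sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Transfer configuration for introducing a new class
#'
#' @param new_class_label Label of the class to be added.
#' @param retrain_epochs Epochs of last-layer retraining.
#' @param mix Fraction of the retraining set drawn from the new class; the
#'   remainder is sampled uniformly from the old classes (default 0.5).
#' @param seed Integer seed for sampling and the new output column init.
#' @return List of class `transfer_config`.
#' @export
transfer_config <- function(new_class_label, retrain_epochs = 10, mix = 0.5,
                            seed = 1) {
  if (mix <= 0 || mix > 1) stop("mix must be in (0, 1]")
  structure(list(new_class_label = new_class_label,
                 retrain_epochs = as.integer(retrain_epochs), mix = mix,
                 seed = as.integer(seed)),
            class = "transfer_config")
}

#' Last-layer transfer learning for a newly introduced cell type
#'
#' Adapts a trained classifier to one additional class without retraining
#' the feature extractor: every layer is frozen except the final dense
#' (pre-softmax) layer, which is widened by one output column for the new
#' class and retrained on a mix of new-class samples and samples of the old
#' classes. Because only the last layer is trainable, all other parameters
#' are bit-identical before and after.
#'
#' @param clf A trained `classifier` that does not know the new class.
#' @param cfg A [transfer_config()].
#' @param new_crops Labelled crops of the new class (training).
#' @param old_crops Crops of the old classes to mix into retraining.
#' @param test_crops Optional labelled test crops (may include the new
#'   class) used to produce before/after confusion matrices.
#' @param train_cfg Optional [train_config()] overriding the retraining
#'   optimizer settings (epochs are taken from `cfg$retrain_epochs`).
#' @return List of class `transfer_result`: `model` (extended `classifier`),
#'   `before`/`after` ([evaluate_classifier()] results or NULL), `history`.
#' @export
transfer_learn <- function(clf, cfg, new_crops, old_crops, test_crops = NULL,
                           train_cfg = NULL) {
  stopifnot(inherits(clf, "classifier"), inherits(cfg, "transfer_config"))
  new_label <- cfg$new_class_label
  if (new_label %in% clf$classes) {
    stop("class '", new_label, "' is already in the model's label set")
  }
  if (!all(crop_labels(new_crops) == new_label)) {
    stop("new_crops must all carry the new class label")
  }
  before <- if (!is.null(test_crops)) evaluate_classifier(clf, test_crops)
  # widen the last dense layer by one output
  model <- clf$model
  dense_idx <- which(vapply(model$layers, function(l) l$kind == "dense", TRUE))
  last <- dense_idx[length(dense_idx)]
  w_old <- model$layers[[last]]$W
  new_col <- rng_local(cfg$seed,
                       stats::rnorm(nrow(w_old), 0, sqrt(2 / nrow(w_old))))
  model$layers[[last]]$W <- cbind(w_old, new_col)
  model$layers[[last]]$b <- c(model$layers[[last]]$b, 0)
  model$layers[[last]]$units <- ncol(w_old) + 1L
  model$output_shape <- ncol(w_old) + 1L
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$trainable <- i == last
  }
  # retraining mix: all new-class crops + old-class crops sampled uniformly
  n_new <- length(new_crops)
  n_old <- round(n_new * (1 - cfg$mix) / cfg$mix)
  old_sample <- rng_local(cfg$seed + 1L, {
    by_class <- split(old_crops, crop_labels(old_crops))
    take <- rep(names(by_class), length.out = n_old)
    lapply(seq_len(n_old), function(i) {
      pool <- by_class[[take[i]]]
      pool[[sample.int(length(pool), 1)]]
    })
  })
  mix_crops <- c(new_crops, old_sample)
  classes2 <- c(clf$classes, new_label)
  x <- crops_for_classifier(mix_crops, clf$input_size)
  y <- one_hot(crop_labels(mix_crops), classes2)
  tcfg <- if (is.null(train_cfg)) train_config(loss = "crossentropy",
                                               epochs = cfg$retrain_epochs,
                                               seed = cfg$seed) else train_cfg
  tcfg$loss <- "crossentropy"
  tcfg$epochs <- cfg$retrain_epochs
  fit <- nn_train(model, x, y, tcfg)
  clf2 <- structure(list(model = fit$model, classes = classes2,
                         input_size = clf$input_size, history = fit$history,
                         spec = clf$spec),
                    class = "classifier")
  after <- if (!is.null(test_crops)) evaluate_classifier(clf2, test_crops)
  structure(list(model = clf2, before = before, after = after,
                 history = fit$history),
            class = "transfer_result")
}

#' Serialize a network (or classifier) to a JSON checkpoint
#'
#' Plain-text checkpoint containing the layer plan, all parameter arrays and
#' the classifier metadata, reloadable with [read_nn()].
#'
#' @param x An `nn_model` or `classifier`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nn <- function(x, path) {
  is_clf <- inherits(x, "classifier")
  model <- if (is_clf) x$model else x
  layers <- lapply(model$layers, function(ly) {
    if (!is.null(ly$W)) {
      ly$W_dim <- dim(ly$W)
      ly$W <- as.numeric(ly$W)
    }
    ly
  })
  obj <- list(kind = if (is_clf) "classifier" else "nn_model",
              input_shape = model$input_shape,
              output_shape = model$output_shape,
              layers = layers)
  if (is_clf) {
    obj$classes <- x$classes
    obj$input_size <- x$input_size
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_nn
#' @export
read_nn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, function(ly) {
    if (!is.null(ly$W)) {
      ly$W <- matrix(unlist(ly$W), unlist(ly$W_dim)[1])
      ly$W_dim <- NULL
      ly$b <- unlist(ly$b)
    }
    ly
  })
  model <- structure(list(layers = layers,
                          input_shape = unlist(obj$input_shape),
                          output_shape = unlist(obj$output_shape)),
                     class = "nn_model")
  if (identical(obj$kind, "classifier")) {
    structure(list(model = model, classes = unlist(obj$classes),
                   input_size = unlist(obj$input_size), history = NULL,
                   spec = NULL),
              class = "classifier")
  } else {
    model
  }
}
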
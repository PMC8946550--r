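#' @useDynLib shadowcyto, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Layer plan for a convolutional network
#'
#' An ordered, serializable description of a network: each element is a list
#' with a `kind` and its parameters. Supported kinds:
#' \describe{
#'   \item{conv}{`kernel` (odd), `n_filters`, same padding, stride 1. The
#'     feature at (i, j) of filter k in layer l is the kernel's inner product
#'     with the input patch around (i, j) plus a per-filter bias.}
#'   \item{activation}{`fun` = "relu" or "linear".}
#'   \item{pool}{`kernel`: max-pooling over non-overlapping `kernel x kernel`
#'     neighborhoods (stride = kernel).}
#'   \item{dropout}{`rate`: training-time random zeroing (inverted scaling).}
#'   \item{flatten}{image to feature-vector transition.}
#'   \item{dense}{`units` fully connected outputs.}
#'   \item{softmax}{class-probability output (rows sum to 1).}
#' }
#'
#' @param ... Layer lists, e.g. `list(kind = "conv", kernel = 3, n_filters = 32)`.
#' @return List of class `conv_plan`.
#' @export
conv_plan <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.null(layers[[1]]$kind)) layers <- layers[[1]]
  for (ly in layers) {
    if (is.null(ly$kind)) stop("every layer needs a kind")
    if (ly$kind == "conv") {
      if (is.null(ly$kernel) || ly$kernel %% 2 == 0) {
        stop("conv kernel sizes must be odd (same padding)")
      }
      if (is.null(ly$n_filters) || ly$n_filters < 1) stop("conv needs n_filters >= 1")
    }
    if (ly$kind == "pool" && (is.null(ly$kernel) || ly$kernel < 1)) {
      stop("pool needs a kernel size")
    }
    if (ly$kind == "dropout" && (is.null(ly$rate) || ly$rate < 0 || ly$rate >= 1)) {
      stop("dropout rate must be in [0, 1)")
    }
    if (ly$kind == "dense" && (is.null(ly$units) || ly$units < 1)) {
      stop("dense needs units >= 1")
    }
  }
  structure(layers, class = "conv_plan")
}

#' Serialize / deserialize a layer plan as JSON
#'
#' @param plan A [conv_plan()].
#' @param path File path; when `NULL`, the JSON string is returned.
#' @return `plan_to_json`: path or JSON string. `plan_from_json`: the plan.
#' @export
plan_to_json <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname plan_to_json
#' @param json JSON string or file path produced by [plan_to_json()].
#' @export
plan_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  conv_plan(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

#' Convolutional denoising-autoencoder plan
#'
#' The all-convolutional denoiser: a cascade of same-padding conv layers with
#' ReLU activations whose kernel sizes grow then condense, ending in a single
#' 1x1 filter that collapses the feature maps back to one channel. Spatial
#' size is preserved throughout, so output shape equals input shape for any
#' crop size.
#'
#' @param kernels Odd kernel sizes, default `c(3, 3, 5, 5, 7, 7, 1)` (the
#'   configuration found to denoise best); the last entry must be 1.
#' @param n_filters Filters per layer except the last (default 32).
#' @return A [conv_plan()].
#' @export
build_cnn_autoencoder <- function(kernels = c(3, 3, 5, 5, 7, 7, 1),
                                  n_filters = 32) {
  if (length(kernels) == 0) stop("kernel plan must be non-empty")
  if (kernels[length(kernels)] != 1) stop("last layer must be a 1x1 condensing filter")
  layers <- list()
  for (i in seq_along(kernels)) {
    last <- i == length(kernels)
    layers[[length(layers) + 1]] <- list(kind = "conv", kernel = kernels[i],
                                         n_filters = if (last) 1L else as.integer(n_filters))
    layers[[length(layers) + 1]] <- list(kind = "activation",
                                         fun = if (last) "linear" else "relu")
  }
  conv_plan(layers)
}

#' Fully connected denoising-autoencoder plan
#'
#' Flattened-pixel autoencoder with ReLU hidden layers; the output layer is
#' linear with as many units as input pixels (set at build time).
#'
#' @param hidden Hidden-layer widths, e.g. `c(512, 256, 512)` or
#'   `c(256, 128, 64, 128, 256)`.
#' @return A [conv_plan()] whose final dense layer is marked `units = NA`
#'   (resolved to the input dimension by [nn_build()]).
#' @export
build_fc_autoencoder <- function(hidden = c(512, 256, 512)) {
  layers <- list(list(kind = "flatten"))
  for (h in hidden) {
    layers[[length(layers) + 1]] <- list(kind = "dense", units = as.integer(h))
    layers[[length(layers) + 1]] <- list(kind = "activation", fun = "relu")
  }
  layers[[length(layers) + 1]] <- list(kind = "dense", units = NA_integer_)
  structure(layers, class = "conv_plan")
}

#' Training configuration
#'
#' @param loss `"mse"` (denoisers) or `"crossentropy"` (classifier).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param lr_decay Multiplicative per-epoch learning-rate decay factor in
#'   (0, 1]; 1 (default) keeps the rate constant.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   dropout.
#' @param optimizer Only `"adam"` is implemented.
#' @param verbose Print per-epoch progress.
#' @return List of class `train_config`.
#' @export
train_config <- function(loss = "mse", epochs = 30, batch_size = 32,
                         learning_rate = 1e-3, lr_decay = 1, seed = 1,
                         optimizer = "adam", verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 seed = as.integer(seed),
                 optimizer = optimizer, verbose = verbose),
            class = "train_config")
}

#' Instantiate a network from a layer plan
#'
#' Walks the plan, propagating the input shape through every layer, and
#' initializes parameters (He-scaled normal weights, zero biases). Pooling
#' layers that would reduce a spatial dimension below one pixel are skipped
#' with a notice, so one plan family can serve all supported crop sizes.
#'
#' @param plan A [conv_plan()].
#' @param input_shape `(H, W, C)` of the input images, or a single integer
#'   `d` for flat `1 x 1 x d`-free dense-only plans.
#' @param seed Integer seed for the initialization draw.
#' @param init `"he"` (default), `"zero"`, or `"passthrough"`. Pass-through
#'   initialization applies to all-conv plans: on top of He noise, the first
#'   filter of every conv layer gets a unit center tap on its first input
#'   channel, so the freshly built network starts close to the identity map
#'   and training spends its budget on the denoising correction rather than
#'   on relearning reconstruction. This speeds up denoiser convergence
#'   considerably.
#' @return List of class `nn_model` with `layers` (parameters attached),
#'   `input_shape`, `output_shape`.
#' @export
nn_build <- function(plan, input_shape, seed = 1, init = "he") {
  stopifnot(inherits(plan, "conv_plan"))
  if (length(input_shape) == 2) input_shape <- c(input_shape, 1L)
  shape <- as.integer(input_shape)   # (H, W, C) or (d) after flatten
  flat <- FALSE
  in_dim <- prod(shape)
  layers <- list()
  rng_local(seed, {
    for (ly in plan) {
      ly$trainable <- TRUE
      if (ly$kind == "conv") {
        if (flat) stop("conv layer after flatten")
        fan_in <- ly$kernel^2 * shape[3]
        sd <- if (init == "zero") 0 else sqrt(2 / fan_in)
        if (init == "passthrough") sd <- sd / 4
        ly$W <- matrix(stats::rnorm(fan_in * ly$n_filters, 0, sd),
                       fan_in, ly$n_filters)
        if (init == "passthrough") {
          centre <- ly$kernel %/% 2
          delta_row <- centre + ly$kernel * centre + 1  # center tap, channel 1
          ly$W[delta_row, 1] <- ly$W[delta_row, 1] + 1
        }
        ly$b <- rep(0, ly$n_filters)
        shape[3] <- as.integer(ly$n_filters)
      } else if (ly$kind == "pool") {
        if (flat) stop("pool layer after flatten")
        if (shape[1] %/% ly$kernel < 1 || shape[2] %/% ly$kernel < 1) {
          message(sprintf("skipping %dx%d pool: input %dx%d too small",
                          ly$kernel, ly$kernel, shape[1], shape[2]))
          ly$skipped <- TRUE
        } else {
          shape[1] <- shape[1] %/% ly$kernel
          shape[2] <- shape[2] %/% ly$kernel
        }
      } else if (ly$kind == "flatten") {
        flat <- TRUE
        shape <- prod(shape)
      } else if (ly$kind == "dense") {
        if (!flat) { flat <- TRUE; shape <- prod(shape) }
        units <- if (is.na(ly$units)) in_dim else ly$units
        sd <- if (init == "zero") 0 else sqrt(2 / shape)
        ly$units <- as.integer(units)
        ly$W <- matrix(stats::rnorm(shape * units, 0, sd), shape, units)
        ly$b <- rep(0, units)
        shape <- as.integer(units)
      }
      layers[[length(layers) + 1]] <- ly
    }
  })
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 output_shape = shape),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("nn_model: input (%s) -> output (%s), %d layers, %d parameters\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x"),
              length(x$layers),
              sum(vapply(x$layers, function(l)
                length(l$W) + length(l$b), 0))))
  invisible(x)
}

#' Symbolic shape trace of a plan
#'
#' Propagates an input shape through the plan without allocating parameters;
#' useful to check that a pooling cascade is realizable for a given input
#' size.
#'
#' @param plan A [conv_plan()].
#' @param input_shape `(H, W, C)`.
#' @return data.frame with layer kind and the (H, W, C) after each layer.
#' @export
plan_shape_trace <- function(plan, input_shape) {
  if (length(input_shape) == 2) input_shape <- c(input_shape, 1L)
  shape <- as.integer(input_shape)
  flat <- FALSE
  rows <- list()
  for (ly in plan) {
    if (ly$kind == "conv") shape[3] <- as.integer(ly$n_filters)
    if (ly$kind == "pool") {
      if (shape[1] %/% ly$kernel >= 1 && shape[2] %/% ly$kernel >= 1) {
        shape[1] <- shape[1] %/% ly$kernel
        shape[2] <- shape[2] %/% ly$kernel
      }
    }
    if (ly$kind == "flatten") { flat <- TRUE; shape <- prod(shape) }
    if (ly$kind == "dense") {
      if (!flat) { flat <- TRUE; shape <- prod(shape) }
      shape <- as.integer(if (is.na(ly$units)) prod(input_shape) else ly$units)
    }
    rows[[length(rows) + 1]] <- data.frame(
      kind = ly$kind,
      h = if (flat) 1L else shape[1], w = if (flat) 1L else shape[2],
      c = if (flat) shape[1] else shape[3])
  }
  do.call(rbind, rows)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. X: (H, W, C, N) array, or N x d matrix for dense-only input.
# Returns list(out, caches). Dropout masks are drawn from the current RNG
# stream when training = TRUE.
nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  a <- x
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "conv") {
      caches[[i]] <- list(x = a)
      a <- .conv2d_forward(a, ly$W, ly$b, as.integer(ly$kernel))
    } else if (ly$kind == "activation") {
      if (ly$fun == "relu") {
        caches[[i]] <- list(pos = a > 0)
        a <- relu_fwd(a)
      }
    } else if (ly$kind == "pool") {
      if (!isTRUE(ly$skipped)) {
        res <- .maxpool_forward(a, as.integer(ly$kernel))
        caches[[i]] <- list(idx = res$idx, in_dim = dim(a))
        a <- res$out
      }
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(a)) >= ly$rate) / (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      }
    } else if (ly$kind == "flatten") {
      if (!is.matrix(a)) {
        caches[[i]] <- list(in_dim = dim(a))
        a <- t(matrix(a, prod(dim(a)[1:3]), dim(a)[4]))
      }
    } else if (ly$kind == "dense") {
      if (!is.matrix(a)) {
        caches[[i]] <- list(in_dim = dim(a))
        a <- t(matrix(a, prod(dim(a)[1:3]), dim(a)[4]))
      }
      caches[[i]] <- c(caches[[i]], list(x = a))
      a <- sweep(a %*% ly$W, 2, ly$b, `+`)
    } else if (ly$kind == "softmax") {
      a <- softmax_rows(a)
      caches[[i]] <- list(p = a)
    }
  }
  list(out = a, caches = caches)
}

# Backward pass from the loss gradient at the output. Returns list of
# per-layer gradients (dW, db) aligned with model$layers.
nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ca <- caches[[i]]
    if (ly$kind == "conv") {
      res <- .conv2d_backward(ca$x, ly$W, d, as.integer(ly$kernel))
      grads[[i]] <- list(dW = res$dW, db = res$db)
      d <- res$dx
    } else if (ly$kind == "activation") {
      if (ly$fun == "relu") d <- d * ca$pos
    } else if (ly$kind == "pool") {
      if (!isTRUE(ly$skipped)) {
        d <- .maxpool_backward(ca$idx, d, as.integer(ca$in_dim))
      }
    } else if (ly$kind == "dropout") {
      if (!is.null(ca$mask)) d <- d * ca$mask
    } else if (ly$kind == "flatten") {
      if (!is.null(ca$in_dim)) d <- array(t(d), ca$in_dim)
    } else if (ly$kind == "dense") {
      grads[[i]] <- list(dW = crossprod(ca$x, d), db = colSums(d))
      d <- d %*% t(ly$W)
      if (!is.null(ca$in_dim)) d <- array(t(d), ca$in_dim)
    } else if (ly$kind == "softmax") {
      # handled jointly with cross-entropy in nn_train; identity here
    }
  }
  grads
}

#' Forward-predict with a trained network
#'
#' @param model An `nn_model`.
#' @param x Input batch: `(H, W, C, N)` array or `N x d` matrix.
#' @param batch_size Evaluate in chunks of this many samples.
#' @return Network output (matrix or array); dropout disabled.
#' @export
nn_predict <- function(model, x, batch_size = 128) {
  is4 <- !is.matrix(x)
  n <- if (is4) dim(x)[4] else nrow(x)
  outs <- list()
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(n, start + batch_size - 1)
    xb <- if (is4) x[, , , take, drop = FALSE] else x[take, , drop = FALSE]
    outs[[length(outs) + 1]] <- nn_forward(model, xb, training = FALSE)$out
  }
  o1 <- outs[[1]]
  if (is.matrix(o1)) {
    do.call(rbind, outs)
  } else {
    d <- dim(o1); d[4] <- n
    arr <- array(0, d)
    at <- 0
    for (o in outs) {
      k <- dim(o)[4]
      arr[, , , at + seq_len(k)] <- o
      at <- at + k
    }
    arr
  }
}

# Loss value and output gradient.
nn_loss_grad <- function(loss, pred, target) {
  if (loss == "mse") {
    r <- pred - target
    list(loss = mean(r^2), grad = 2 * r / length(r))
  } else if (loss == "crossentropy") {
    # pred are softmax probabilities; combined softmax+CE gradient
    eps <- 1e-12
    n <- nrow(pred)
    list(loss = -sum(target * log(pred + eps)) / n,
         grad = (pred - target) / n)
  } else {
    stop("unknown loss: ", loss)
  }
}

#' Train a network by minibatch Adam
#'
#' Shuffles the data each epoch, draws dropout masks per batch, and applies
#' Adam updates to every trainable layer. The per-step loss trace and
#' per-epoch summaries (plus validation metrics when a validation set is
#' given) are returned alongside the model. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param model An `nn_model` from [nn_build()].
#' @param x,y Training inputs and targets (arrays `(H, W, C, N)` or matrices
#'   `N x d`; for cross-entropy, `y` is a one-hot matrix).
#' @param cfg A [train_config()].
#' @param x_val,y_val Optional validation set.
#' @return List with `model`, `loss_trace` (per step), and `history`
#'   (per-epoch data.frame).
#' @export
nn_train <- function(model, x, y, cfg, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "nn_model"), inherits(cfg, "train_config"))
  is4 <- !is.matrix(x)
  n <- if (is4) dim(x)[4] else nrow(x)
  state <- list()  # adam moments per layer
  step <- 0
  trace <- numeric(0)
  hist <- list()
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  rng_local(cfg$seed, {
    decay <- if (is.null(cfg$lr_decay)) 1 else cfg$lr_decay
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * decay^(epoch - 1)
      ord <- sample(n)
      ep_loss <- 0; ep_batches <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        take <- ord[start:min(n, start + cfg$batch_size - 1)]
        xb <- if (is4) x[, , , take, drop = FALSE] else x[take, , drop = FALSE]
        yb <- if (is.matrix(y)) y[take, , drop = FALSE] else y[, , , take, drop = FALSE]
        fw <- nn_forward(model, xb, training = TRUE)
        lg <- nn_loss_grad(cfg$loss, fw$out, yb)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite loss at epoch %d step %d (lr %.3g); try a smaller learning rate",
                       epoch, step + 1, cfg$learning_rate))
        }
        grads <- nn_backward(model, fw$caches, lg$grad)
        step <- step + 1
        for (i in seq_along(model$layers)) {
          g <- grads[[i]]
          if (is.null(g) || !isTRUE(model$layers[[i]]$trainable)) next
          if (is.null(state[[as.character(i)]])) {
            state[[as.character(i)]] <- list(mW = 0 * g$dW, vW = 0 * g$dW,
                                             mb = 0 * g$db, vb = 0 * g$db)
          }
          s <- state[[as.character(i)]]
          s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
          s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
          s$mb <- beta1 * s$mb + (1 - beta1) * g$db
          s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
          state[[as.character(i)]] <- s
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          model$layers[[i]]$W <- model$layers[[i]]$W -
            lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
          model$layers[[i]]$b <- model$layers[[i]]$b -
            lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
        }
        trace <- c(trace, lg$loss)
        ep_loss <- ep_loss + lg$loss; ep_batches <- ep_batches + 1
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / ep_batches)
      if (cfg$loss == "crossentropy") {
        row$train_acc <- nn_accuracy(model, x, y)
      }
      if (!is.null(x_val)) {
        vfw <- nn_predict(model, x_val)
        row$val_loss <- nn_loss_grad(cfg$loss, vfw, y_val)$loss
        if (cfg$loss == "crossentropy") {
          row$val_acc <- mean(max.col(vfw) == max.col(y_val))
        }
      }
      if (cfg$verbose) {
        cat(sprintf("epoch %d/%d: %s\n", epoch, cfg$epochs,
                    paste(sprintf("%s=%.4f", names(row)[-1],
                                  as.numeric(row[-1])), collapse = " ")))
      }
      hist[[epoch]] <- row
    }
  })
  list(model = model, loss_trace = trace,
       history = do.call(rbind, lapply(hist, function(r) {
         for (cn in c("train_acc", "val_loss", "val_acc")) {
           if (is.null(r[[cn]])) r[[cn]] <- NA_real_
         }
         r
       })))
}

# Classification accuracy of a model on one-hot targets.
nn_accuracy <- function(model, x, y_onehot) {
  p <- nn_predict(model, x)
  mean(max.col(p) == max.col(y_onehot))
}

#' One-hot encode labels
#'
#' @param labels Label vector.
#' @param classes Class universe fixing the column order.
#' @return `length(labels) x length(classes)` 0/1 matrix.
#' @export
one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}
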
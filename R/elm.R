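#' Fit an extreme-learning-machine denoising autoencoder (batch solve)
#'
#' A single-hidden-layer network whose input weights and biases are drawn
#' randomly once and never trained; only the output weights \eqn{\beta} are
#' learned, in closed form. With hidden activations
#' \eqn{H = g(X W + b)} and targets \eqn{T}, the regularized least-squares
#' solution is
#' \deqn{\beta = (H^\top H + I/C)^{-1} H^\top T,}
#' the ridge form of the Moore-Penrose pseudoinverse solution of
#' \eqn{H \beta = T}. The inverse term
#' \eqn{P = (H^\top H + I/C)^{-1}} is retained so that [elm_update()] can
#' later fold in new batches recursively without refitting.
#'
#' For denoising, rows of `noisy` are flattened noisy crops scaled to
#' `[0, 1]` and rows of `clean` the corresponding clean crops.
#'
#' @param noisy Sample matrix (n x d features).
#' @param clean Target matrix (n x m), same row count.
#' @param n_hidden Hidden-layer width (default 2000, the width at which the
#'   denoiser's SNR improvement saturates).
#' @param C Positive ridge regularizer; `Inf` requests the plain
#'   pseudoinverse (used as a fallback with a message if the normal matrix is
#'   singular).
#' @param seed Integer seed for the random input weights.
#' @param activation `"sigmoid"` (default), `"relu"` or `"linear"`.
#' @return List of class `elm_model` with `input_weights` (d x n_hidden,
#'   immutable), `input_biases`, `beta`, `P`, `C`, `n_seen`.
#' @export
elm_fit <- function(noisy, clean, n_hidden = 2000, C = 1e3, seed = 1,
                    activation = "sigmoid") {
  noisy <- as.matrix(noisy); clean <- as.matrix(clean)
  if (nrow(noisy) != nrow(clean)) stop("noisy and clean must have equal row counts")
  if (n_hidden < 1) stop("n_hidden must be at least 1")
  d <- ncol(noisy)
  w <- rng_local(seed, {
    list(W = matrix(stats::runif(d * n_hidden, -1, 1), d, n_hidden),
         b = stats::runif(n_hidden, 0, 1))
  })
  model <- structure(
    list(input_weights = w$W, input_biases = w$b, beta = NULL, P = NULL,
         C = C, n_hidden = as.integer(n_hidden), activation = activation,
         seed = as.integer(seed), n_seen = 0L),
    class = "elm_model")
  h <- elm_hidden(model, noisy)
  gram <- crossprod(h)
  if (is.finite(C)) gram <- gram + diag(n_hidden) / C
  p <- tryCatch(solve(gram), error = function(e) NULL)
  if (is.null(p)) {
    message("normal matrix singular; falling back to Moore-Penrose pseudoinverse")
    model$beta <- MASS::ginv(h) %*% clean
    model$P <- MASS::ginv(gram)
  } else {
    model$P <- p
    model$beta <- p %*% crossprod(h, clean)
  }
  model$n_seen <- nrow(noisy)
  model
}

# Hidden-layer activations H = g(X W + b).
elm_hidden <- function(model, x) {
  z <- sweep(as.matrix(x) %*% model$input_weights, 2, model$input_biases, `+`)
  switch(model$activation,
         sigmoid = 1 / (1 + exp(-z)),
         relu = pmax(z, 0),
         linear = z,
         stop("unknown activation: ", model$activation))
}

#' Online-sequential update of an ELM
#'
#' Folds a new batch into a fitted model by the recursive least-squares
#' update of online-sequential ELM, which reproduces the batch solution on
#' the union of all data seen so far (to numerical precision):
#' \deqn{P_{k+1} = P_k - P_k H^\top (I + H P_k H^\top)^{-1} H P_k,}
#' \deqn{\beta_{k+1} = \beta_k + P_{k+1} H^\top (T - H \beta_k),}
#' with \eqn{H, T} the hidden activations and targets of the new batch and
#' \eqn{P_0} the inverse term from [elm_fit()]. Input weights are never
#' touched. This is what makes the denoiser incrementally extensible to new
#' sample types without retraining from scratch.
#'
#' @param model An `elm_model` from [elm_fit()].
#' @param noisy_batch,clean_batch New batch (0 rows is a no-op).
#' @return Updated `elm_model`.
#' @export
elm_update <- function(model, noisy_batch, clean_batch) {
  stopifnot(inherits(model, "elm_model"))
  if (is.null(model$P)) stop("model has no running inverse term; fit it first")
  noisy_batch <- as.matrix(noisy_batch); clean_batch <- as.matrix(clean_batch)
  if (nrow(noisy_batch) == 0) return(model)
  if (ncol(noisy_batch) != nrow(model$input_weights)) {
    stop("feature dimension mismatch with the fitted model")
  }
  if (nrow(noisy_batch) != nrow(clean_batch)) {
    stop("noisy and clean batches must have equal row counts")
  }
  h <- elm_hidden(model, noisy_batch)
  ph <- model$P %*% t(h)                       # n_hidden x k
  inner <- diag(nrow(h)) + h %*% ph            # k x k
  p_new <- model$P - ph %*% solve(inner, t(ph))
  model$beta <- model$beta + p_new %*% crossprod(h, clean_batch - h %*% model$beta)
  model$P <- p_new
  model$n_seen <- model$n_seen + nrow(noisy_batch)
  model
}

#' Predict with an ELM
#'
#' @param model An `elm_model`.
#' @param x Sample matrix (n x d).
#' @return Output matrix `H(x) beta`.
#' @export
elm_predict <- function(model, x) {
  elm_hidden(model, x) %*% model$beta
}

#' Denoise a crop with a fitted ELM autoencoder
#'
#' Flattens the crop to the `[0, 1]` feature scale the model was trained on,
#' maps it through the network, and rescales the reconstruction back to the
#' crop's intensity range (clipped). Deterministic.
#'
#' @param model An `elm_model` trained on flattened crops of the same size.
#' @param noisy A [cell_crop()].
#' @return Denoised [cell_crop()] with metadata preserved.
#' @export
elm_denoise <- function(model, noisy) {
  stopifnot(inherits(model, "elm_model"), inherits(noisy, "cell_crop"))
  d <- noisy$size
  if (d * d != nrow(model$input_weights)) {
    stop(sprintf("crop size %d^2 does not match model feature dimension %d; center_crop() the input",
                 d, nrow(model$input_weights)))
  }
  full <- 2^noisy$bit_depth - 1
  y <- elm_predict(model, matrix(as.numeric(noisy$pixels) / full, 1))
  out <- noisy
  out$pixels <- matrix(pmin(pmax(y * full, 0), full), d, d)
  out$context <- NULL
  out
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("elm_model: %d features -> %d hidden (%s) -> %d outputs, C = %g, %d samples seen\n",
              nrow(x$input_weights), x$n_hidden, x$activation,
              if (is.null(x$beta)) 0L else ncol(x$beta), x$C, x$n_seen))
  invisible(x)
}
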
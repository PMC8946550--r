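#' Train a learned denoiser on noisy/clean crop pairs
#'
#' Trains a denoising autoencoder: the network sees the noisy crop and is
#' fit by Adam to reconstruct the clean crop under mean-squared-error loss.
#' Three architectures are provided: the all-convolutional autoencoder
#' ([build_cnn_autoencoder()]), and two fully connected ones with hidden
#' widths 512-256-512 (`"fc3"`) and 256-128-64-128-256 (`"fc5"`). Pixels are
#' scaled to `[0, 1]` internally.
#'
#' @param arch `"cnn"`, `"fc3"`, `"fc5"`, or a custom [conv_plan()].
#' @param noisy_crops,clean_crops Aligned lists of same-size [cell_crop()].
#' @param cfg A [train_config()] (loss is forced to `"mse"`).
#' @param seed Seed for weight initialization (training randomness comes from
#'   `cfg$seed`).
#' @return List of class `denoiser`: `model`, `arch`, `size`, `loss_trace`,
#'   `history`.
#' @export
train_denoiser <- function(arch, noisy_crops, clean_crops, cfg, seed = cfg$seed) {
  if (length(noisy_crops) != length(clean_crops)) {
    stop("noisy and clean crop lists must be aligned")
  }
  size <- clean_crops[[1]]$size
  cfg$loss <- "mse"
  if (is.character(arch)) {
    plan <- switch(arch,
                   cnn = build_cnn_autoencoder(),
                   fc3 = build_fc_autoencoder(c(512, 256, 512)),
                   fc5 = build_fc_autoencoder(c(256, 128, 64, 128, 256)),
                   stop("unknown denoiser arch: ", arch,
                        " (use cnn, fc3, fc5 or a conv_plan)"))
    name <- arch
  } else {
    plan <- arch
    name <- "custom"
  }
  convolutional <- any(vapply(plan, function(l) l$kind == "conv", TRUE))
  if (convolutional) {
    x <- crops_to_array(noisy_crops)
    y <- crops_to_array(clean_crops)
  } else {
    x <- crops_to_matrix(noisy_crops)
    y <- crops_to_matrix(clean_crops)
  }
  model <- nn_build(plan, if (convolutional) c(size, size, 1L) else c(1L, 1L, size^2),
                    seed = seed,
                    init = if (convolutional) "passthrough" else "he")
  fit <- nn_train(model, x, y, cfg)
  structure(list(model = fit$model, arch = name, size = as.integer(size),
                 convolutional = convolutional, loss_trace = fit$loss_trace,
                 history = fit$history),
            class = "denoiser")
}

#' Denoise a crop with a trained model
#'
#' Dispatches on the model type: a `denoiser` (neural network) or an
#' `elm_model`. Output pixels are clipped to the crop's intensity range;
#' results are deterministic.
#'
#' @param model A `denoiser` or `elm_model`.
#' @param crop A [cell_crop()] of the size the model was trained on.
#' @return Denoised [cell_crop()].
#' @export
denoise <- function(model, crop) {
  if (inherits(model, "elm_model")) return(elm_denoise(model, crop))
  stopifnot(inherits(model, "denoiser"), inherits(crop, "cell_crop"))
  if (crop$size != model$size) {
    stop(sprintf("crop size %d does not match model size %d; center_crop() the input",
                 crop$size, model$size))
  }
  full <- 2^crop$bit_depth - 1
  if (model$convolutional) {
    x <- array(crop$pixels / full, c(crop$size, crop$size, 1, 1))
    y <- nn_predict(model$model, x)[, , 1, 1]
  } else {
    x <- matrix(as.numeric(crop$pixels) / full, 1)
    y <- matrix(nn_predict(model$model, x), crop$size, crop$size)
  }
  out <- crop
  out$pixels <- pmin(pmax(y * full, 0), full)
  out$context <- NULL
  out
}

# --- classical filter baselines ---------------------------------------------

# 5x5 (radius r) bilateral filter with replicated edges; sigma_color on the
# intensity scale, sigma_space in pixels.
bilateral_filter <- function(img, d = 5, sigma_color = 75, sigma_space = 75) {
  r <- d %/% 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[pmin(pmax(seq(1 - r, nr + r), 1), nr),
             pmin(pmax(seq(1 - r, nc + r), 1), nc)]
  acc <- matrix(0, nr, nc); wsum <- matrix(0, nr, nc)
  for (dy in -r:r) {
    for (dx in -r:r) {
      shifted <- pad[r + dy + seq_len(nr), r + dx + seq_len(nc)]
      w <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2)) *
        exp(-(shifted - img)^2 / (2 * sigma_color^2))
      acc <- acc + w * shifted
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# Orthonormal 1D DCT-II matrix of size n.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  m[1, ] <- sqrt(1 / n)
  m
}

# Orthonormal Haar matrix for n a power of two.
haar_matrix <- function(n) {
  h <- matrix(1)
  while (nrow(h) < n) {
    h <- rbind(kronecker(h, matrix(c(1, 1), 1)),
               kronecker(diag(nrow(h)), matrix(c(1, -1), 1)))
  }
  h / sqrt(rowSums(h^2))
}

# Single-stage collaborative filter in the BM3D style: block matching of
# 8x8 patches, 2D DCT + 1D Haar transform of each matched group, hard
# thresholding at thr_k * sigma, and weighted aggregation of the filtered
# patches. `sigma` is the noise standard deviation on the image's own scale.
bm3d_hard_filter <- function(img, sigma, patch = 8, step = 3, search = 16,
                             max_group = 16, thr_k = 2.7) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < patch || nc < patch) stop("image smaller than the matching patch")
  pos_i <- seq(1, nr - patch + 1)
  pos_j <- seq(1, nc - patch + 1)
  npos_i <- length(pos_i); npos_j <- length(pos_j)
  # all stride-1 patches as columns (patch^2 x n_patches), then their 2D DCT
  n_pat <- npos_i * npos_j
  pat <- matrix(0, patch * patch, n_pat)
  r <- 1
  for (dj in 0:(patch - 1)) {
    for (di in 0:(patch - 1)) {
      pat[r, ] <- as.numeric(img[pos_i + di, pos_j + dj, drop = FALSE])
      r <- r + 1
    }
  }
  d1 <- dct_matrix(patch)
  d2 <- kronecker(d1, d1)             # 2D DCT as a single matrix
  coef <- d2 %*% pat
  ref_i <- unique(c(seq(1, npos_i, step), npos_i))
  ref_j <- unique(c(seq(1, npos_j, step), npos_j))
  haar <- haar_matrix(max_group)
  thr <- thr_k * sigma
  acc <- matrix(0, nr, nc); wmap <- matrix(0, nr, nc)
  pid <- function(i, j) i + (j - 1) * npos_i
  for (rj in ref_j) {
    for (ri in ref_i) {
      ci <- max(1, ri - search):min(npos_i, ri + search)
      cj <- max(1, rj - search):min(npos_j, rj + search)
      cand <- as.integer(outer(ci, (cj - 1) * npos_i, `+`))
      dist <- colSums((coef[, cand, drop = FALSE] - coef[, pid(ri, rj)])^2)
      grp <- cand[order(dist)[seq_len(min(max_group, length(cand)))]]
      g <- coef[, grp, drop = FALSE]
      k <- length(grp)
      hk <- if (k == max_group) haar else haar_matrix(2^floor(log2(k)))
      if (nrow(hk) < k) { grp <- grp[seq_len(nrow(hk))]; g <- g[, seq_len(nrow(hk)), drop = FALSE]; k <- nrow(hk) }
      tg <- g %*% t(hk)
      keep <- abs(tg) >= thr
      keep[1, 1] <- TRUE              # always keep the group DC component
      nkept <- sum(keep)
      tg[!keep] <- 0
      filt <- t(d2) %*% (tg %*% hk)   # back to pixel-domain patches
      w <- 1 / max(1, nkept)
      for (m in seq_len(k)) {
        jj <- (grp[m] - 1) %/% npos_i + 1
        ii <- grp[m] - (jj - 1) * npos_i
        rows <- ii:(ii + patch - 1); cls <- jj:(jj + patch - 1)
        acc[rows, cls] <- acc[rows, cls] + w * matrix(filt[, m], patch, patch)
        wmap[rows, cls] <- wmap[rows, cls] + w
      }
    }
  }
  out <- acc / wmap
  out[wmap == 0] <- img[wmap == 0]
  out
}

#' Classical denoising filter baselines
#'
#' Reference point for the learned denoisers: Gaussian blur, box (average)
#' filter, median filter, bilateral filter, and a single-stage
#' (hard-thresholding) BM3D-style collaborative filter. The BM3D baseline
#' takes the true noise standard deviation as a parameter, an oracle
#' advantage the learned models do not get.
#'
#' @param crop A [cell_crop()].
#' @param method One of `"gaussian"`, `"average"`, `"median"`, `"bilateral"`,
#'   `"bm3d"`.
#' @param sigma Gaussian blur sigma in pixels (method `"gaussian"`).
#' @param size Box/median window side in pixels (methods `"average"`,
#'   `"median"`; odd).
#' @param d,sigma_color,sigma_space Bilateral window and range/space scales.
#' @param noise_sd Noise standard deviation on the intensity scale (method
#'   `"bm3d"`).
#' @return Filtered [cell_crop()], clipped to the intensity range.
#' @export
baseline_denoise <- function(crop, method,
                             sigma = 1, size = 3,
                             d = 5, sigma_color = 75, sigma_space = 75,
                             noise_sd = 10) {
  stopifnot(inherits(crop, "cell_crop"))
  full <- 2^crop$bit_depth - 1
  img <- crop$pixels
  out_px <- switch(method,
    gaussian = if (sigma <= 0.01) img else EBImage::gblur(img, sigma = sigma),
    average = {
      k <- matrix(1 / size^2, size, size)
      EBImage::filter2(img, k)
    },
    median = full * EBImage::medianFilter(img / full, size %/% 2),
    bilateral = bilateral_filter(img, d, sigma_color, sigma_space),
    bm3d = bm3d_hard_filter(img, noise_sd),
    stop("unknown method '", method,
         "'; available: gaussian, average, median, bilateral, bm3d")
  )
  out <- crop
  out$pixels <- pmin(pmax(out_px, 0), full)
  out$context <- NULL
  out
}

#' Benchmark denoisers over a noise-variance sweep
#'
#' For every noise variance, corrupts each clean test crop with seeded
#' Gaussian noise and evaluates every method's mean SNR improvement over the
#' crop set, in the layout of a variance-by-method comparison table.
#'
#' @param clean_crops List of clean test [cell_crop()].
#' @param methods Named list of functions `function(noisy_crop, variance)`
#'   returning a denoised crop. Learned models can be wrapped via
#'   `function(cr, v) denoise(model, cr)`; variance-aware baselines can use
#'   `v` (e.g. BM3D's oracle sigma).
#' @param variances Noise variances to sweep (default `seq(100, 600, 100)`).
#' @param seed Base seed; the noise for crop i at variance v is derived from
#'   it deterministically.
#' @return data.frame: one row per variance, one column per method, entries
#'   mean SNR improvement in dB; attribute `"scale"` records the intensity
#'   scale the SNR was computed on.
#' @export
snr_benchmark <- function(clean_crops, methods, variances = seq(100, 600, 100),
                          seed = 1) {
  stopifnot(length(methods) > 0, !is.null(names(methods)))
  rows <- lapply(variances, function(v) {
    imps <- matrix(NA_real_, length(clean_crops), length(methods))
    for (i in seq_along(clean_crops)) {
      cl <- clean_crops[[i]]
      no <- add_gaussian_noise(cl, noise_spec(v, seed = seed + 7919L * i + as.integer(v)))
      for (m in seq_along(methods)) {
        den <- methods[[m]](no, v)
        imps[i, m] <- snr_improvement(cl, no, den)$snr_imp
      }
    }
    stats::setNames(data.frame(v, t(colMeans(imps))), c("variance", names(methods)))
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- sprintf("%d-bit intensity", clean_crops[[1]]$bit_depth)
  out
}

#' Standard baseline set for [snr_benchmark()]
#'
#' @param sigma,size,d,sigma_color,sigma_space Parameters passed to
#'   [baseline_denoise()].
#' @return Named list of benchmark method functions for the five classical
#'   filters; the BM3D entry uses `sqrt(variance)` as its oracle sigma.
#' @export
baseline_methods <- function(sigma = 1, size = 3, d = 5, sigma_color = 75,
                             sigma_space = 75) {
  list(
    gaussian = function(cr, v) baseline_denoise(cr, "gaussian", sigma = sigma),
    average = function(cr, v) baseline_denoise(cr, "average", size = size),
    median = function(cr, v) baseline_denoise(cr, "median", size = size),
    bilateral = function(cr, v) baseline_denoise(cr, "bilateral", d = d,
                                                 sigma_color = sigma_color,
                                                 sigma_space = sigma_space),
    bm3d = function(cr, v) baseline_denoise(cr, "bm3d", noise_sd = sqrt(v))
  )
}

#' Serialize an ELM model to a portable file
#'
#' Writes all arrays and metadata as a single JSON container (plain text).
#'
#' @param model An `elm_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_elm <- function(model, path) {
  obj <- list(n_hidden = model$n_hidden, C = model$C,
              activation = model$activation, seed = model$seed,
              n_seen = model$n_seen,
              dims = list(input_weights = dim(model$input_weights),
                          beta = dim(model$beta), P = dim(model$P)),
              input_weights = as.numeric(model$input_weights),
              input_biases = model$input_biases,
              beta = as.numeric(model$beta), P = as.numeric(model$P))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(input_weights = matrix(obj$input_weights, obj$dims$input_weights[1]),
         input_biases = obj$input_biases,
         beta = matrix(obj$beta, obj$dims$beta[1]),
         P = matrix(obj$P, obj$dims$P[1]),
         C = obj$C, n_hidden = as.integer(obj$n_hidden),
         activation = obj$activation, seed = as.integer(obj$seed),
         n_seen = as.integer(obj$n_seen)),
    class = "elm_model")
}
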
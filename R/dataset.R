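#' Single-cell diffraction crop
#'
#' The unit of all learning in this package: a square intensity patch around
#' one particle, together with its class label and augmentation provenance.
#' `base_id` identifies the un-augmented source crop; every rotated copy
#' shares it, which is what the leakage-aware split keys on.
#'
#' @param pixels Square numeric matrix of quantized intensities.
#' @param class_label Class label string.
#' @param base_id Integer identity of the source crop.
#' @param rotation_deg Rotation applied to the source, degrees clockwise.
#' @param bit_depth Intensity scale of `pixels`.
#' @param context Optional larger square matrix around the same center, kept
#'   on unrotated crops so rotations can be rendered without undefined
#'   corners.
#' @return List of class `cell_crop`; `$size` is the side length in pixels.
#' @export
cell_crop <- function(pixels, class_label, base_id = 1L, rotation_deg = 0L,
                      bit_depth = 8L, context = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("crop must be square")
  structure(list(pixels = pixels, class_label = class_label,
                 base_id = as.integer(base_id),
                 rotation_deg = as.integer(rotation_deg),
                 size = nrow(pixels), bit_depth = as.integer(bit_depth),
                 context = context),
            class = "cell_crop")
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("cell_crop %dx%d %s (base %d, rot %d deg)\n",
              x$size, x$size, x$class_label, x$base_id, x$rotation_deg))
  invisible(x)
}

# Context side for a given crop window: at least window*sqrt(2), grown to
# keep (context - window) even so the two centers align on the pixel grid.
context_window <- function(window) {
  cw <- ceiling(window * sqrt(2))
  if ((cw - window) %% 2 == 1) cw <- cw + 1
  as.integer(cw)
}

#' Crop single-particle patches out of a micrograph
#'
#' Extracts a `window x window` patch centered on each (rounded) center, plus
#' the larger rotation-context patch. Centers too close to the frame edge for
#' the context window are skipped with a warning.
#'
#' @param micrograph A `micrograph` (synthetic truth centers are typically
#'   used as `centers`).
#' @param centers Two-column matrix or data.frame of 0-based `(x, y)` centers.
#' @param window Crop side in pixels (default 66).
#' @param labels Optional class labels per center (defaults to the
#'   micrograph truth labels when `centers` is omitted).
#' @return List of [cell_crop()] with sequential `base_id` and
#'   `rotation_deg = 0`.
#' @export
crop_patches <- function(micrograph, centers = NULL, window = 66, labels = NULL) {
  stopifnot(inherits(micrograph, "micrograph"))
  if (is.null(centers)) {
    centers <- as.matrix(micrograph$truth[, c("x", "y")])
    if (is.null(labels)) labels <- micrograph$truth$class_label
  }
  centers <- as.matrix(centers)
  if (length(centers) == 0) return(list())
  if (is.null(labels)) labels <- rep("unknown", nrow(centers))
  cw <- context_window(window)
  chalf <- floor(cw / 2)
  img <- micrograph$intensity
  nr <- nrow(img); nc <- ncol(img)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(centers))) {
    cx <- round(centers[i, 1]); cy <- round(centers[i, 2])
    r0 <- cy - chalf; c0 <- cx - chalf          # 0-based top-left of context
    if (r0 < 0 || c0 < 0 || r0 + cw > nr || c0 + cw > nc) {
      skipped <- skipped + 1L
      next
    }
    ctx <- img[r0 + seq_len(cw), c0 + seq_len(cw)]
    off <- (cw - window) / 2
    out[[length(out) + 1L]] <- cell_crop(
      ctx[off + seq_len(window), off + seq_len(window)],
      labels[i], base_id = length(out) + 1L, rotation_deg = 0L,
      bit_depth = micrograph$optics$bit_depth, context = ctx)
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d center(s) within %d px of the frame edge",
                    skipped, chalf))
  }
  out
}

#' Render a set of base crops for one class directly
#'
#' Convenience generator for dataset construction without a whole-frame
#' simulation: renders `n` jittered particles of one class, each with its
#' rotation context.
#'
#' @param class_label Class to render.
#' @param n Number of base crops.
#' @param optics An [optics_config()].
#' @param window Crop side in pixels.
#' @param seed Integer seed; crop i uses a seed derived from `seed` and `i`.
#' @param jitter Relative signature jitter (see [sample_particles()]).
#' @return List of `n` [cell_crop()] with `base_id` 1..n.
#' @export
make_base_crops <- function(class_label, n, optics, window = 66, seed = 1,
                            jitter = 0.1) {
  cw <- context_window(window)
  parts <- sample_particles(class_label, n, jitter = jitter, seed = seed)
  lapply(seq_len(n), function(i) {
    ctx <- render_particle_crop(parts[[i]], optics, window = cw,
                                seed = seed + 13L * i)
    off <- (cw - window) / 2
    cell_crop(ctx[off + seq_len(window), off + seq_len(window)],
              class_label, base_id = i, rotation_deg = 0L,
              bit_depth = optics$bit_depth, context = ctx)
  })
}

# Cached bilinear sampling maps for rotating a context window onto an output
# crop. Keyed by (context side, output side, angle, direction).
.rotation_cache <- new.env(parent = emptyenv())

rotation_map <- function(ctx_n, out_n, angle_deg, clockwise = TRUE) {
  key <- paste(ctx_n, out_n, angle_deg, clockwise, sep = "_")
  cached <- .rotation_cache[[key]]
  if (!is.null(cached)) return(cached)
  th <- angle_deg * pi / 180
  if (clockwise) th <- -th  # image rows grow downward: negate for clockwise
  centre_ctx <- floor(ctx_n / 2)          # particle position in the context
  centre_out <- floor(out_n / 2)
  xo <- as.numeric(outer(rep(1, out_n), seq_len(out_n) - 1)) - centre_out
  yo <- as.numeric(outer(seq_len(out_n) - 1, rep(1, out_n))) - centre_out
  xs <- centre_ctx + cos(th) * xo - sin(th) * yo
  ys <- centre_ctx + sin(th) * xo + cos(th) * yo
  x0 <- pmin(pmax(floor(xs), 0), ctx_n - 2)
  y0 <- pmin(pmax(floor(ys), 0), ctx_n - 2)
  wx <- pmin(pmax(xs - x0, 0), 1)
  wy <- pmin(pmax(ys - y0, 0), 1)
  idx <- function(y, x) y + 1 + x * ctx_n  # column-major linear index
  map <- list(i00 = idx(y0, x0), i10 = idx(y0 + 1, x0),
              i01 = idx(y0, x0 + 1), i11 = idx(y0 + 1, x0 + 1),
              w00 = (1 - wy) * (1 - wx), w10 = wy * (1 - wx),
              w01 = (1 - wy) * wx, w11 = wy * wx)
  .rotation_cache[[key]] <- map
  map
}

#' Rotation augmentation of a crop
#'
#' Produces every rotation of the source crop in steps of `step_deg` degrees
#' (clockwise by default), including the unrotated original. Each rotation is
#' resampled with bilinear interpolation from the crop's oversized context
#' window, so no corner pixel of the output is ever undefined. All outputs
#' share the source's `base_id`.
#'
#' @param crop An unrotated [cell_crop()] carrying a `context`.
#' @param step_deg Angular step; must divide 360.
#' @param clockwise Rotation direction (default `TRUE`, clockwise).
#' @return List of `360 / step_deg` crops with `rotation_deg`
#'   `0, step, 2*step, ...`.
#' @export
augment_rotations <- function(crop, step_deg = 10, clockwise = TRUE) {
  stopifnot(inherits(crop, "cell_crop"))
  if (step_deg <= 0 || 360 %% step_deg != 0) {
    stop("step_deg must be a positive divisor of 360")
  }
  if (crop$rotation_deg != 0) stop("augment_rotations expects an unrotated source crop")
  if (is.null(crop$context)) stop("crop carries no rotation context")
  ctx <- crop$context
  ctx_n <- nrow(ctx)
  out_n <- crop$size
  full <- 2^crop$bit_depth - 1
  angles <- seq(0, 359, by = step_deg)
  lapply(angles, function(a) {
    if (a == 0) {
      px <- crop$pixels
    } else {
      m <- rotation_map(ctx_n, out_n, a, clockwise)
      v <- m$w00 * ctx[m$i00] + m$w10 * ctx[m$i10] +
           m$w01 * ctx[m$i01] + m$w11 * ctx[m$i11]
      px <- matrix(round(pmin(pmax(v, 0), full)), out_n, out_n)
    }
    cell_crop(px, crop$class_label, base_id = crop$base_id,
              rotation_deg = as.integer(a), bit_depth = crop$bit_depth)
  })
}

#' Specification of a train/validation/test split
#'
#' @param n_train,n_val,n_test Per-class fold sizes; they must sum to the
#'   per-class dataset size.
#' @param group_aware If `TRUE` (default) every fold holds whole
#'   augmentation groups (all rotations of a base crop stay together), so no
#'   rotated copy of a training cell can leak into validation or test. If
#'   `FALSE` ("paper-compatible" mode) only the test fold is group-aligned
#'   and the train/validation boundary may cut within a group.
#' @param seed Integer seed for the group shuffle.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(n_train, n_val, n_test, group_aware = TRUE, seed = 1) {
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), group_aware = group_aware,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Leakage-aware dataset splitting
#'
#' Splits a rotation-augmented crop set into train/validation/test folds,
#' per class. Because augmented copies of one cell are near-duplicates,
#' distributing them across folds would leak training information into the
#' test estimate; splitting is therefore organized by `(class_label,
#' base_id)` groups (see [split_spec()] for the two modes).
#'
#' @param crops List of [cell_crop()].
#' @param spec A [split_spec()].
#' @return List with elements `train`, `val`, `test`, each a list of crops.
#' @export
split_dataset <- function(crops, spec) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- vapply(crops, function(cr) cr$class_label, "")
  folds <- list(train = list(), val = list(), test = list())
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    base <- vapply(crops[idx], function(cr) cr$base_id, 0L)
    groups <- split(idx, base)
    gs <- lengths(groups)
    if (length(unique(gs)) != 1) stop("unequal group sizes within class ", cl)
    gs <- gs[[1]]
    n_class <- length(idx)
    if (spec$n_train + spec$n_val + spec$n_test != n_class) {
      stop(sprintf("fold sizes %d+%d+%d do not sum to per-class size %d",
                   spec$n_train, spec$n_val, spec$n_test, n_class))
    }
    ord <- rng_local(spec$seed + utf8ToInt(substr(cl, 1, 1)),
                     sample(seq_along(groups)))
    groups <- groups[ord]
    if (spec$group_aware) {
      if (spec$n_test %% gs != 0 || spec$n_val %% gs != 0) {
        stop(sprintf(
          "group-aware split needs fold sizes in multiples of %d; nearest achievable: %d/%d/%d",
          gs,
          n_class - round(spec$n_val / gs) * gs - round(spec$n_test / gs) * gs,
          round(spec$n_val / gs) * gs, round(spec$n_test / gs) * gs))
      }
      n_test_g <- spec$n_test %/% gs
      n_val_g <- spec$n_val %/% gs
      test_i <- unlist(groups[seq_len(n_test_g)], use.names = FALSE)
      val_i <- unlist(groups[n_test_g + seq_len(n_val_g)], use.names = FALSE)
      rest <- setdiff(seq_along(groups), seq_len(n_test_g + n_val_g))
      train_i <- unlist(groups[rest], use.names = FALSE)
    } else {
      if (spec$n_test %% gs != 0) {
        stop(sprintf("test fold must be whole groups (multiple of %d)", gs))
      }
      n_test_g <- spec$n_test %/% gs
      test_i <- unlist(groups[seq_len(n_test_g)], use.names = FALSE)
      rest <- unlist(groups[-seq_len(n_test_g)], use.names = FALSE)
      train_i <- rest[seq_len(spec$n_train)]
      val_i <- rest[spec$n_train + seq_len(spec$n_val)]
    }
    folds$train <- c(folds$train, crops[train_i])
    folds$val <- c(folds$val, crops[val_i])
    folds$test <- c(folds$test, crops[test_i])
  }
  folds
}

#' Gaussian noise specification
#'
#' Zero-mean additive Gaussian pixel noise on the raw intensity scale (a
#' variance of 100 on an 8-bit image means sigma = 10 gray levels).
#'
#' @param variance Noise variance in squared intensity units (> 0).
#' @param seed Integer seed.
#' @param clip Clip noisy pixels back to the bit-depth range (default TRUE).
#' @return List of class `noise_spec` (mean is fixed at 0).
#' @export
noise_spec <- function(variance, seed = 1, clip = TRUE) {
  if (variance <= 0) stop("variance must be positive")
  structure(list(mean = 0, variance = variance, seed = as.integer(seed),
                 clip = clip),
            class = "noise_spec")
}

#' Corrupt a crop with additive Gaussian noise
#'
#' @param crop A [cell_crop()].
#' @param noise A [noise_spec()].
#' @return New crop with noisy pixels; all metadata (label, base_id,
#'   rotation) unchanged. Deterministic for a fixed seed.
#' @export
add_gaussian_noise <- function(crop, noise) {
  stopifnot(inherits(crop, "cell_crop"), inherits(noise, "noise_spec"))
  n <- length(crop$pixels)
  eps <- rng_local(noise$seed, stats::rnorm(n, 0, sqrt(noise$variance)))
  px <- crop$pixels + matrix(eps, crop$size, crop$size)
  if (noise$clip) px <- pmin(pmax(px, 0), 2^crop$bit_depth - 1)
  out <- crop
  out$pixels <- px
  out$context <- NULL
  out
}

#' Central sub-crop of a crop
#'
#' Extracts the central `size x size` window; when the parities of the two
#' sizes differ the window is offset toward the top-left by half a pixel
#' (floor of the centered start index).
#'
#' @param crop A [cell_crop()].
#' @param size Target side, at most `crop$size`.
#' @return Cropped [cell_crop()] with metadata preserved.
#' @export
center_crop <- function(crop, size) {
  stopifnot(inherits(crop, "cell_crop"))
  if (size > crop$size) stop("size exceeds crop size; cannot center-crop upward")
  if (size == crop$size) return(crop)
  start <- floor((crop$size - size) / 2)
  out <- crop
  out$pixels <- crop$pixels[start + seq_len(size), start + seq_len(size)]
  out$size <- as.integer(size)
  out$context <- crop$context
  out
}

#' Manifest data.frame for a crop list
#'
#' @param crops List of [cell_crop()].
#' @param fold Optional fold name recycled over the crops.
#' @return data.frame (class_label, base_id, rotation_deg, size, fold).
#' @export
crop_manifest <- function(crops, fold = NA_character_) {
  data.frame(
    class_label = vapply(crops, function(cr) cr$class_label, ""),
    base_id = vapply(crops, function(cr) cr$base_id, 0L),
    rotation_deg = vapply(crops, function(cr) cr$rotation_deg, 0L),
    size = vapply(crops, function(cr) cr$size, 0L),
    fold = fold,
    stringsAsFactors = FALSE
  )
}

#' Write split folds to disk as PNG crops plus a manifest CSV
#'
#' Layout: `<dir>/<class>/<class>_<base>_<rot>.png` and `<dir>/manifest.csv`
#' with columns path, class_label, base_id, rotation_deg, fold, size.
#'
#' @param folds List with `train`/`val`/`test` crop lists (or a plain crop
#'   list, written with fold = NA).
#' @param dir Output directory, created if needed.
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(folds, dir) {
  if (inherits(folds[[1]], "cell_crop")) folds <- list(all = folds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (fold in names(folds)) {
    for (cr in folds[[fold]]) {
      cdir <- file.path(dir, cr$class_label)
      dir.create(cdir, showWarnings = FALSE)
      rel <- file.path(cr$class_label,
                       sprintf("%s_%04d_%03d.png", cr$class_label, cr$base_id,
                               cr$rotation_deg))
      write_image(cr, file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        path = rel, class_label = cr$class_label, base_id = cr$base_id,
        rotation_deg = cr$rotation_deg, fold = fold, size = cr$size,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @param bit_depth Intensity scale of the stored crops.
#' @return List with `train`/`val`/`test`/... crop lists keyed by fold.
#' @export
read_dataset <- function(dir, bit_depth = 8) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  folds <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    px <- read_image(file.path(dir, row$path), bit_depth)
    cr <- cell_crop(px, row$class_label, row$base_id, row$rotation_deg,
                    bit_depth)
    folds[[row$fold]] <- c(folds[[row$fold]], list(cr))
  }
  folds
}

#' Flatten crops into a feature matrix
#'
#' @param crops List of same-size [cell_crop()].
#' @param scale Scale pixels to `[0, 1]` by the bit-depth maximum (default
#'   TRUE), the feature scale consumed by the learned denoisers.
#' @return Numeric matrix, one row per crop, `size^2` columns
#'   (column-major pixel order).
#' @export
crops_to_matrix <- function(crops, scale = TRUE) {
  stopifnot(length(crops) > 0)
  d <- crops[[1]]$size
  full <- 2^crops[[1]]$bit_depth - 1
  m <- t(vapply(crops, function(cr) {
    if (cr$size != d) stop("crops differ in size; center_crop them first")
    as.numeric(cr$pixels)
  }, numeric(d * d)))
  if (scale) m <- m / full
  m
}

#' Stack crops into a 4D image array
#'
#' @param crops List of same-size [cell_crop()].
#' @param scale Scale pixels to `[0, 1]` (default TRUE).
#' @return Array of dim `(size, size, 1, n)` for the convolutional models.
#' @export
crops_to_array <- function(crops, scale = TRUE) {
  stopifnot(length(crops) > 0)
  d <- crops[[1]]$size
  full <- 2^crops[[1]]$bit_depth - 1
  a <- array(0, c(d, d, 1L, length(crops)))
  for (i in seq_along(crops)) {
    if (crops[[i]]$size != d) stop("crops differ in size; center_crop them first")
    a[, , 1, i] <- crops[[i]]$pixels
  }
  if (scale) a <- a / full
  a
}

#' Class labels of a crop list
#'
#' @param crops List of [cell_crop()].
#' @return Character vector of labels.
#' @export
crop_labels <- function(crops) vapply(crops, function(cr) cr$class_label, "")
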
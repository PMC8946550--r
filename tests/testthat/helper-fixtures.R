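# Shared, lazily built fixtures. Everything is generated in code from fixed
# seeds; heavyweight objects are memoised so several test files can reuse
# them without re-rendering.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_optics <- function() optics_config()

all_classes <- function() class_signatures()$class_label

# n base crops per class at the given window, center-cropped variants cached.
fx_base_crops <- function(n_per_class, window = 66, seed = 42) {
  key <- sprintf("base_%d_%d_%d", n_per_class, window, seed)
  fx_memo(key, function() {
    out <- list()
    for (ci in seq_along(all_classes())) {
      out[[ci]] <- make_base_crops(all_classes()[ci], n_per_class, fx_optics(),
                                   window = window, seed = seed + 1000L * ci)
    }
    names(out) <- all_classes()
    out
  })
}

# Rotation-augmented 6-class dataset with a group-aware split, used by the
# classifier and transfer suites. 8 base crops/class, 36 rotations each:
# 5 train / 1 val / 2 test groups per class.
fx_class_folds <- function() {
  fx_memo("class_folds", function() {
    crops <- list()
    base <- fx_base_crops(8, window = 66, seed = 2024)
    for (cl in all_classes()) {
      for (b in base[[cl]]) crops <- c(crops, augment_rotations(b, 10))
    }
    split_dataset(crops, split_spec(5 * 36, 1 * 36, 2 * 36,
                                    group_aware = TRUE, seed = 7))
  })
}

# Denoiser training/test material at 50x50 (the size the comparison study
# fixes): clean crops plus seeded mixed-variance noisy counterparts.
fx_denoise_pairs <- function() {
  fx_memo("denoise_pairs", function() {
    base <- fx_base_crops(40, window = 66, seed = 4242)
    clean <- lapply(unlist(base, recursive = FALSE), center_crop, size = 50)
    vars <- rep(seq(100, 600, 100), length.out = length(clean))
    noisy <- mapply(function(cr, v, i)
      add_gaussian_noise(cr, noise_spec(v, seed = 5000L + i)),
      clean, vars, seq_along(clean), SIMPLIFY = FALSE)
    test_base <- fx_base_crops(3, window = 66, seed = 977)
    test <- lapply(unlist(test_base, recursive = FALSE), center_crop, size = 50)
    list(clean = clean, noisy = noisy, test = test)
  })
}

# The trained CNN denoiser shared by the denoising acceptance checks.
fx_cnn_denoiser <- function() {
  fx_memo("cnn_denoiser", function() {
    pairs <- fx_denoise_pairs()
    train_denoiser("cnn", pairs$noisy, pairs$clean,
                   train_config(loss = "mse", epochs = 12, batch_size = 4,
                                learning_rate = 1e-3, lr_decay = 0.93,
                                seed = 11))
  })
}

expect_crop_valid <- function(crop) {
  expect_s3_class(crop, "cell_crop")
  expect_true(all(crop$pixels >= 0 & crop$pixels <= 2^crop$bit_depth - 1))
  expect_equal(nrow(crop$pixels), crop$size)
}
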
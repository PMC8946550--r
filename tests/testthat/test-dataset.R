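# Cropping, rotation augmentation, leakage-aware splitting, noise, sizing.

test_that("crop_patches extracts centered windows and skips edge cases", {
  opt <- fx_optics()
  p <- particle_spec("WBC"); p$center <- c(150, 120)
  frame <- simulate_micrograph(scene_spec(c(256, 300), list(p)), opt)
  crops <- crop_patches(frame, window = 66)
  expect_length(crops, 1)
  expect_identical(dim(crops[[1]]$pixels), c(66L, 66L))
  expect_identical(crops[[1]]$rotation_deg, 0L)
  expect_identical(dim(crops[[1]]$context), c(94L, 94L))
  # a center 10 px from the edge cannot fit the rotation context
  p2 <- particle_spec("WBC"); p2$center <- c(10, 120)
  frame2 <- simulate_micrograph(scene_spec(c(256, 300), list(p, p2)), opt)
  expect_warning(crops2 <- crop_patches(frame2, window = 66), "skipped 1")
  expect_length(crops2, 1)
  expect_length(crop_patches(frame, centers = matrix(numeric(0), 0, 2)), 0)
})

test_that("synthetic crops are shadow-centered: intensity argmin near the crop center", {
  opt <- fx_optics()
  sc <- make_scene(c(400, 420), c(WBC = 3, BEAD20 = 3, HepG2 = 3),
                   min_separation = 80, seed = 21)
  frame <- simulate_micrograph(sc, opt)
  crops <- crop_patches(frame, window = 66)
  expect_length(crops, 9)
  for (cr in crops) {
    # center of the shadow = centroid of squared darkening mass; robust to
    # flat shadow plateaus and annular dark rings, unlike a bare argmin
    contrast <- pmax(round(0.6 * 255) - cr$pixels, 0)^2
    rows <- row(contrast); cols <- col(contrast)
    cen <- c(sum(rows * contrast), sum(cols * contrast)) / sum(contrast)
    # crop center sits at 0-based (33, 33) = 1-based (34, 34)
    expect_lte(sqrt(sum((cen - c(34, 34))^2)), 3)
  }
})

test_that("rotation augmentation yields 360/step crops sharing the base identity", {
  base <- fx_base_crops(2, window = 66, seed = 42)[["MCF7"]]
  aug <- augment_rotations(base[[1]], 10)
  expect_length(aug, 36)
  expect_identical(vapply(aug, function(x) x$rotation_deg, 0L),
                   as.integer(seq(0, 350, 10)))
  expect_true(all(vapply(aug, function(x) x$base_id, 0L) == base[[1]]$base_id))
  expect_identical(aug[[1]]$pixels, base[[1]]$pixels)  # 0 degrees = original
  expect_length(augment_rotations(base[[2]], 90), 4)
  for (a in aug) expect_crop_valid(a)
  expect_error(augment_rotations(base[[1]], 7), "divisor of 360")
})

test_that("rotating a quarter turn four times returns near the original", {
  base <- fx_base_crops(2, window = 66, seed = 42)[["BEAD20"]][[1]]
  r90 <- augment_rotations(base, 90)[[2]]
  # rotating the isotropic-background crop by 90 degrees keeps the center
  expect_identical(r90$pixels[34, 34], base$pixels[34, 34])
  # rotation resamples from the context, so no corner is left undefined
  expect_true(all(r90$pixels >= 0 & r90$pixels <= 255))
})

test_that("group-aware splits never distribute one base crop across folds", {
  crops <- list()
  for (cl in c("RBC", "WBC")) {
    for (b in 1:10) {
      for (r in seq(0, 350, 10)) {
        crops[[length(crops) + 1]] <- cell_crop(matrix(0, 2, 2), cl, b, r)
      }
    }
  }
  folds <- split_dataset(crops, split_spec(7 * 36, 36, 2 * 36,
                                           group_aware = TRUE, seed = 3))
  # brute-force scan: every (class, base_id) group lives in exactly one fold
  key <- function(crs) unique(paste(crop_labels(crs),
                                    vapply(crs, function(x) x$base_id, 0L)))
  ks <- lapply(folds, key)
  expect_length(intersect(ks$train, c(ks$val, ks$test)), 0)
  expect_length(intersect(ks$val, ks$test), 0)
  expect_identical(sort(unname(lengths(folds))),
                   sort(as.integer(c(7 * 36 * 2, 36 * 2, 2 * 36 * 2))))
  # partition property: union of folds is the input, per class
  expect_identical(length(unlist(ks)), 20L)
  expect_error(split_dataset(crops, split_spec(250, 50, 60, TRUE, 1)),
               "multiples of 36")
})

test_that("single-group degenerate split puts everything in train", {
  crops <- lapply(seq(0, 350, 10), function(r) cell_crop(matrix(0, 2, 2), "RBC", 1L, r))
  folds <- split_dataset(crops, split_spec(36, 0, 0, group_aware = TRUE))
  expect_length(folds$train, 36)
  expect_length(folds$val, 0)
  expect_length(folds$test, 0)
})

test_that("Gaussian noise is seeded, metadata-preserving and variance-true", {
  crop <- fx_base_crops(2, window = 66, seed = 42)[["WBC"]][[1]]
  ns <- noise_spec(100, seed = 5)
  n1 <- add_gaussian_noise(crop, ns)
  n2 <- add_gaussian_noise(crop, ns)
  expect_identical(n1$pixels, n2$pixels)
  expect_identical(n1$class_label, crop$class_label)
  expect_identical(n1$base_id, crop$base_id)
  expect_identical(n1$rotation_deg, crop$rotation_deg)
  # moment matching on a constant mid-scale crop without clipping
  const <- cell_crop(matrix(128, 66, 66), "RBC")
  noisy <- add_gaussian_noise(const, noise_spec(100, seed = 9, clip = FALSE))
  v <- var(as.numeric(noisy$pixels - const$pixels))
  expect_lt(abs(v - 100) / 100, 0.1)
  expect_error(noise_spec(0), "variance")
})

test_that("stronger corruption lowers the input SNR", {
  crop <- fx_base_crops(2, window = 66, seed = 42)[["HepG2"]][[1]]
  n100 <- add_gaussian_noise(crop, noise_spec(100, seed = 4))
  n600 <- add_gaussian_noise(crop, noise_spec(600, seed = 4))
  s100 <- snr_improvement(crop$pixels, n100$pixels, n100$pixels)$snr_in
  s600 <- snr_improvement(crop$pixels, n600$pixels, n600$pixels)$snr_in
  expect_lt(s600, s100)
})

test_that("center cropping uses exact index arithmetic", {
  crop <- cell_crop(matrix(seq_len(66^2), 66), "RBC")
  cc <- center_crop(crop, 50)
  expect_identical(cc$pixels, crop$pixels[9:58, 9:58])  # 0-based [8, 58)
  expect_identical(cc$size, 50L)
  expect_identical(center_crop(crop, 66), crop)
  # the center pixel value survives any supported target size
  for (s in c(60, 56, 50, 46, 40, 36)) {
    expect_identical(center_crop(crop, s)$pixels[s %/% 2 + 1, s %/% 2 + 1],
                     crop$pixels[34, 34])
  }
  expect_error(center_crop(crop, 70), "exceeds")
})

test_that("datasets round-trip through the on-disk PNG + manifest layout", {
  base <- fx_base_crops(2, window = 66, seed = 42)
  crops <- c(augment_rotations(base[["RBC"]][[1]], 90),
             augment_rotations(base[["WBC"]][[1]], 90))
  folds <- list(train = crops[c(1:3, 5:7)], test = crops[c(4, 8)])
  dir <- file.path(tempdir(), "ds_roundtrip")
  manifest <- write_dataset(folds, dir)
  expect_identical(nrow(manifest), 8L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_length(back$train, 6)
  expect_length(back$test, 2)
  expect_identical(back$test[[1]]$pixels,
                   unname(folds$test[[1]]$pixels))
  expect_identical(sort(unique(crop_manifest(back$train)$class_label)),
                   c("RBC", "WBC"))
})

test_that("feature matrices and arrays are consistent views of the same crops", {
  base <- fx_base_crops(2, window = 66, seed = 42)[["BEAD10"]]
  crops <- lapply(base, center_crop, size = 36)
  m <- crops_to_matrix(crops)
  a <- crops_to_array(crops)
  expect_identical(dim(m), c(2L, 36L * 36L))
  expect_identical(dim(a), c(36L, 36L, 1L, 2L))
  expect_identical(as.numeric(m[1, ]), as.numeric(a[, , 1, 1]))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(crops_to_matrix(list(crops[[1]], center_crop(crops[[2]], 20))),
               "differ in size")
})
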
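# Angular-spectrum propagation, particle rendering and frame simulation.

test_that("zero-distance propagation is the identity map", {
  opt <- fx_optics()
  set.seed(1)
  f <- matrix(complex(real = rnorm(16^2), imaginary = rnorm(16^2)), 16)
  expect_identical(propagate_angular_spectrum(f, opt, z = 0), f + 0i)
})

test_that("propagation conserves field energy (Parseval)", {
  opt <- fx_optics()
  set.seed(2)
  for (i in 1:3) {
    f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
    u <- propagate_angular_spectrum(f, opt, z = 300e-6)
    e_in <- sum(Mod(f)^2)
    e_out <- sum(Mod(u)^2)
    expect_lt(abs(e_out - e_in) / e_in, 1e-6)
  }
})

test_that("first bright ring radius grows monotonically with distance", {
  p <- particle_spec("BEAD10", opacity = 1)
  ring_radius <- function(z) {
    crop <- render_particle_crop(p, optics_config(z_distance = z),
                                 window = 66, seed = 1)
    prof <- radial_profile(crop)
    # first bright ring: radial argmax beyond the geometric shadow
    shadow_px <- ceiling(p$diameter / 2 / 2.2e-6)
    which.max(prof[(shadow_px + 1):length(prof)]) + shadow_px
  }
  radii <- vapply(c(100e-6, 200e-6, 400e-6), ring_radius, 0)
  expect_true(all(diff(radii) > 0))
})

test_that("invalid optics parameters are rejected", {
  expect_error(optics_config(pixel_pitch = 0), "pixel_pitch")
  expect_error(optics_config(wavelength = -1), "wavelength")
  expect_error(optics_config(bit_depth = 12), "bit_depth")
  expect_error(particle_spec("RBC", opacity = 1.2), "opacity")
  expect_error(particle_spec("NOPE"), "unknown class")
})

test_that("rendering is deterministic and quantized to the bit depth", {
  opt <- fx_optics()
  p <- particle_spec("WBC")
  a <- render_particle_crop(p, opt, window = 66, seed = 7)
  b <- render_particle_crop(p, opt, window = 66, seed = 7)
  expect_identical(a, b)
  expect_true(all(a == round(a)))
  expect_true(all(a >= 0 & a <= 255))
  c2 <- render_particle_crop(p, opt, window = 66, seed = 8)
  expect_false(identical(a, c2))
})

test_that("a fully transparent particle renders a uniform background", {
  opt <- fx_optics()
  p <- particle_spec("RBC", opacity = 0, phase_shift = 0)
  crop <- render_particle_crop(p, opt, window = 66, seed = 1)
  expect_identical(length(unique(as.numeric(crop))), 1L)
  expect_equal(crop[1, 1], round(0.6 * 255))
})

test_that("a too-small window warns but still renders", {
  opt <- fx_optics()
  expect_warning(crop <- render_particle_crop(particle_spec("BEAD20"), opt,
                                              window = 12, seed = 1),
                 "ring extent")
  expect_identical(dim(crop), c(12L, 12L))
})

test_that("the 20 um bead casts a larger central shadow than the 10 um bead", {
  opt <- fx_optics()
  shadow_area <- function(class) {
    crop <- render_particle_crop(particle_spec(class), opt, window = 66, seed = 3)
    contrast <- pmax(0.6 * 255 - crop, 0)       # darkening below background
    sum(contrast > max(contrast) / 2)
  }
  expect_gt(shadow_area("BEAD20"), shadow_area("BEAD10"))
})

test_that("a frame-sized scene carries one truth row per requested particle", {
  opt <- fx_optics()
  counts <- c(RBC = 84, WBC = 84, MCF7 = 83, HepG2 = 83, BEAD10 = 83,
              BEAD20 = 83)  # ~500 patterns in one sensor frame
  scene <- make_scene(c(1920, 2560), counts, min_separation = 40, seed = 5)
  frame <- simulate_micrograph(scene, opt)
  expect_identical(nrow(frame$truth), 500L)
  expect_identical(dim(frame$intensity), c(1920L, 2560L))
  expect_true(all(frame$intensity >= 0 & frame$intensity <= 255))
  expect_identical(unname(table(frame$truth$class_label)["RBC"]), 84L)
})

test_that("an empty scene yields a flat background frame", {
  opt <- fx_optics()
  frame <- simulate_micrograph(scene_spec(c(64, 64), list()), opt)
  expect_identical(nrow(frame$truth), 0L)
  expect_identical(length(unique(as.numeric(frame$intensity))), 1L)
})

test_that("simulation is deterministic for a fixed scene seed", {
  opt <- fx_optics()
  sc1 <- make_scene(c(256, 256), c(RBC = 3, BEAD20 = 3), seed = 9)
  sc2 <- make_scene(c(256, 256), c(RBC = 3, BEAD20 = 3), seed = 9)
  expect_identical(simulate_micrograph(sc1, opt)$intensity,
                   simulate_micrograph(sc2, opt)$intensity)
})

test_that("far-apart particles superpose locally: adding one leaves the other's crop unchanged", {
  opt <- fx_optics()
  p1 <- particle_spec("WBC"); p1$center <- c(100, 100)
  p2 <- particle_spec("BEAD20"); p2$center <- c(400, 380)
  lone <- simulate_micrograph(scene_spec(c(480, 512), list(p1)), opt)
  both <- simulate_micrograph(scene_spec(c(480, 512), list(p1, p2)), opt)
  rows <- 101 + (-30:30); cols <- 101 + (-30:30)   # 1-based window around p1
  expect_lte(max(abs(lone$intensity[rows, cols] - both$intensity[rows, cols])), 1)
})

test_that("the six class signatures are linearly separable from radial profiles", {
  skip_if_not_installed("MASS")
  base <- fx_base_crops(20, window = 66, seed = 42)
  feats <- do.call(rbind, lapply(unlist(base, recursive = FALSE), function(cr) {
    radial_profile(cr$pixels)[1:16]
  }))
  labels <- factor(rep(all_classes(), each = 20))
  fit <- MASS::lda(feats, grouping = labels, CV = TRUE)  # leave-one-out
  expect_gt(mean(fit$class == labels), 0.8)
})

test_that("images and truth tables round-trip through disk", {
  opt <- fx_optics()
  crop <- render_particle_crop(particle_spec("HepG2"), opt, window = 40, seed = 2)
  png_path <- tempfile(fileext = ".png")
  tif_path <- tempfile(fileext = ".tiff")
  write_image(crop, png_path)
  write_image(crop, tif_path)
  expect_identical(read_image(png_path), unname(crop))
  expect_identical(read_image(tif_path), unname(crop))
  sc <- make_scene(c(256, 256), c(RBC = 2), seed = 1)
  frame <- simulate_micrograph(sc, opt)
  csv <- tempfile(fileext = ".csv")
  write_truth_csv(frame, csv)
  back <- read.csv(csv)
  expect_equal(back$x, frame$truth$x, tolerance = 1e-9)
  expect_identical(back$class_label, frame$truth$class_label)
})

test_that("placement respects separation and fails gracefully when impossible", {
  parts <- sample_particles("RBC", 30, seed = 1)
  expect_error(place_particles(parts, c(128, 128), min_separation = 60,
                               margin = 20, seed = 1, max_attempts = 50),
               "could not place")
  sc <- make_scene(c(400, 400), c(RBC = 10), min_separation = 50, seed = 3)
  centers <- t(vapply(sc$particles, function(p) p$center, c(0, 0)))
  dists <- as.matrix(dist(centers))
  diag(dists) <- Inf
  expect_gte(min(dists), 50)
})
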
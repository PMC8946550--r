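#' Optics configuration for a lens-free shadow imaging setup
#'
#' Describes the imaging geometry of an inline (lens-free) holographic
#' cytometer: a semi-coherent source illuminates particles held a few hundred
#' micrometers above a bare image sensor, which records their diffraction
#' ("shadow") patterns.
#'
#' @param wavelength Peak illumination wavelength in meters (default 470 nm,
#'   a blue LED).
#' @param z_distance Sample-to-sensor distance in meters (default 300 um).
#' @param pixel_pitch Sensor pixel pitch in meters (default 2.2 um, typical
#'   of 5-megapixel CMOS sensors).
#' @param bit_depth Intensity quantization depth, 8 or 16.
#' @param illumination_sigma Partial-coherence blur scale in pixels: the
#'   intensity pattern is blurred by a Gaussian of this sigma to emulate the
#'   finite spatial coherence of a pinhole-conjugated LED.
#' @return List of class `optics_config`.
#' @export
optics_config <- function(wavelength = 470e-9, z_distance = 300e-6,
                          pixel_pitch = 2.2e-6, bit_depth = 8,
                          illumination_sigma = 1) {
  if (wavelength <= 0) stop("wavelength must be positive")
  if (z_distance < 0) stop("z_distance must be non-negative")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (illumination_sigma < 0) stop("illumination_sigma must be non-negative")
  structure(list(wavelength = wavelength, z_distance = z_distance,
                 pixel_pitch = pixel_pitch, bit_depth = as.integer(bit_depth),
                 illumination_sigma = illumination_sigma),
            class = "optics_config")
}

#' Default optical signatures of the six supported particle classes
#'
#' Diameter, opacity (absorbed amplitude fraction) and phase retardation used
#' to render class-distinctive diffraction signatures: red and white blood
#' cells, MCF7 and HepG2 cancer cell lines, and 10/20 um polystyrene
#' calibration beads. The values are package choices tuned for clearly
#' distinct radial ring profiles, not measured optical constants; per-particle
#' jitter is added by [sample_particles()].
#'
#' @return data.frame with columns class_label, diameter (m), opacity,
#'   phase_shift (rad).
#' @export
class_signatures <- function() {
  data.frame(
    class_label = c("RBC", "WBC", "MCF7", "HepG2", "BEAD10", "BEAD20"),
    diameter = c(7e-6, 10e-6, 18e-6, 16e-6, 10e-6, 20e-6),
    opacity = c(0.6, 0.5, 0.5, 0.7, 0.9, 0.9),
    phase_shift = c(1.0, 1.5, 2.0, 1.2, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' A single particle to be rendered
#'
#' @param class_label One of the labels in [class_signatures()].
#' @param diameter Particle diameter in meters; defaults to the class value.
#' @param opacity Fraction of the amplitude absorbed inside the particle,
#'   in \[0, 1\].
#' @param phase_shift Phase retardation in radians imposed by the particle.
#' @param center Optional `(x, y)` position in pixels (0-based, sub-pixel
#'   allowed) within a frame.
#' @return List of class `particle_spec`.
#' @export
particle_spec <- function(class_label, diameter = NULL, opacity = NULL,
                          phase_shift = NULL, center = NULL) {
  sig <- class_signatures()
  if (!class_label %in% sig$class_label) {
    stop("unknown class_label: ", class_label)
  }
  row <- sig[sig$class_label == class_label, ]
  diameter <- if (is.null(diameter)) row$diameter else diameter
  opacity <- if (is.null(opacity)) row$opacity else opacity
  phase_shift <- if (is.null(phase_shift)) row$phase_shift else phase_shift
  if (diameter <= 0) stop("diameter must be positive")
  if (opacity < 0 || opacity > 1) stop("opacity must be in [0, 1]")
  structure(list(class_label = class_label, diameter = diameter,
                 opacity = opacity, phase_shift = phase_shift, center = center),
            class = "particle_spec")
}

#' Sample jittered particles of one class
#'
#' Draws `n` particles whose diameter, opacity and phase are the class
#' defaults perturbed by independent uniform relative jitter, emulating
#' natural cell-to-cell variability.
#'
#' @param class_label Class to sample.
#' @param n Number of particles.
#' @param jitter Relative half-width of the uniform perturbation (default
#'   0.1, i.e. +/-10%).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return List of [particle_spec()] objects.
#' @export
sample_particles <- function(class_label, n, jitter = 0.1, seed = 1) {
  base <- particle_spec(class_label)
  rng_local(seed, {
    lapply(seq_len(n), function(i) {
      j <- stats::runif(3, 1 - jitter, 1 + jitter)
      particle_spec(class_label,
                    diameter = base$diameter * j[1],
                    opacity = min(1, base$opacity * j[2]),
                    phase_shift = base$phase_shift * j[3])
    })
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# FFT sample frequencies (cycles per unit), length n, sample spacing d.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

#' Angular-spectrum propagation of a complex optical field
#'
#' Propagates a monochromatic scalar field over a distance `z` using the
#' angular-spectrum method: the field is decomposed into plane waves by FFT,
#' each component is advanced by its exact propagation phase
#' \eqn{\exp(i 2 \pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2})}, and evanescent
#' components (spatial frequencies beyond \eqn{1/\lambda}) are zeroed. This is
#' the forward model that turns a particle's transmission function into the
#' diffraction pattern recorded by the sensor.
#'
#' Propagating components have unit-modulus transfer factors, so total energy
#' is conserved whenever no evanescent content is present (always true at
#' sensor pixel pitches much larger than the wavelength). `z = 0` returns the
#' input unchanged, bit-exactly.
#'
#' @param field Complex (or numeric) matrix: the field in the source plane.
#' @param optics An [optics_config()] (wavelength and pixel pitch are used).
#' @param z Propagation distance in meters; defaults to `optics$z_distance`.
#' @return Complex matrix of the propagated field.
#' @export
propagate_angular_spectrum <- function(field, optics, z = optics$z_distance) {
  stopifnot(inherits(optics, "optics_config"))
  if (z < 0) stop("z must be non-negative")
  field <- as.matrix(field)
  if (z == 0) return(field + 0i)
  nr <- nrow(field); nc <- ncol(field)
  fx <- fft_freq(nr, optics$pixel_pitch)
  fy <- fft_freq(nc, optics$pixel_pitch)
  f2 <- outer(fx^2, fy^2, `+`)
  arg <- 1 / optics$wavelength^2 - f2
  h <- matrix(0+0i, nr, nc)
  prop <- arg >= 0
  h[prop] <- exp(2i * pi * z * sqrt(arg[prop]))
  stats::fft(stats::fft(field) * h, inverse = TRUE) / (nr * nc)
}

# Gaussian blur of a real image via its Fourier transform (periodic border);
# sigma in pixels. Used to emulate partial spatial coherence.
fourier_gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fx <- fft_freq(nr); fy <- fft_freq(nc)
  g <- exp(-2 * pi^2 * sigma^2 * outer(fx^2, fy^2, `+`))
  Re(stats::fft(stats::fft(img) * g, inverse = TRUE)) / (nr * nc)
}

# Complex transmission of an anti-aliased disk particle on a pixel grid.
# cx, cy are 0-based pixel coordinates of the disk center within the grid.
disk_transmission <- function(nrow_, ncol_, cx, cy, radius_px, opacity, phase) {
  x <- outer(rep(1, nrow_), seq_len(ncol_) - 1)
  y <- outer(seq_len(nrow_) - 1, rep(1, ncol_))
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  cov <- pmin(pmax(radius_px - r + 0.5, 0), 1)  # 1 px anti-aliased edge
  inside <- (1 - opacity) * exp(1i * phase)
  (1 - cov) + cov * inside
}

# Background-normalized, quantized 8/16-bit intensity from a raw |field|^2
# image. Background (unit plane wave) maps to 60% of full scale, leaving
# headroom for the bright diffraction rings.
quantize_intensity <- function(intensity, optics, background = 1) {
  full <- 2^optics$bit_depth - 1
  scaled <- intensity / background * 0.6 * full
  round(pmin(pmax(scaled, 0), full))
}

#' Render a single-particle diffraction crop
#'
#' Places one particle at the center of an oversized grid, propagates the
#' field to the sensor plane, applies the partial-coherence blur, and returns
#' the quantized intensity crop. A sub-pixel center offset drawn from `seed`
#' emulates the arbitrary sampling phase of real cells relative to the pixel
#' grid, so different seeds give slightly different (but same-class) crops.
#'
#' @param particle A [particle_spec()].
#' @param optics An [optics_config()].
#' @param window Crop side in pixels. A warning is issued (and the render
#'   still returned) if the window cannot contain the first diffraction ring.
#' @param seed Integer seed for the sub-pixel offset; the render is
#'   deterministic given (`particle`, `optics`, `window`, `seed`).
#' @return Numeric matrix `window x window` of quantized intensities; the
#'   particle center is at 0-based position (`floor(window/2)`,
#'   `floor(window/2)`) up to the sub-pixel offset.
#' @export
render_particle_crop <- function(particle, optics, window = 66, seed = 1) {
  stopifnot(inherits(particle, "particle_spec"), inherits(optics, "optics_config"))
  # first-ring extent ~ sqrt(lambda z); require window to span twice that
  ring_px <- sqrt(optics$wavelength * max(optics$z_distance, 1e-12)) / optics$pixel_pitch
  extent_px <- particle$diameter / 2 / optics$pixel_pitch + ring_px
  if (window < 2 * extent_px) {
    warning(sprintf("window %d px smaller than twice the expected ring extent (%.1f px)",
                    window, extent_px))
  }
  n <- 2^ceiling(log2(max(2 * window, 128)))
  off <- rng_local(seed, stats::runif(2, -0.5, 0.5))
  gc <- floor(n / 2)
  t_field <- disk_transmission(n, n, gc + off[1], gc + off[2],
                               particle$diameter / 2 / optics$pixel_pitch,
                               particle$opacity, particle$phase_shift)
  u <- propagate_angular_spectrum(t_field, optics)
  intensity <- fourier_gaussian_blur(Mod(u)^2, optics$illumination_sigma)
  half <- floor(window / 2)
  rows <- (gc - half):(gc - half + window - 1) + 1
  quantize_intensity(intensity[rows, rows], optics)
}

#' Scene description for a whole-frame simulation
#'
#' @param frame_shape `(rows, cols)` of the sensor frame in pixels.
#' @param particles List of [particle_spec()] objects, each with a `center`
#'   set (see [place_particles()]), or without centers if placement is left
#'   to [place_particles()].
#' @param min_separation Minimum pairwise center distance in pixels.
#' @param seed Integer seed governing all randomness in the scene.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(frame_shape, particles, min_separation = 40, seed = 1) {
  structure(list(frame_shape = as.integer(frame_shape), particles = particles,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Place particles at random non-overlapping positions
#'
#' Rejection-samples particle centers inside the frame, keeping every pair at
#' least `min_separation` pixels apart and every center at least `margin`
#' pixels from the frame edge (so crops and their rotation context fit).
#'
#' @param particles List of [particle_spec()] without centers.
#' @param frame_shape `(rows, cols)` in pixels.
#' @param min_separation Minimum pairwise distance in pixels.
#' @param margin Edge margin in pixels.
#' @param seed Integer seed.
#' @param max_attempts Rejection attempts per particle before giving up.
#' @return [scene_spec()] with all centers set.
#' @export
place_particles <- function(particles, frame_shape, min_separation = 40,
                            margin = 48, seed = 1, max_attempts = 2000) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  centers <- matrix(NA_real_, length(particles), 2)
  rng_local(seed, {
    for (i in seq_along(particles)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- c(stats::runif(1, margin, nc - 1 - margin),
                  stats::runif(1, margin, nr - 1 - margin))  # (x, y)
        if (i == 1 || all(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2)) >= min_separation)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place particle %d of %d at min_separation %.0f px (placed %d)",
                     i, length(particles), min_separation, i - 1))
      }
    }
  })
  for (i in seq_along(particles)) particles[[i]]$center <- centers[i, ]
  scene_spec(frame_shape, particles, min_separation, seed)
}

#' Build a random scene with given per-class particle counts
#'
#' Convenience wrapper: samples jittered particles per class and places them.
#'
#' @param frame_shape `(rows, cols)` in pixels.
#' @param counts Named integer vector of particles per class label.
#' @param min_separation,margin,seed See [place_particles()].
#' @param jitter Relative signature jitter, see [sample_particles()].
#' @return A [scene_spec()].
#' @export
make_scene <- function(frame_shape, counts, min_separation = 40, margin = 48,
                       seed = 1, jitter = 0.1) {
  parts <- list()
  for (i in seq_along(counts)) {
    cl <- names(counts)[i]
    parts <- c(parts, sample_particles(cl, counts[[i]], jitter = jitter,
                                       seed = seed + 1000L * i))
  }
  rng_local(seed + 7L, parts <- sample(parts))
  place_particles(parts, frame_shape, min_separation, margin, seed)
}

#' Simulate a whole-frame lens-free micrograph
#'
#' Builds the complex transmission of the whole scene (particles are
#' non-overlapping by construction, so transmissions multiply), propagates the
#' field coherently to the sensor plane in one step, records the intensity,
#' applies the partial-coherence blur, and quantizes to the configured bit
#' depth. A typical sensor frame holds several hundred diffraction patterns.
#'
#' @param scene A [scene_spec()] with all particle centers set.
#' @param optics An [optics_config()].
#' @return List of class `micrograph`: `intensity` (rows x cols matrix),
#'   `optics`, and `truth` data.frame (x, y, class_label, diameter_um), one
#'   row per particle.
#' @export
simulate_micrograph <- function(scene, optics) {
  stopifnot(inherits(scene, "scene_spec"), inherits(optics, "optics_config"))
  nr <- scene$frame_shape[1]; nc <- scene$frame_shape[2]
  t_field <- matrix(1 + 0i, nr, nc)
  for (p in scene$particles) {
    if (is.null(p$center)) stop("all particles need centers; use place_particles()")
    cx <- p$center[1]; cy <- p$center[2]
    if (cx < 0 || cx > nc - 1 || cy < 0 || cy > nr - 1) {
      stop("particle center outside frame")
    }
    r_px <- p$diameter / 2 / optics$pixel_pitch
    ext <- ceiling(r_px) + 2
    rows <- max(1, floor(cy) - ext + 1):min(nr, ceiling(cy) + ext + 1)
    cols <- max(1, floor(cx) - ext + 1):min(nc, ceiling(cx) + ext + 1)
    local_t <- disk_transmission(length(rows), length(cols),
                                 cx - (cols[1] - 1), cy - (rows[1] - 1),
                                 r_px, p$opacity, p$phase_shift)
    t_field[rows, cols] <- t_field[rows, cols] * local_t
  }
  u <- propagate_angular_spectrum(t_field, optics)
  intensity <- fourier_gaussian_blur(Mod(u)^2, optics$illumination_sigma)
  truth <- if (length(scene$particles)) {
    data.frame(
      x = vapply(scene$particles, function(p) p$center[1], 0),
      y = vapply(scene$particles, function(p) p$center[2], 0),
      class_label = vapply(scene$particles, function(p) p$class_label, ""),
      diameter_um = vapply(scene$particles, function(p) p$diameter * 1e6, 0),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(x = numeric(0), y = numeric(0), class_label = character(0),
               diameter_um = numeric(0))
  }
  structure(list(intensity = quantize_intensity(intensity, optics),
                 optics = optics, truth = truth),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph %d x %d px, %d particles, %d-bit\n",
              nrow(x$intensity), ncol(x$intensity), nrow(x$truth),
              x$optics$bit_depth))
  invisible(x)
}

#' Mean radial intensity profile of a crop
#'
#' Averages intensity over annuli of 1-pixel width around a center, the basic
#' rotation-invariant summary of a concentric-ring diffraction signature.
#'
#' @param img Numeric matrix.
#' @param center 0-based `(x, y)` center; defaults to the crop center pixel
#'   `floor(dim/2)`.
#' @param n_bins Number of radial bins; defaults to `floor(min(dim)/2)`.
#' @return Numeric vector of mean intensity per radius bin (bin k covers
#'   radii `[k-1, k)` pixels).
#' @export
radial_profile <- function(img, center = NULL, n_bins = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(center)) center <- c(floor(nc / 2), floor(nr / 2))
  if (is.null(n_bins)) n_bins <- floor(min(nr, nc) / 2)
  x <- outer(rep(1, nr), seq_len(nc) - 1)
  y <- outer(seq_len(nr) - 1, rep(1, nc))
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  bin <- pmin(n_bins, floor(r) + 1)
  as.numeric(tapply(as.numeric(img), bin, mean))[seq_len(n_bins)]
}

#' Write a micrograph or crop as an 8-bit grayscale image
#'
#' @param img A `micrograph`, `cell_crop`, or numeric matrix on the
#'   quantized intensity scale.
#' @param path Output path ending in .png or .tif/.tiff.
#' @param bit_depth Scale of `img` when it is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8) {
  if (inherits(img, "micrograph")) {
    bit_depth <- img$optics$bit_depth
    img <- img$intensity
  } else if (inherits(img, "cell_crop")) {
    bit_depth <- img$bit_depth
    img <- img$pixels
  }
  norm <- pmin(pmax(img / (2^bit_depth - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read an 8-bit grayscale image back onto the intensity scale
#'
#' @param path .png or .tif/.tiff file.
#' @param bit_depth Target intensity scale.
#' @return Numeric matrix on `[0, 2^bit_depth - 1]`.
#' @export
read_image <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * (2^bit_depth - 1))
}

#' Write the ground-truth particle table of a synthetic micrograph
#'
#' @param micrograph A `micrograph`.
#' @param path CSV output path; columns x, y, class_label, diameter_um.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(micrograph, path) {
  utils::write.csv(micrograph$truth, path, row.names = FALSE)
  invisible(path)
}
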
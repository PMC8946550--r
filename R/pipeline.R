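#' Default end-to-end run configuration
#'
#' Returns the full nested configuration consumed by [run_pipeline()], with
#' every section at its package default. Any subset of fields can be
#' overridden via `modifyList()` semantics by passing a partial list (or a
#' YAML file) to [run_pipeline()].
#'
#' Sections: `optics` (see [optics_config()]), `scene` (frame shape and
#' per-class particle counts), `dataset` (crop window, rotation step, base
#' crops per class, split mode), `denoise` (architecture and training
#' budget), `classify` (depth, input size, epochs), `transfer` (held-out
#' class and retraining budget), plus the global `seed`.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    optics = list(wavelength = 470e-9, z_distance = 300e-6,
                  pixel_pitch = 2.2e-6, bit_depth = 8, illumination_sigma = 1),
    scene = list(frame_shape = c(480, 640),
                 counts = list(RBC = 8, WBC = 8, MCF7 = 8, HepG2 = 8,
                               BEAD10 = 8, BEAD20 = 8),
                 min_separation = 40, margin = 48),
    dataset = list(window = 66, step_deg = 10, base_per_class = 10,
                   split = "group", train_groups = 7, val_groups = 1,
                   test_groups = 2, jitter = 0.1),
    denoise = list(arch = "cnn", variances = seq(100, 600, 100),
                   epochs = 8, batch_size = 16, learning_rate = 1e-3,
                   pairs_per_class = 15, size = 50, test_per_class = 3),
    classify = list(depth = "shallow", input_size = 50, epochs = 10,
                    batch_size = 32, learning_rate = 1e-3),
    transfer = list(new_class = "RBC", epochs = 10, mix = 0.5),
    log_level = "INFO"
  )
}

# Merge a partial config (list or YAML file path) over the defaults.
resolve_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(base, config)
  # the per-class count map is one unit: replace it, never merge class-wise
  if (!is.null(config$scene$counts)) cfg$scene$counts <- config$scene$counts
  cfg
}

# Stable hash of a configuration (md5 of its canonical YAML rendering).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

pipe_log <- function(run_dir, level, stage, msg) {
  line <- sprintf("%s [%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  level, stage, msg)
  cat(line, "\n")
  cat(line, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

stage_done <- function(run_dir, stage) {
  file.exists(file.path(run_dir, stage, ".done"))
}

mark_done <- function(run_dir, stage) {
  writeLines(format(Sys.time()), file.path(run_dir, stage, ".done"))
}

# Build the rotation-augmented, split dataset the later stages consume.
build_dataset_folds <- function(cfg, optics) {
  ds <- cfg$dataset
  classes <- names(cfg$scene$counts)
  crops <- list()
  for (ci in seq_along(classes)) {
    base <- make_base_crops(classes[ci], ds$base_per_class, optics,
                            window = ds$window,
                            seed = cfg$seed + 101L * ci, jitter = ds$jitter)
    for (b in base) crops <- c(crops, augment_rotations(b, ds$step_deg))
  }
  gs <- 360 %/% ds$step_deg
  spec <- split_spec(ds$train_groups * gs, ds$val_groups * gs,
                     ds$test_groups * gs,
                     group_aware = identical(ds$split, "group"),
                     seed = cfg$seed + 17L)
  split_dataset(crops, spec)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full study on synthetic data: frame simulation, dataset
#' construction (crop, rotate, split), denoiser training and benchmarking
#' against the classical filters, classifier training and evaluation,
#' last-layer transfer learning, and a final count-comparison report. Stage
#' outputs are written under `runs/<config-hash>/<stage>/`; a completed
#' stage (marker file present) is skipped on re-run, so the run directory is
#' content-addressed by its configuration. All stage seeds derive from the
#' single global `seed`.
#'
#' @param config Partial configuration list or YAML file path (merged over
#'   [default_run_config()]).
#' @param stages Subset of `c("simulate", "dataset", "denoise", "classify",
#'   "transfer", "report")`; dependencies must already have run (or be
#'   included).
#' @param out_root Directory under which run directories are created.
#' @return Invisibly, a list with `run_dir`, `config`, `hash`, and a
#'   `summary` list of the key numbers each executed stage produced.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "dataset", "denoise",
                                    "classify", "transfer", "report"),
                         out_root = "runs") {
  cfg <- resolve_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  hash <- config_hash(cfg)
  run_dir <- file.path(out_root, hash)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  optics <- do.call(optics_config, cfg$optics)
  summary <- list()
  t_all <- Sys.time()

  need <- function(stage, dep) {
    if (!stage_done(run_dir, dep)) {
      stop(sprintf("stage '%s' requires completed stage '%s'; include it in `stages`",
                   stage, dep))
    }
  }
  folds_cache <- NULL
  load_folds <- function() {
    if (is.null(folds_cache)) {
      folds_cache <<- read_dataset(file.path(run_dir, "dataset"),
                                   bit_depth = optics$bit_depth)
    }
    folds_cache
  }

  if ("simulate" %in% stages && !stage_done(run_dir, "simulate")) {
    sdir <- file.path(run_dir, "simulate")
    dir.create(sdir, showWarnings = FALSE)
    t0 <- Sys.time()
    counts <- unlist(cfg$scene$counts)
    scene <- make_scene(cfg$scene$frame_shape, counts,
                        min_separation = cfg$scene$min_separation,
                        margin = cfg$scene$margin, seed = cfg$seed,
                        jitter = cfg$dataset$jitter)
    frame <- simulate_micrograph(scene, optics)
    write_image(frame, file.path(sdir, "frame.png"))
    write_truth_csv(frame, file.path(sdir, "truth.csv"))
    summary$simulate <- list(n_particles = nrow(frame$truth))
    mark_done(run_dir, "simulate")
    pipe_log(run_dir, "INFO", "simulate",
             sprintf("%d particles in %.1fs", nrow(frame$truth),
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("dataset" %in% stages && !stage_done(run_dir, "dataset")) {
    ddir <- file.path(run_dir, "dataset")
    dir.create(ddir, showWarnings = FALSE)
    t0 <- Sys.time()
    folds <- build_dataset_folds(cfg, optics)
    manifest <- write_dataset(folds, ddir)
    folds_cache <- folds
    summary$dataset <- list(n_train = length(folds$train),
                            n_val = length(folds$val),
                            n_test = length(folds$test))
    mark_done(run_dir, "dataset")
    pipe_log(run_dir, "INFO", "dataset",
             sprintf("%d crops (%d/%d/%d) in %.1fs", nrow(manifest),
                     length(folds$train), length(folds$val),
                     length(folds$test),
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("denoise" %in% stages && !stage_done(run_dir, "denoise")) {
    need("denoise", "dataset")
    ndir <- file.path(run_dir, "denoise")
    dir.create(ndir, showWarnings = FALSE)
    t0 <- Sys.time()
    dn <- cfg$denoise
    folds <- load_folds()
    by_class <- split(folds$train, crop_labels(folds$train))
    clean <- unlist(lapply(by_class, function(crops) {
      crops[seq_len(min(dn$pairs_per_class, length(crops)))]
    }), recursive = FALSE)
    clean <- lapply(clean, center_crop, size = dn$size)
    vars <- rep(dn$variances, length.out = length(clean))
    noisy <- mapply(function(cr, v, i)
      add_gaussian_noise(cr, noise_spec(v, seed = cfg$seed + 31L * i)),
      clean, vars, seq_along(clean), SIMPLIFY = FALSE)
    den <- train_denoiser(dn$arch, noisy, clean,
                          train_config(loss = "mse", epochs = dn$epochs,
                                       batch_size = dn$batch_size,
                                       learning_rate = dn$learning_rate,
                                       seed = cfg$seed + 41L))
    test_by_class <- split(folds$test, crop_labels(folds$test))
    test <- lapply(unlist(lapply(test_by_class, function(crops) {
      crops[seq_len(min(dn$test_per_class, length(crops)))]
    }), recursive = FALSE), center_crop, size = dn$size)
    methods <- c(baseline_methods(),
                 stats::setNames(list(function(cr, v) denoise(den, cr)), dn$arch))
    bench <- snr_benchmark(test, methods, variances = dn$variances,
                           seed = cfg$seed + 43L)
    utils::write.csv(bench, file.path(ndir, "snr_benchmark.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(step = seq_along(den$loss_trace),
                                loss = den$loss_trace),
                     file.path(ndir, "loss_trace.csv"), row.names = FALSE)
    summary$denoise <- list(mean_snr_imp = mean(bench[[dn$arch]]),
                            benchmark = bench)
    mark_done(run_dir, "denoise")
    pipe_log(run_dir, "INFO", "denoise",
             sprintf("%s mean SNR_imp %.2f dB in %.1fs", dn$arch,
                     mean(bench[[dn$arch]]),
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("classify" %in% stages && !stage_done(run_dir, "classify")) {
    need("classify", "dataset")
    cdir <- file.path(run_dir, "classify")
    dir.create(cdir, showWarnings = FALSE)
    t0 <- Sys.time()
    cl <- cfg$classify
    folds <- load_folds()
    spec <- build_classifier(cl$depth, cl$input_size,
                             n_classes = length(unique(crop_labels(folds$train))))
    clf <- train_classifier(spec, folds,
                            train_config(loss = "crossentropy",
                                         epochs = cl$epochs,
                                         batch_size = cl$batch_size,
                                         learning_rate = cl$learning_rate,
                                         seed = cfg$seed + 53L))
    ev <- evaluate_classifier(clf, folds$test)
    write_nn(clf, file.path(cdir, "classifier.json"))
    utils::write.csv(as.data.frame(ev$confusion),
                     file.path(cdir, "confusion.csv"), row.names = FALSE)
    write_metrics_json(ev$metrics, file.path(cdir, "metrics.json"))
    utils::write.csv(clf$history, file.path(cdir, "curves.csv"),
                     row.names = FALSE)
    summary$classify <- list(test_accuracy = ev$accuracy)
    mark_done(run_dir, "classify")
    pipe_log(run_dir, "INFO", "classify",
             sprintf("test accuracy %.4f in %.1fs", ev$accuracy,
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("transfer" %in% stages && !stage_done(run_dir, "transfer")) {
    need("transfer", "dataset")
    tdir <- file.path(run_dir, "transfer")
    dir.create(tdir, showWarnings = FALSE)
    t0 <- Sys.time()
    tr <- cfg$transfer
    cl <- cfg$classify
    folds <- load_folds()
    is_new <- function(crops) crop_labels(crops) == tr$new_class
    folds_old <- list(train = folds$train[!is_new(folds$train)],
                      val = folds$val[!is_new(folds$val)])
    spec <- build_classifier(cl$depth, cl$input_size,
                             n_classes = length(unique(crop_labels(folds_old$train))))
    clf <- train_classifier(spec, folds_old,
                            train_config(loss = "crossentropy",
                                         epochs = cl$epochs,
                                         batch_size = cl$batch_size,
                                         learning_rate = cl$learning_rate,
                                         seed = cfg$seed + 59L))
    res <- transfer_learn(clf,
                          transfer_config(tr$new_class, tr$epochs, tr$mix,
                                          seed = cfg$seed + 61L),
                          new_crops = folds$train[is_new(folds$train)],
                          old_crops = folds_old$train,
                          test_crops = folds$test)
    acc_new_before <- res$before$confusion[tr$new_class, tr$new_class] /
      sum(res$before$confusion[tr$new_class, ])
    acc_new_after <- res$after$confusion[tr$new_class, tr$new_class] /
      sum(res$after$confusion[tr$new_class, ])
    utils::write.csv(as.data.frame(res$before$confusion),
                     file.path(tdir, "confusion_before.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(res$after$confusion),
                     file.path(tdir, "confusion_after.csv"), row.names = FALSE)
    summary$transfer <- list(new_class = tr$new_class,
                             acc_new_before = acc_new_before,
                             acc_new_after = acc_new_after)
    mark_done(run_dir, "transfer")
    pipe_log(run_dir, "INFO", "transfer",
             sprintf("%s accuracy %.3f -> %.3f in %.1fs", tr$new_class,
                     acc_new_before, acc_new_after,
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("report" %in% stages && !stage_done(run_dir, "report")) {
    need("report", "classify")
    rdir <- file.path(run_dir, "report")
    dir.create(rdir, showWarnings = FALSE)
    t0 <- Sys.time()
    clf <- read_nn(file.path(run_dir, "classify", "classifier.json"))
    counts <- unlist(cfg$scene$counts)
    scene <- make_scene(cfg$scene$frame_shape, counts,
                        min_separation = cfg$scene$min_separation,
                        margin = cfg$scene$margin, seed = cfg$seed + 71L,
                        jitter = cfg$dataset$jitter)
    frame <- simulate_micrograph(scene, optics)
    crops <- crop_patches(frame, window = cfg$dataset$window)
    prob <- predict_classifier(clf, crops)
    pred <- clf$classes[max.col(prob)]
    pred_counts <- table(factor(pred, levels = names(counts)))
    rep_tab <- count_report(counts, as.numeric(pred_counts)[match(names(counts), names(pred_counts))] |>
                              stats::setNames(names(counts)))
    utils::write.csv(rep_tab, file.path(rdir, "count_comparison.csv"),
                     row.names = FALSE)
    summary$report <- list(count_comparison = rep_tab)
    mark_done(run_dir, "report")
    pipe_log(run_dir, "INFO", "report",
             sprintf("max |count diff| %.0f in %.1fs",
                     max(abs(rep_tab$diff)),
                     as.numeric(Sys.time() - t0, units = "secs")))
  }

  manifest <- list(hash = hash, config = cfg,
                   stages = stages,
                   elapsed_s = as.numeric(Sys.time() - t_all, units = "secs"),
                   timestamp = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(run_dir = run_dir, config = cfg, hash = hash,
                 summary = summary))
}
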
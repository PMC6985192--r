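#' Pipeline configuration
#'
#' One flat configuration object drives the whole map-production pipeline:
#' sample quality control (SOM), classifier training and cross-validation
#' (SVM), per-year classification, Bayesian smoothing, base-map and
#' trajectory rules, and validation. A single master seed fans out to
#' stage-specific seeds (`seed + fixed stage offset`) so stages are
#' independently reproducible.
#'
#' @param years Integer vector of consecutive map years.
#' @param n_per_class Synthetic samples per class when simulating.
#' @param mislabel_rate Injected mislabel fraction when simulating.
#' @param som_runs Number of SOM runs for reliability estimation.
#' @param som_epochs SOM training epochs per run.
#' @param threshold QC retention threshold (default 0.8).
#' @param C,gamma,k_folds SVM parameters, see [svm_config()].
#' @param sigma2,radius Smoothing parameters, see [smooth_cube()].
#' @param pixel_area Pixel area in hectares for area accounting.
#' @param skip_qc Skip the SOM quality-control stage (logged).
#' @param seed Master seed.
#' @return A `luc_pipeline_config` list.
#' @export
pipeline_config <- function(years = 2014:2017, n_per_class = 100,
                            mislabel_rate = 0.1, som_runs = 20,
                            som_epochs = 100, threshold = 0.8, C = 1,
                            gamma = 1 / 92, k_folds = 5, sigma2 = 10,
                            radius = 1, pixel_area = 6.25, skip_qc = FALSE,
                            seed = 1L) {
  structure(list(years = as.integer(years), n_per_class = n_per_class,
                 mislabel_rate = mislabel_rate, som_runs = som_runs,
                 som_epochs = som_epochs, threshold = threshold, C = C,
                 gamma = gamma, k_folds = k_folds, sigma2 = sigma2,
                 radius = radius, pixel_area = pixel_area, skip_qc = skip_qc,
                 seed = as.integer(seed)),
            class = "luc_pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `luc_pipeline_config`.
#' @param path File path for the plain-text `key: value` serialization.
#' @export
write_pipeline_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, paste(config[[k]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- strsplit(x[2], " ", fixed = TRUE)[[1]]
    if (x[1] == "skip_qc") as.logical(v) else as.numeric(v)
  }), vapply(kv, `[[`, character(1), 1))
  do.call(pipeline_config, vals)
}

#' Run the full map-production pipeline
#'
#' Executes, in order: (1) SOM quality control of the training samples,
#' (2) SVM training on the retained samples plus stratified k-fold
#' cross-validation, (3) per-year classification of the scene cube into
#' class probabilities, (4) Bayesian neighborhood smoothing, (5) base-map
#' fusion and trajectory rules with auxiliary masks, and (6) validation
#' against the scene truth (confusion matrix, accuracies, area series).
#' When `samples` or `scene` are `NULL` they are simulated from the default
#' patterns under the configuration's seed.
#'
#' @param config A [pipeline_config()].
#' @param samples Optional sample tibble; simulated when `NULL`.
#' @param scene Optional `luc_scene` from [generate_scene()]; simulated on
#'   the default scene layout when `NULL`.
#' @param log_file Optional path; the stage log is also written there.
#' @return A `luc_pipeline_result` list with the per-stage artifacts:
#'   `samples`, `qc`, `model`, `cv`, `classified` (per-year raw probability
#'   cubes and maps), `smoothed`, `final` (post-processed maps and rule
#'   report), `validation` and the stage `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), samples = NULL,
                         scene = NULL, log_file = NULL) {
  stopifnot(inherits(config, "luc_pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log <<- c(log, line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  }
  fp <- function(x) sprintf("%.6g", sum(as.numeric(x), na.rm = TRUE))
  patterns <- default_patterns()

  if (is.null(samples)) {
    samples <- generate_samples(patterns, n_per_class = config$n_per_class,
                                mislabel_rate = config$mislabel_rate,
                                seed = config$seed + 11L)
    say("simulate: %d samples (n_per_class=%s, mislabel_rate=%s)",
        nrow(samples), config$n_per_class, config$mislabel_rate)
  }
  if (is.null(scene)) {
    scene <- generate_scene(default_scene_spec(years = config$years,
                                               seed = config$seed + 23L),
                            patterns)
    say("simulate: %dx%d scene, %d years", scene$spec$height,
        scene$spec$width, length(scene$spec$years))
  }

  # ---- quality control ----
  if (config$skip_qc) {
    say("qc: skipped by configuration")
    qc <- NULL
    training <- samples
  } else {
    rel <- evaluate_samples(samples, n_runs = config$som_runs,
                            epochs = config$som_epochs,
                            seed = config$seed + 100L)
    qc <- filter_samples(rel, samples, threshold = config$threshold)
    training <- qc$retained
    say("qc: %d -> %d samples (%.1f%% reduction), checksum %s",
        qc$report$n_in, qc$report$n_retained, qc$report$pct_reduction,
        fp(sample_features(training)))
  }

  # ---- classifier ----
  svm_cfg <- svm_config(C = config$C, gamma = config$gamma,
                        k_folds = config$k_folds, seed = config$seed + 200L)
  cv <- cross_validate(training, svm_cfg)
  say("cv: overall accuracy %.3f over %d folds", cv$overall, cv$k_folds)
  model <- train_svm(training, svm_cfg)
  say("train: C=%s gamma=%.5f, %d classes", config$C, config$gamma,
      length(model$classes))

  # ---- per-year classification and smoothing ----
  classified <- purrr::imap(scene$cube, function(a, yr) {
    out <- classify_cube(model, a, as.integer(yr))
    say("classify %s: checksum %s", yr, fp(out$probs))
    out
  })
  smoothed <- purrr::imap(classified, function(cl, yr) {
    out <- smooth_cube(cl$probs, sigma2 = config$sigma2,
                       radius = config$radius)
    say("smooth %s: sigma2=%s radius=%s, checksum %s", yr, config$sigma2,
        config$radius, fp(out$probs))
    out
  })

  # ---- rules and masks ----
  final <- run_postprocessing(purrr::map(smoothed, "map"), scene$masks,
                              scene$ref)
  say("rules: %d pixels rewritten", sum(final$report$n_pixels))

  # ---- validation against scene truth ----
  mask_any <- as.vector(scene$masks$water | scene$masks$urban |
                          scene$masks$sugarcane)
  pred <- unlist(purrr::map(final$maps, function(m) {
    code_label(as.vector(unclass(m)))[!mask_any]
  }))
  ref <- unlist(purrr::map(scene$truth, function(m) {
    code_label(as.vector(unclass(m)))[!mask_any]
  }))
  cm <- confusion(pred, ref)
  acc <- accuracies(cm)
  areas <- area_series(final$maps, pixel_area = config$pixel_area)
  say("validate: overall agreement with truth %.3f", acc$overall)

  structure(list(samples = samples, scene = scene, qc = qc, model = model,
                 cv = cv, classified = classified, smoothed = smoothed,
                 final = final,
                 validation = list(confusion = cm, overall = acc$overall,
                                   by_class = acc$by_class, areas = areas),
                 config = config, log = log),
            class = "luc_pipeline_result")
}
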
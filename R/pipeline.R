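#' Run the end-to-end pipeline from a configuration
#'
#' Executes the stage list `synth -> preprocess -> train -> sample ->
#' evaluate` from a YAML configuration (or an equivalent named list),
#' writing each stage's artifact (HDF5 epochs containers, RDS model
#' checkpoints, JSON metric reports) plus a JSON log of seeds and
#' durations into the output directory. Stages are resumable: an existing
#' artifact produced under the same configuration hash is reused unless
#' `overwrite` is set. A rerun with an unchanged configuration reproduces
#' the metric JSON exactly.
#'
#' The configuration sections are `synth` (fields of [synth_config()]),
#' `preprocess` (`low_hz`, `high_hz`, `channels`), `train` (arguments of
#' [mrm_gan()]), `sample` (`n`), `evaluate` (`n_proj`), plus the top-level
#' `out_dir`, `seed` and `stages`. Every stage derives its own seed from
#' the master seed, so partial pipelines stay reproducible.
#'
#' @param config path to a YAML file or a named list.
#' @param overwrite rerun stages whose artifacts already exist.
#' @return (invisibly) a list with the artifact paths and, when the
#'   evaluate stage ran, the metric report.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config error: expected a YAML file or a list")
  for (field in c("out_dir", "stages"))
    if (is.null(cfg[[field]]))
      stop(sprintf("config error: missing field '%s'", field))
  seed <- as.integer(cfg$seed %||% 1L)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(cfg)
  log <- list(config_hash = cfg_hash, seed = seed, stages = list())
  paths <- list(raw = file.path(out, "raw.h5"),
                pre = file.path(out, "preprocessed.h5"),
                model = file.path(out, "model.rds"),
                gen = file.path(out, "generated.h5"),
                metrics = file.path(out, "metrics.json"),
                log = file.path(out, "run_log.json"))
  known <- c("synth", "preprocess", "train", "sample", "evaluate")
  stages <- as.character(cfg$stages)
  if (!all(stages %in% known))
    stop("config error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  result <- list(paths = paths)
  stage_seed <- function(k)
    as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483647)
  tic <- function() proc.time()[["elapsed"]]
  need <- function(p, what)
    if (!file.exists(p))
      stop(sprintf("dependency error: stage needs missing artifact %s (%s)",
                   p, what))

  if ("synth" %in% stages) {
    t0 <- tic()
    if (overwrite || !file.exists(paths$raw)) {
      sc <- do.call(synth_config,
                    c(cfg$synth %||% list(),
                      list(seed = stage_seed(1L))))
      write_epochs(generate_oddball(sc), paths$raw)
    }
    log$stages$synth <- list(seed = stage_seed(1L), seconds = tic() - t0)
  }
  if ("preprocess" %in% stages) {
    t0 <- tic()
    need(paths$raw, "synth")
    if (overwrite || !file.exists(paths$pre)) {
      x <- read_epochs(paths$raw)
      pp <- cfg$preprocess %||% list()
      x <- bandpass_fir(x, filter_spec(pp$low_hz %||% 0.01,
                                       pp$high_hz %||% 40))
      if (!is.null(pp$channels)) x <- select_channels(x, pp$channels)
      write_epochs(maxabs_scale(x), paths$pre)
    }
    log$stages$preprocess <- list(seconds = tic() - t0)
  }
  if ("train" %in% stages) {
    t0 <- tic()
    need(paths$pre, "preprocess")
    if (overwrite || !file.exists(paths$model)) {
      x <- read_epochs(paths$pre)
      tr <- cfg$train %||% list()
      model <- mrm_gan(
        x, variant = tr$variant %||% "wgan_gp",
        weights = regularizer_weights(tr$lambda %||% 0.6,
                                      tr$sr_mode %||% "reciprocal"),
        terms = tr$terms %||% c("tr", "fr", "sr"),
        steps = tr$steps %||% 200L,
        batch_size = tr$batch_size %||% 32L,
        seed = stage_seed(3L))
      model$config_hash <- cfg_hash
      saveRDS(model, paths$model)
    }
    log$stages$train <- list(seed = stage_seed(3L), seconds = tic() - t0)
  }
  if ("sample" %in% stages) {
    t0 <- tic()
    need(paths$model, "train")
    model <- readRDS(paths$model)
    if (!identical(model$config_hash, cfg_hash) && !overwrite)
      stop("dependency error: model checkpoint has a different config hash")
    if (overwrite || !file.exists(paths$gen)) {
      n <- (cfg$sample %||% list())$n %||% 100L
      write_epochs(gan_sample(model, n, seed = stage_seed(4L)), paths$gen)
    }
    log$stages$sample <- list(seed = stage_seed(4L), seconds = tic() - t0)
  }
  if ("evaluate" %in% stages) {
    t0 <- tic()
    real_path <- if (file.exists(paths$pre)) paths$pre else paths$raw
    need(real_path, "synth/preprocess")
    real <- read_epochs(real_path)
    fake <- if (file.exists(paths$gen)) read_epochs(paths$gen) else {
      # no generation stage: compare two halves of the real data
      epochs_subset(real, seq(2L, n_epochs(real), by = 2L))
    }
    base <- if (file.exists(paths$gen))
      real else epochs_subset(real, seq(1L, n_epochs(real), by = 2L))
    clf <- train_eval_classifier(real, seed = stage_seed(5L),
                                 steps = (cfg$evaluate %||% list())$clf_steps
                                 %||% 200L)
    rep <- metric_report(clf, base, fake,
                         n_proj = (cfg$evaluate %||% list())$n_proj %||%
                           128L,
                         seed = stage_seed(5L))
    jsonlite::write_json(
      list(MS = rep$MS, SWD = rep$SWD, n_projections = rep$n_projections,
           seed = rep$seed, config_hash = cfg_hash),
      paths$metrics, auto_unbox = TRUE, digits = NA)
    result$metrics <- rep
    log$stages$evaluate <- list(seed = stage_seed(5L), seconds = tic() - t0)
  }
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA)
  invisible(result)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  v <- utf8ToInt(as.character(s))
  as.character(sum(v * (seq_along(v) %% 97 + 1)) %% 1e9)
}
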
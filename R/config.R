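#' Assemble and validate a run configuration
#'
#' A run configuration bundles the synthetic-generator spec, preprocessing
#' parameters, architecture and training configuration. All schema
#' violations are collected and reported together.
#'
#' @param synthetic named list of [synthetic_spec()] arguments.
#' @param preprocessing named list: `low`, `high`, `notch`, `window_s`,
#'   `overlap`, `scales`, `pool_t`, `preictal_s`, `min_interictal_s`,
#'   `interictal_gap_s`.
#' @param branch named list of [branch_config()] arguments.
#' @param train named list of [train_config()] arguments.
#' @param patient_id label used in reports.
#' @return Object of class `run_config` with a `hash` field.
#' @export
run_config <- function(synthetic = list(), preprocessing = list(),
                       branch = list(), train = list(),
                       patient_id = "patient") {
  problems <- character(0)
  keep <- function(f, args) {
    tryCatch(do.call(f, args),
             error = function(e) {
               problems <<- c(problems, conditionMessage(e))
               NULL
             })
  }
  spec <- keep(synthetic_spec, synthetic)
  bcfg <- keep(branch_config, branch)
  tcfg <- keep(train_config, train)
  pp <- utils::modifyList(
    list(low = 0.1, high = NULL, notch = NULL, window_s = 1, overlap = 0,
         scales = 1:32, pool_t = 4L, preictal_s = 300,
         min_interictal_s = 300, interictal_gap_s = 1800),
    preprocessing)
  fs <- if (!is.null(spec)) spec$fs else 512
  # unset cutoffs adapt to the sampling rate: the 70 Hz low-pass and the
  # 48-52 Hz mains notch apply whenever the rate allows them
  if (is.null(pp$high)) {
    pp$high <- if (fs > 140) 70 else 0.44 * fs
    if (is.null(preprocessing$notch) && !("notch" %in% names(preprocessing)) &&
        fs > 140) {
      pp$notch <- c(48, 52)
    }
  }
  if (!is.null(spec) && pp$high * 2 >= spec$fs) {
    problems <- c(problems, sprintf(
      "preprocessing.high (%g Hz) requires fs > %g Hz but synthetic.fs = %g; lower 'high' or raise 'fs'",
      pp$high, 2 * pp$high, spec$fs))
  }
  if (length(problems)) {
    stop(paste(c("invalid run configuration:",
                 paste0("  - ", problems)), collapse = "\n"), call. = FALSE)
  }
  cfg <- structure(list(synthetic = spec, preprocessing = pp, branch = bcfg,
                        train = tcfg, patient_id = patient_id),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys `synthetic`, `preprocessing`, `branch`, `train`,
#' `patient_id` map to the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  run_config(synthetic = raw$synthetic %||% list(),
             preprocessing = raw$preprocessing %||% list(),
             branch = raw$branch %||% list(),
             train = raw$train %||% list(),
             patient_id = raw$patient_id %||% "patient")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$hash <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run a pipeline command
#'
#' Single programmatic entry point behind the command-line tool. Commands:
#' \describe{
#'   \item{simulate}{generate the synthetic patient and write EDF files plus
#'     JSON sidecars to `out_dir`.}
#'   \item{preprocess}{read a patient directory (or simulate one) and cache
#'     the model-ready dataset as `dataset.rds`.}
#'   \item{loocv}{full leave-one-episode-out run; writes `folds.csv`,
#'     `summary.json` and a manifest.}
#'   \item{evaluate}{recompute metrics from a stored `predictions.csv`.}
#' }
#' Every command writes `manifest.json` (config hash, seed, package version,
#' timing) into `out_dir`.
#'
#' @param command one of `"simulate"`, `"preprocess"`, `"loocv"`,
#'   `"evaluate"`.
#' @param config a `run_config` (or path to a YAML file).
#' @param out_dir output directory.
#' @param data_dir optional directory of EDF episodes (defaults to fresh
#'   simulation).
#' @return The command's main artifact, invisibly.
#' @export
sz_run <- function(command = c("simulate", "preprocess", "loocv", "evaluate"),
                   config, out_dir, data_dir = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  get_recs <- function() {
    if (!is.null(data_dir)) read_patient_dir(data_dir)
    else generate_patient(config$synthetic)
  }
  pp <- config$preprocessing
  result <- switch(command,
    simulate = {
      write_recordings(generate_patient(config$synthetic), out_dir)
    },
    preprocess = {
      ds <- preprocess_patient(get_recs(), low = pp$low, high = pp$high,
                               notch = pp$notch, window_s = pp$window_s,
                               overlap = pp$overlap, scales = pp$scales,
                               pool_t = pp$pool_t)
      saveRDS(ds, file.path(out_dir, "dataset.rds"))
      ds
    },
    loocv = {
      ds <- preprocess_patient(get_recs(), low = pp$low, high = pp$high,
                               notch = pp$notch, window_s = pp$window_s,
                               overlap = pp$overlap, scales = pp$scales,
                               pool_t = pp$pool_t)
      run <- loocv(ds, config$train, config$branch,
                   patient_id = config$patient_id, keep_fits = FALSE)
      utils::write.csv(run$aggregate$per_fold,
                       file.path(out_dir, "folds.csv"), row.names = FALSE)
      pred <- do.call(rbind, lapply(run$predictions, function(p) {
        data.frame(episode = p$episode, index = p$index, y = p$y,
                   pred = p$class, p_preictal = p$prob[, 2L])
      }))
      utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(mean = run$aggregate$mean,
                                sd = run$aggregate$sd,
                                pooled = run$aggregate$pooled),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      run
    },
    evaluate = {
      pred <- utils::read.csv(file.path(out_dir, "predictions.csv"))
      reports <- lapply(split(pred, pred$episode), function(pf) {
        fold_report(pf$y, pf$pred, patient_id = config$patient_id,
                    held_out_episode = pf$episode[1L])
      })
      ag <- aggregate_folds(unname(reports))
      jsonlite::write_json(list(mean = ag$mean, sd = ag$sd,
                                pooled = ag$pooled),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      ag
    })

  manifest <- list(command = command, config_hash = config$hash,
                   seed = config$train$seed,
                   package_version = as.character(utils::packageVersion("seizefuse")),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Grid-search over configuration values
#'
#' Evaluates `eval_fn` on every combination of the supplied parameter
#' values (the hyperparameter search the training recipe prescribes,
#' exposed as a utility rather than hard-coded).
#'
#' @param grid named list of value vectors.
#' @param eval_fn function taking one named combination (a list) and
#'   returning a scalar score.
#' @return Data frame of combinations with a `score` column, best first.
#' @export
sweep_grid <- function(grid, eval_fn) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  combos$score <- vapply(seq_len(nrow(combos)), function(i) {
    eval_fn(as.list(combos[i, , drop = FALSE]))
  }, numeric(1))
  combos[order(-combos$score), , drop = FALSE]
}
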
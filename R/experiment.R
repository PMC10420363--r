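#' End-to-end experiment configuration
#'
#' Bundles every stage of a simulate - split - train - detect - evaluate
#' experiment: the synthetic cohort, the subject-level split, one detector
#' configuration per event type, post-processing, the heuristic baseline
#' with its threshold grid, and the matching windows. Every stochastic
#' stage derives its stream from `seed`, so a config reproduces its report
#' exactly.
#'
#' @param cohort a [cohort_spec()].
#' @param fractions train/val/test fractions (default `c(0.6, 0.1, 0.3)`).
#' @param holdout_classes pathology labels (e.g. `"SYNTH-DF-forefoot-drag"`)
#'   placed wholly in TEST for zero-shot evaluation.
#' @param ic_config,fo_config [detector_config()]s for the two models.
#' @param post a [postprocess_config()].
#' @param heuristic a [heuristic_config()] (non-fitted parameters).
#' @param th_ic_grid,th_fo_grid heuristic threshold grids for
#'   [fit_thresholds()].
#' @param eval_config an [evaluation_config()].
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              fractions = c(0.6, 0.1, 0.3),
                              holdout_classes = character(),
                              ic_config = detector_config("IC"),
                              fo_config = detector_config("FO"),
                              post = postprocess_config(),
                              heuristic = heuristic_config(),
                              th_ic_grid = c(0, 0.05, 0.1),
                              th_fo_grid = c(1.5, 1.7, 1.9, 2.1, 2.3),
                              eval_config = evaluation_config(),
                              seed = 1L) {
  structure(list(cohort = cohort, fractions = fractions,
                 holdout_classes = holdout_classes,
                 ic_config = ic_config, fo_config = fo_config, post = post,
                 heuristic = heuristic, th_ic_grid = th_ic_grid,
                 th_fo_grid = th_fo_grid, eval_config = eval_config,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full detection experiment
#'
#' Simulates the cohort, splits it at the subject level, trains the IC and
#' FO detectors on the training set (model selection on validation loss),
#' fits the heuristic thresholds on the training set, detects events on
#' the test set with both methods, and evaluates temporal error, detection
#' rate, cumulative detection curves and pairwise statistics per pathology
#' class. Test-set reference events are the TRUTH annotations only.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return object of class `gait_experiment`: list with `config`,
#'   `dataset`, `detectors`, `heuristic_fitted`, `metrics` (data.frame:
#'   method x etype x pathology rows with MAE, CI, detection rate),
#'   `curves`, `comparisons` and `log`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_fmt("experiment stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  say("simulating cohort")
  dataset <- stage("simulate", simulate_cohort(config$cohort))
  say("splitting %d trials", length(dataset$trials))
  dataset <- stage("split", split_dataset(dataset, config$fractions,
                                          holdout_classes = config$holdout_classes,
                                          seed = derive_seed(config$seed, "split")))
  train <- partition_trials(dataset, "TRAIN")
  val <- partition_trials(dataset, "VAL")
  test <- partition_trials(dataset, "TEST")

  say("training IC model (%d trials)", length(train))
  ic_cfg <- config$ic_config
  ic_cfg$seed <- derive_seed(config$seed, "ic")
  ic_fit <- stage("train-ic", train_detector(train, etype = "IC",
                                             config = ic_cfg, val = val))
  say("training FO model")
  fo_cfg <- config$fo_config
  fo_cfg$seed <- derive_seed(config$seed, "fo")
  fo_fit <- stage("train-fo", train_detector(train, etype = "FO",
                                             config = fo_cfg, val = val))
  say("fitting heuristic thresholds")
  heur <- stage("fit-heuristic",
                fit_thresholds(train, config$th_ic_grid, config$th_fo_grid,
                               config = config$heuristic,
                               eval_config = config$eval_config))

  say("evaluating on %d test trials", length(test))
  detectors <- list(IC = ic_fit, FO = fo_fit)
  per_trial <- stage("detect", lapply(test, function(tr) {
    list(trial = tr,
         MODEL = rbind(predict(ic_fit, tr, post = config$post),
                       predict(fo_fit, tr, post = config$post)),
         HEURISTIC = detect_events_heuristic(tr, heur))
  }))

  metrics <- list(); curves <- list(); matches <- list()
  paths <- sort(unique(vapply(test, function(tr) tr$pathology, "")))
  for (method in c("MODEL", "HEURISTIC")) {
    for (et in c("IC", "FO")) {
      for (cls in c(paths, "ALL")) {
        ms <- list()
        for (pt in per_trial) {
          if (cls != "ALL" && pt$trial$pathology != cls) next
          pred <- pt[[method]]
          for (sd in c("L", "R")) {
            truth <- trial_events(pt$trial, etype = et, side = sd, source = "TRUTH")
            p <- pred[pred$etype == et & pred$side == sd, , drop = FALSE]
            ms[[length(ms) + 1L]] <- match_events(p, truth, config$eval_config,
                                                  fs = pt$trial$fs)
          }
        }
        pooled <- pool_matches(ms)
        summ <- tryCatch(
          temporal_error_summary(pooled, seed = derive_seed(config$seed, "ci", method, et, cls)),
          error = function(e) list(mae_ms = NA_real_, ci_low = NA_real_,
                                   ci_high = NA_real_, n = 0L))
        metrics[[length(metrics) + 1L]] <- data.frame(
          method = method, etype = et, pathology = cls,
          mae_ms = summ$mae_ms, ci_low = summ$ci_low, ci_high = summ$ci_high,
          n_events = pooled$n_tp + pooled$n_fp + pooled$n_fn,
          n_tp = pooled$n_tp, n_fp = pooled$n_fp, n_fn = pooled$n_fn,
          detection_rate = detection_rate(pooled),
          n_spurious = length(pooled$spurious),
          stringsAsFactors = FALSE)
        curves[[paste(method, et, cls, sep = ".")]] <-
          cumulative_detection_curve(pooled)
        matches[[paste(method, et, cls, sep = ".")]] <- pooled
      }
    }
  }
  metrics <- do.call(rbind, metrics)

  # paired model-vs-heuristic comparison per event type (pooled classes):
  # events matched by both methods contribute their absolute errors.
  comparisons <- list()
  for (et in c("IC", "FO")) {
    a <- matches[[paste("MODEL", et, "ALL", sep = ".")]]$per_event
    b <- matches[[paste("HEURISTIC", et, "ALL", sep = ".")]]$per_event
    ok <- !is.na(a$abs_error_ms) & !is.na(b$abs_error_ms)
    comparisons[[et]] <- if (sum(ok) >= 5L) {
      compare_methods(a$abs_error_ms[ok], b$abs_error_ms[ok])
    } else {
      list(note = "fewer than 5 paired events")
    }
  }

  structure(list(
    config = config, dataset = dataset, detectors = detectors,
    heuristic_fitted = heur, metrics = metrics, curves = curves,
    comparisons = comparisons,
    log = list(seed = config$seed,
               n_train = length(train), n_val = length(val),
               n_test = length(test),
               heuristic_th_ic = heur$th_ic,
               heuristic_th_fo_factor = heur$th_fo_factor)
  ), class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat("<gait_experiment>\n")
  cat(sprintf("  %d train / %d val / %d test trials, seed %d\n",
              x$log$n_train, x$log$n_val, x$log$n_test, x$log$seed))
  overall <- x$metrics[x$metrics$pathology == "ALL", ]
  for (i in seq_len(nrow(overall))) {
    r <- overall[i, ]
    cat(sprintf("  %-9s %s: MAE %5.1f ms (%.1f-%.1f), detection rate %.1f%%\n",
                r$method, r$etype, r$mae_ms, r$ci_low, r$ci_high,
                100 * r$detection_rate))
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (metrics, curves, comparisons, log; versioned
#' schema) and `metrics.csv` into `dir`. The JSON is a pure function of
#' the experiment object, so identical configurations produce identical
#' reports.
#'
#' @param experiment a `gait_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(schema = "gaitevents-report", version = 1L,
              metrics = experiment$metrics,
              curves = experiment$curves,
              comparisons = experiment$comparisons,
              log = experiment$log)
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(experiment$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
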
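#' Detector configuration
#'
#' Architecture and training settings for one event-type model. The
#' grid-search-optimized clinical configuration is three bi-directional
#' LSTM layers of 200 hidden units, dropout 0.4 after every recurrent
#' layer and an event sample-weight ratio of 1:10; those are the
#' architecture defaults here. Optimizer settings (Adam learning rate,
#' epochs, batch size) are not part of that protocol and carry package
#' defaults sized for CPU-scale experiments.
#'
#' @param etype `"IC"` or `"FO"`; one independent model per event type.
#' @param n_layers number of bi-directional LSTM layers (>= 1).
#' @param hidden_units hidden units per direction (>= 1).
#' @param dropout dropout rate in \[0, 1) applied after each recurrent
#'   layer (training only).
#' @param weight_ratio event sample weight `w >= 1` (non-event:event ratio
#'   `1:w`).
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size sequences per gradient step.
#' @param seed integer seed governing initialization, cropping, shuffling
#'   and dropout.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(etype = c("IC", "FO"), n_layers = 3L,
                            hidden_units = 200L, dropout = 0.4,
                            weight_ratio = 10, learning_rate = 2e-3,
                            epochs = 20L, batch_size = 8L, seed = 1L) {
  etype <- match.arg(etype)
  if (n_layers < 1L) stop_fmt("n_layers must be >= 1")
  if (hidden_units < 1L) stop_fmt("hidden_units must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_fmt("dropout must be in [0, 1)")
  if (weight_ratio < 1) stop_fmt("weight_ratio must be >= 1")
  structure(list(etype = etype, n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units), dropout = dropout,
                 weight_ratio = weight_ratio, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Build an untrained detector
#'
#' Initializes the stacked bi-directional LSTM frame classifier: a masking
#' front (all-zero padded rows are never fed through the recurrence),
#' `n_layers` bi-directional LSTM layers with dropout after each, and a
#' time-distributed dense layer with 3-way softmax (no event / left event
#' / right event). Weights use Glorot-uniform initialization with forget
#' gate biases at 1; identical seeds give identical parameters.
#'
#' @param config a [detector_config()].
#' @param n_channels input channels (36 for the six-marker feature set).
#' @return object of class `gait_detector` (untrained).
#' @export
build_detector <- function(config, n_channels = 36L) {
  H <- config$hidden_units
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- with_seed(derive_seed(config$seed, "init", config$etype), {
    p <- list()
    for (l in seq_len(config$n_layers)) {
      D <- if (l == 1L) n_channels else 2L * H
      for (d in c("f", "b")) {
        p[[sprintf("W%d%s", l, d)]] <- glorot(4L * H, D)
        p[[sprintf("U%d%s", l, d)]] <- glorot(4L * H, H)
        b <- numeric(4L * H)
        b[(H + 1L):(2L * H)] <- 1          # forget gate bias
        p[[sprintf("b%d%s", l, d)]] <- b
      }
    }
    p[["Wo"]] <- glorot(3L, 2L * H)
    p[["bo"]] <- numeric(3L)
    p
  })
  structure(list(config = config, params = params, n_channels = n_channels,
                 history = NULL, trained = FALSE),
            class = "gait_detector")
}

## Split a padded batch back into per-sequence (X, classes, weights) lists,
## keeping only real (unpadded) frames so the recurrence never traverses
## padding -- this is the masking contract.
batch_to_seqs <- function(batch) {
  lapply(seq_along(batch$lengths), function(i) {
    len <- batch$lengths[i]
    list(X = matrix(batch$values[i, seq_len(len), ], nrow = len),
         classes = batch$classes[i, seq_len(len)],
         weights = batch$weights[i, seq_len(len)])
  })
}

#' Weighted categorical cross-entropy
#'
#' The detector's loss for one sequence: the sample-weighted mean of
#' `-log p[true class]` over frames, i.e.
#' `sum_t w_t * (-log p_t[y_t]) / sum_t w_t`. Frames with weight 0
#' (padding) do not contribute.
#'
#' @param probs `T x 3` row-stochastic matrix.
#' @param classes length-`T` integer vector in `{0, 1, 2}`.
#' @param weights length-`T` non-negative weights.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, classes, weights) {
  wsum <- sum(weights)
  if (wsum <= 0) return(0)
  p <- probs[cbind(seq_along(classes), classes + 1L)]
  sum(weights * -log(pmax(p, 1e-12))) / wsum
}

#' Loss of a detector on a padded batch
#'
#' Mean per-sequence weighted cross-entropy (dropout disabled). Used for
#' validation tracking and for verifying masking invariance.
#'
#' @param model a `gait_detector`.
#' @param batch a padded batch from [pad_batch()] / [prepare_batch()].
#' @return scalar loss.
#' @export
detector_loss <- function(model, batch) {
  seqs <- batch_to_seqs(batch)
  mean(vapply(seqs, function(s) {
    cpp_bilstm_run(model$params, s$X, as.integer(s$classes), s$weights,
                   model$config$n_layers, model$config$hidden_units,
                   0, FALSE, FALSE)$loss
  }, 0))
}

#' Train a gait event detector
#'
#' The main fitting function. Prepares features and labels from the
#' training trials (random event-window crop, 36-channel assembly,
#' per-trial \[0.1, 1.1\] normalization, single-frame labels with sample
#' weights), then minimizes the weighted categorical cross-entropy with
#' Adam over mini-batches of sequences. If validation trials are given,
#' the parameters with the best validation loss are retained; training
#' history records per-epoch train/val loss. Fully deterministic given
#' `config$seed`.
#'
#' @param train list of `gait_trial` (or a padded batch from
#'   [prepare_batch()]).
#' @param etype `"IC"` or `"FO"`; overrides `config$etype` when supplied.
#' @param config a [detector_config()].
#' @param val optional validation trials (or padded batch).
#' @param verbose print per-epoch losses.
#' @return a trained `gait_detector` with elements `config`, `params`,
#'   `history` (data.frame epoch/train_loss/val_loss) and `n_channels`.
#' @export
train_detector <- function(train, etype = NULL, config = detector_config(),
                           val = NULL, verbose = FALSE) {
  if (!is.null(etype)) config$etype <- match.arg(etype, c("IC", "FO"))
  train_batch <- if (is.list(train) && !is.null(train$values)) train else
    prepare_batch(train, config$etype, config$weight_ratio, crop = TRUE,
                  seed = derive_seed(config$seed, "traincrop"))
  if (is.list(val) && is.null(val$values) && length(val) == 0L) val <- NULL
  val_batch <- if (is.null(val)) NULL else if (is.list(val) && !is.null(val$values)) val else
    prepare_batch(val, config$etype, config$weight_ratio, crop = TRUE,
                  seed = derive_seed(config$seed, "valcrop"))
  seqs <- batch_to_seqs(train_batch)
  if (length(seqs) == 0L) stop_fmt("empty training set")
  n_ch <- ncol(seqs[[1L]]$X)
  model <- build_detector(config, n_channels = n_ch)

  opt <- adam_state(model$params)
  best_val <- Inf
  best_params <- model$params
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  with_seed(derive_seed(config$seed, "sgd", config$etype), {
    n <- length(seqs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        acc <- NULL
        bloss <- 0
        for (i in idx) {
          s <- seqs[[i]]
          res <- cpp_bilstm_run(model$params, s$X, as.integer(s$classes),
                                s$weights, config$n_layers, config$hidden_units,
                                config$dropout, TRUE, TRUE)
          if (!is.finite(res$loss)) stop_fmt("NaN loss at epoch %d", epoch)
          bloss <- bloss + res$loss
          acc <- if (is.null(acc)) res$grads else
            mapply(`+`, acc, res$grads[names(acc)], SIMPLIFY = FALSE)
        }
        acc <- lapply(acc, `/`, length(idx))
        opt <- adam_step(opt, model$params, acc, config$learning_rate)
        model$params <- opt$params
        epoch_loss <- epoch_loss + bloss
      }
      train_loss <- epoch_loss / n
      val_loss <- if (is.null(val_batch)) NA_real_ else detector_loss(model, val_batch)
      history[epoch, ] <- list(epoch, train_loss, val_loss)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %s", epoch, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      }
      if (!is.na(val_loss) && val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
      }
    }
  })
  if (!is.null(val_batch)) model$params <- best_params
  model$history <- history
  model$trained <- TRUE
  model
}

adam_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(params = params, m = zeros, v = zeros, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  opt$params <- params
  opt
}

#' Per-frame class probabilities for a trial or feature tensor
#'
#' Runs the detector's forward pass (dropout disabled, hence
#' deterministic). Only unmasked frames are fed through the recurrence;
#' masked (padded) frames are reported as `NA` rows and flagged via the
#' `"masked"` attribute, so right-padding can never alter real-frame
#' predictions.
#'
#' @param model a `gait_detector`.
#' @param tensor a `feature_tensor` (normalized), or a `gait_trial` which
#'   is assembled and normalized on the fly.
#' @return `T x 3` matrix of row-stochastic probabilities (columns: none,
#'   left, right), with attribute `masked`.
#' @export
predict_probabilities <- function(model, tensor) {
  if (inherits(tensor, "gait_trial")) {
    tensor <- normalize_features(assemble_features(tensor))
  }
  if (ncol(tensor$values) != model$n_channels) {
    stop_fmt("channel count mismatch: model expects %d, tensor has %d",
             model$n_channels, ncol(tensor$values))
  }
  mask <- tensor$mask
  probs <- matrix(NA_real_, nrow(tensor$values), 3L)
  if (any(mask)) {
    probs[mask, ] <- cpp_bilstm_predict(model$params,
                                        tensor$values[mask, , drop = FALSE],
                                        model$config$n_layers,
                                        model$config$hidden_units)
  }
  colnames(probs) <- c("none", "left", "right")
  attr(probs, "masked") <- !mask
  probs
}

#' @export
print.gait_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<gait_detector> %s model: %d bi-LSTM layer(s) x %d units, dropout %.2g, weight ratio 1:%g\n",
              cfg$etype, cfg$n_layers, cfg$hidden_units, cfg$dropout, cfg$weight_ratio))
  cat(sprintf("  %s; %d input channels, seed %d\n",
              if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained",
              x$n_channels, cfg$seed))
  invisible(x)
}

#' @export
summary.gait_detector <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  final train loss %.4f%s\n", h$train_loss[nrow(h)],
                if (!all(is.na(h$val_loss)))
                  sprintf(", best val loss %.4f (epoch %d)",
                          min(h$val_loss, na.rm = TRUE),
                          which.min(h$val_loss)) else ""))
  }
  n_par <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d parameters\n", n_par))
  invisible(object)
}

#' @export
coef.gait_detector <- function(object, ...) object$params

#' Predict events or probabilities from a trained detector
#'
#' @param object a `gait_detector`.
#' @param newdata a `gait_trial` or normalized `feature_tensor`.
#' @param type `"events"` (peak-detected event table, source `"MODEL"`) or
#'   `"prob"` (the `T x 3` probability matrix).
#' @param post a [postprocess_config()].
#' @param fs sampling rate for event post-processing; taken from
#'   `newdata` when available.
#' @param ... unused.
#' @return event `data.frame` or probability matrix.
#' @export
predict.gait_detector <- function(object, newdata, type = c("events", "prob"),
                                  post = postprocess_config(), fs = NULL, ...) {
  type <- match.arg(type)
  probs <- predict_probabilities(object, newdata)
  if (type == "prob") return(probs)
  if (is.null(fs)) fs <- newdata$fs
  keep <- !attr(probs, "masked")
  detect_events(probs[keep, , drop = FALSE], etype = object$config$etype,
                config = post, fs = fs)
}

#' @export
plot.gait_detector <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop_fmt("model has no training history")
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = sprintf("%s model training", x$config$etype), ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Evaluate a trained detector on a set of trials
#'
#' Predicts events for every trial, matches them per (etype, side) stream
#' against the TRUTH annotations and pools the results.
#'
#' @param model a trained `gait_detector`.
#' @param trials list of `gait_trial`.
#' @param post a [postprocess_config()].
#' @param eval_config an [evaluation_config()].
#' @return list with `mae_ms`, `detection_rate`, `curve` (cumulative
#'   detection curve) and `pooled` (the pooled `match_result`).
#' @export
evaluate_detector <- function(model, trials, post = postprocess_config(),
                              eval_config = evaluation_config()) {
  etype <- model$config$etype
  matches <- list()
  for (tr in trials) {
    pred <- predict(model, tr, type = "events", post = post)
    for (sd in c("L", "R")) {
      truth <- trial_events(tr, etype = etype, side = sd, source = "TRUTH")
      p <- pred[pred$side == sd, , drop = FALSE]
      matches[[length(matches) + 1L]] <- match_events(p, truth, eval_config, fs = tr$fs)
    }
  }
  pooled <- pool_matches(matches)
  err <- pooled$per_event$abs_error_ms[pooled$per_event$outcome != "FN"]
  list(mae_ms = if (length(err)) mean(err) else NA_real_,
       detection_rate = detection_rate(pooled),
       curve = cumulative_detection_curve(pooled),
       pooled = pooled)
}

#' Hyperparameter grid specification
#'
#' Defaults reproduce the full search space of the clinical protocol:
#' layers {1,2,3} x hidden units {50..350} x dropout {0.2,0.4,0.6} x
#' weight ratios {10,100,500,1000} = 252 combinations.
#'
#' @param n_layers,hidden_units,dropout,weight_ratio candidate vectors.
#' @return object of class `grid_space`.
#' @export
grid_space <- function(n_layers = c(1L, 2L, 3L),
                       hidden_units = c(50L, 100L, 150L, 200L, 250L, 300L, 350L),
                       dropout = c(0.2, 0.4, 0.6),
                       weight_ratio = c(10, 100, 500, 1000)) {
  if (!length(n_layers) || !length(hidden_units) || !length(dropout) ||
      !length(weight_ratio)) stop_fmt("empty grid dimension")
  structure(list(n_layers = n_layers, hidden_units = hidden_units,
                 dropout = dropout, weight_ratio = weight_ratio),
            class = "grid_space")
}

#' Enumerate a grid space
#' @param space a [grid_space()].
#' @return data.frame with one row per hyperparameter combination.
#' @export
enumerate_grid <- function(space) {
  expand.grid(n_layers = space$n_layers, hidden_units = space$hidden_units,
              dropout = space$dropout, weight_ratio = space$weight_ratio,
              KEEP.OUT.ATTRS = FALSE)
}

#' Hyperparameter grid search
#'
#' Trains one model per grid combination (optionally a deterministic
#' subsample of `budget` combinations) and ranks them on the validation
#' set by detection rate at the true-positive window, with MAE as the
#' tie-breaker.
#'
#' @param space a [grid_space()].
#' @param train,val lists of `gait_trial`.
#' @param etype `"IC"` or `"FO"`.
#' @param base_config [detector_config()] supplying the non-searched
#'   settings (epochs, learning rate, seed, ...).
#' @param budget optional number of combinations to evaluate; subsampled
#'   deterministically from the full enumeration using the base seed.
#' @param post,eval_config post-processing and matching settings.
#' @return list with `best_config` (a `detector_config`) and
#'   `leaderboard` (data.frame sorted best first).
#' @export
grid_search <- function(space, train, val, etype = "IC",
                        base_config = detector_config(), budget = NULL,
                        post = postprocess_config(),
                        eval_config = evaluation_config()) {
  grid <- enumerate_grid(space)
  if (!is.null(budget) && budget < nrow(grid)) {
    keep <- with_seed(derive_seed(base_config$seed, "budget"),
                      sort(sample.int(nrow(grid), budget)))
    grid <- grid[keep, , drop = FALSE]
  }
  grid$detection_rate <- NA_real_
  grid$mae_ms <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$etype <- etype
    cfg$n_layers <- grid$n_layers[k]
    cfg$hidden_units <- grid$hidden_units[k]
    cfg$dropout <- grid$dropout[k]
    cfg$weight_ratio <- grid$weight_ratio[k]
    fit <- train_detector(train, etype = etype, config = cfg, val = val)
    res <- evaluate_detector(fit, val, post = post, eval_config = eval_config)
    grid$detection_rate[k] <- res$detection_rate
    grid$mae_ms[k] <- res$mae_ms
  }
  ord <- order(-grid$detection_rate, grid$mae_ms)
  leaderboard <- grid[ord, , drop = FALSE]
  best <- leaderboard[1L, ]
  best_config <- base_config
  best_config$etype <- etype
  best_config$n_layers <- best$n_layers
  best_config$hidden_units <- best$hidden_units
  best_config$dropout <- best$dropout
  best_config$weight_ratio <- best$weight_ratio
  list(best_config = best_config, leaderboard = leaderboard)
}

#' Save or load a detector checkpoint
#'
#' The checkpoint is R's native serialized form plus a human-readable JSON
#' sidecar (`<path>.json`) of the [detector_config()], so a stored model's
#' architecture is inspectable without loading it.
#'
#' @param model a `gait_detector`.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `save_detector()` returns `path` invisibly; `load_detector()`
#'   returns the `gait_detector`.
#' @export
save_detector <- function(model, path) {
  if (!inherits(model, "gait_detector")) stop_fmt("not a gait_detector")
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gait_detector")) stop_fmt("%s is not a detector checkpoint", path)
  model
}
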
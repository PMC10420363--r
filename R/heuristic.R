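#' Velocity-threshold heuristic configuration
#'
#' Parameters of the Ghoussayni-style baseline: initial contact is a gated
#' local minimum of heel sagittal speed, foot off an ascending crossing of
#' toe sagittal speed through a walking-speed-proportional threshold.
#'
#' @param th_ic IC speed threshold in m/s (>= 0). The fitted clinical
#'   operating point is 0, which degenerates to "local minima of heel
#'   speed" gated by `ic_gate * v` (a strictly-below-zero crossing of a
#'   non-negative speed being impossible).
#' @param th_fo_factor FO threshold as a multiple of walking speed `v`
#'   (> 0); fitted clinical operating point 1.9.
#' @param ic_gate gate factor: IC minima must lie below
#'   `max(th_ic, ic_gate * v)`; suppresses swing-phase spurious minima.
#' @param min_separation per-stream deduplication distance, frames at
#'   150 Hz (scaled by `fs/150`).
#' @param smoothing moving-average window for speeds, frames at 150 Hz
#'   (scaled by `fs/150`).
#' @param ic_search_window frames (at 150 Hz, scaled by `fs/150`) searched
#'   after a descending gate crossing for the heel-speed minimum that
#'   marks initial contact; spans the final deceleration of the heel.
#' @return object of class `heuristic_config`.
#' @export
heuristic_config <- function(th_ic = 0, th_fo_factor = 1.9, ic_gate = 0.2,
                             min_separation = 25L, smoothing = 5L,
                             ic_search_window = 12L) {
  if (th_ic < 0) stop_fmt("th_ic must be >= 0")
  if (th_fo_factor <= 0) stop_fmt("th_fo_factor must be > 0")
  structure(list(th_ic = th_ic, th_fo_factor = th_fo_factor,
                 ic_gate = ic_gate, min_separation = min_separation,
                 smoothing = smoothing,
                 ic_search_window = as.integer(ic_search_window)),
            class = "heuristic_config")
}

#' Mean walking speed of a trial
#'
#' Absolute mean anterior-posterior velocity of the midpoint of the two
#' ankle markers over the trial, in m/s. Direction-agnostic, so trials
#' walked in either AP direction give the same speed.
#'
#' @param trial a `gait_trial`.
#' @return speed in m/s.
#' @export
walking_speed <- function(trial) {
  mid <- (trial$markers$L_ANKLE[, "AP"] + trial$markers$R_ANKLE[, "AP"]) / 2
  T_ <- length(mid)
  abs(mid[T_] - mid[1L]) / (T_ - 1L) * trial$fs / 1000
}

#' Sagittal-plane speed of a marker trajectory
#'
#' `sqrt(v_AP^2 + v_V^2)` in m/s, with the anterior-posterior and vertical
#' velocity components smoothed by a centered moving average before the
#' magnitude is taken (equivalent to differentiating a smoothed
#' trajectory, which keeps the stance-phase noise floor low).
#' Medio-lateral motion does not contribute.
#'
#' @param positions `T x 3` matrix in mm, columns (AP, ML, V).
#' @param fs sampling rate in Hz.
#' @param smoothing moving-average width in frames (<= 1 disables).
#' @return length-`T` non-negative numeric vector.
#' @export
sagittal_speed <- function(positions, fs, smoothing = 5L) {
  vel <- compute_velocity(positions, fs) / 1000   # m/s
  ap <- moving_average(vel[, 1L], smoothing)      # columns (AP, ML, V)
  v <- moving_average(vel[, 3L], smoothing)
  sqrt(ap^2 + v^2)
}

#' Detect gait events with the velocity-threshold heuristic
#'
#' Per foot: an IC candidate arises where the smoothed heel sagittal speed
#' falls through the gate `max(th_ic, ic_gate * v)` (stance onset) and is
#' placed at the smoothed-speed minimum within the deceleration window
#' after the crossing, refined to the frame of minimal unsmoothed speed
#' within the smoothing window (ties to the earliest frame); FO candidates
#' are ascending crossings of the smoothed toe sagittal speed through
#' `th_fo_factor * v`. Candidates closer than `min_separation` are
#' deduplicated, keeping the earlier frame.
#'
#' @param trial a `gait_trial`.
#' @param config a [heuristic_config()].
#' @return event `data.frame` (source `"HEURISTIC"`), 0-based frames. If
#'   the walking speed is zero the FO threshold is undetectable and an
#'   empty table is returned with attribute `warning = "zero walking
#'   speed"`.
#' @export
detect_events_heuristic <- function(trial, config = heuristic_config()) {
  validate_trial(trial)
  fs <- trial$fs
  v <- walking_speed(trial)
  smooth <- max(1L, as.integer(round(config$smoothing * fs / 150)))
  sep <- max(1L, as.integer(round(config$min_separation * fs / 150)))
  if (v <= 0) {
    ev <- gait_events()
    attr(ev, "warning") <- "zero walking speed"
    return(ev)
  }
  out <- list()
  for (side in c("L", "R")) {
    heel <- trial$markers[[paste0(side, "_HEEL")]]
    toe <- trial$markers[[paste0(side, "_TOE")]]
    heel_s <- sagittal_speed(heel, fs, smooth)
    heel_raw <- sagittal_speed(heel, fs, 1L)
    toe_s <- sagittal_speed(toe, fs, smooth)

    ic_gate <- max(config$th_ic, config$ic_gate * v)
    # stance onset: heel speed falls through the gate; the event is the
    # speed minimum within the short deceleration window after the
    # crossing (ties to the earliest frame)
    below <- heel_s < ic_gate
    cross <- which(!below[-length(below)] & below[-1L]) + 1L
    search <- max(1L, as.integer(round(config$ic_search_window * fs / 150)))
    ic <- vapply(cross, function(cr) {
      win <- cr:min(length(heel_s), cr + search)
      win[which.min(heel_s[win])]
    }, 0L)
    ic <- unique(ic)
    # refine each candidate on the unsmoothed speed within the window
    half <- smooth %/% 2L
    ic <- vapply(ic, function(i) {
      win <- max(1L, i - half):min(length(heel_raw), i + half)
      win[which.min(heel_raw[win])]
    }, 0L)
    ic <- dedup_frames(ic, seq_along(ic), sep, keep = "first")

    th_fo <- config$th_fo_factor * v
    above <- toe_s >= th_fo
    fo <- which(!above[-length(above)] & above[-1L]) + 1L  # first frame at/above
    fo <- dedup_frames(fo, seq_along(fo), sep, keep = "first")

    out[[side]] <- data.frame(
      etype = c(rep("IC", length(ic)), rep("FO", length(fo))),
      side = side, frame = c(ic, fo) - 1L, source = "HEURISTIC",
      stringsAsFactors = FALSE
    )
  }
  ev <- do.call(rbind, out)
  gait_events(ev$etype, ev$side, ev$frame, ev$source)
}

## Deduplicate candidate frames closer than `sep`. keep = "min": keep the
## candidate with the smaller score in a violating pair; "first": keep the
## earlier frame.
dedup_frames <- function(frames, scores, sep, keep = c("min", "first")) {
  keep <- match.arg(keep)
  if (length(frames) <= 1L) return(frames)
  ord <- order(frames)
  frames <- frames[ord]; scores <- scores[ord]
  res_f <- frames[1L]; res_s <- scores[1L]
  for (i in 2L:length(frames)) {
    last <- length(res_f)
    if (frames[i] - res_f[last] >= sep) {
      res_f <- c(res_f, frames[i]); res_s <- c(res_s, scores[i])
    } else if (keep == "min" && scores[i] < res_s[last]) {
      res_f[last] <- frames[i]; res_s[last] <- scores[i]
    }
  }
  res_f
}

#' Fit heuristic thresholds by grid search on a training set
#'
#' Evaluates every `(th_ic, th_fo_factor)` combination by the mean absolute
#' temporal error of matched events (IC and FO pooled) against the TRUTH
#' annotations of the training trials, and returns the configuration with
#' the lowest MAE. Ties go to the smaller thresholds.
#'
#' @param train list of `gait_trial` (or a `gait_dataset`, whose TRAIN
#'   partition is used if present).
#' @param th_ic_grid,th_fo_grid candidate values; defaults bracket the
#'   clinical operating point `(0, 1.9)`.
#' @param config base [heuristic_config()] supplying the non-fitted
#'   parameters.
#' @param eval_config an [evaluation_config()].
#' @return the fitted `heuristic_config`, with attribute `leaderboard` (a
#'   data.frame of all combinations and their training MAE and detection
#'   rate).
#' @export
fit_thresholds <- function(train,
                           th_ic_grid = c(0, 0.05, 0.1),
                           th_fo_grid = c(1.5, 1.7, 1.9, 2.1, 2.3),
                           config = heuristic_config(),
                           eval_config = evaluation_config()) {
  if (inherits(train, "gait_dataset")) {
    train <- if (is.null(train$partition)) train$trials else partition_trials(train, "TRAIN")
  }
  if (length(th_ic_grid) == 0L || length(th_fo_grid) == 0L) stop_fmt("empty threshold grid")
  grid <- expand.grid(th_ic = sort(th_ic_grid), th_fo_factor = sort(th_fo_grid))
  grid <- grid[order(grid$th_ic, grid$th_fo_factor), , drop = FALSE]
  grid$mae_ms <- NA_real_
  grid$detection_rate <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$th_ic <- grid$th_ic[k]
    cfg$th_fo_factor <- grid$th_fo_factor[k]
    res <- evaluate_heuristic(train, cfg, eval_config)
    grid$mae_ms[k] <- res$mae_ms
    grid$detection_rate[k] <- res$detection_rate
  }
  best <- which.min(grid$mae_ms)   # which.min takes the first (smallest thresholds)
  fitted <- config
  fitted$th_ic <- grid$th_ic[best]
  fitted$th_fo_factor <- grid$th_fo_factor[best]
  attr(fitted, "leaderboard") <- grid
  fitted
}

## Pooled IC+FO matching of heuristic detections against TRUTH for a list
## of trials; returns overall MAE (ms) and detection rate.
evaluate_heuristic <- function(trials, config, eval_config = evaluation_config()) {
  matches <- list()
  for (tr in trials) {
    pred <- detect_events_heuristic(tr, config)
    for (et in c("IC", "FO")) {
      for (sd in c("L", "R")) {
        truth <- trial_events(tr, etype = et, side = sd, source = "TRUTH")
        p <- pred[pred$etype == et & pred$side == sd, , drop = FALSE]
        matches[[length(matches) + 1L]] <-
          match_events(p, truth, eval_config, fs = tr$fs)
      }
    }
  }
  pooled <- pool_matches(matches)
  err <- pooled$per_event$abs_error_ms[pooled$per_event$outcome != "FN"]
  list(mae_ms = if (length(err)) mean(err) else Inf,
       detection_rate = detection_rate(pooled))
}
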
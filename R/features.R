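#' First derivative of a trajectory
#'
#' Central differences on interior frames, one-sided differences at the two
#' ends, scaled by the sampling rate, so a position in mm yields a velocity
#' in mm/s.
#'
#' @param positions `T x k` numeric matrix (or vector), `T >= 2`.
#' @param fs sampling rate in Hz.
#' @return matrix of the same shape.
#' @export
compute_velocity <- function(positions, fs) {
  m <- as.matrix(positions)
  T_ <- nrow(m)
  if (T_ < 2L) stop_fmt("need at least 2 frames to differentiate")
  v <- m
  v[1L, ] <- (m[2L, ] - m[1L, ]) * fs
  v[T_, ] <- (m[T_, ] - m[T_ - 1L, ]) * fs
  if (T_ > 2L) {
    v[2:(T_ - 1L), ] <- (m[3:T_, , drop = FALSE] - m[1:(T_ - 2L), , drop = FALSE]) * (fs / 2)
  }
  v
}

FEATURE_CHANNELS <- as.vector(vapply(
  MARKER_NAMES,
  function(mk) paste(mk, rep(c("pos", "vel"), each = 3L), AXIS_NAMES, sep = "."),
  character(6L)
))

#' Assemble the 36-channel input tensor of a trial
#'
#' For each marker in the fixed order `L_HEEL, L_TOE, L_ANKLE, R_HEEL,
#' R_TOE, R_ANKLE`, the three position axes followed by the three velocity
#' axes (first derivative, computed on raw mm trajectories), giving the
#' 36 input channels of the frame classifier. Values are *not* normalized;
#' see [normalize_features()].
#'
#' @param trial a `gait_trial` with all six markers.
#' @return object of class `feature_tensor`: list with `values` (`T x 36`),
#'   `mask` (length-`T` logical, all `TRUE` here), `channel_names`, `fs`,
#'   `trial_id`.
#' @export
assemble_features <- function(trial) {
  validate_trial(trial)
  cols <- list()
  for (mk in MARKER_NAMES) {
    pos <- trial$markers[[mk]]
    cols[[paste0(mk, ".pos")]] <- pos
    cols[[paste0(mk, ".vel")]] <- compute_velocity(pos, trial$fs)
  }
  values <- do.call(cbind, cols)
  colnames(values) <- FEATURE_CHANNELS
  structure(list(values = values,
                 mask = rep(TRUE, nrow(values)),
                 channel_names = FEATURE_CHANNELS,
                 fs = trial$fs, trial_id = trial$trial_id),
            class = "feature_tensor")
}

#' Crop a trial around its annotated events with a random buffer
#'
#' Keeps the span from the first to the last TRUTH event plus an
#' independently drawn buffer of `min_buf`..`max_buf` frames on each side
#' (clamped at the trial boundaries). Events are re-indexed to the cropped
#' frame origin. Uses the current RNG stream; seed it (or wrap in a seeded
#' context) for reproducibility.
#'
#' @param trial a `gait_trial` with at least one TRUTH event.
#' @param min_buf,max_buf inclusive buffer bounds in frames (defaults 25
#'   and 125).
#' @return the cropped `gait_trial`.
#' @export
crop_with_buffer <- function(trial, min_buf = 25L, max_buf = 125L) {
  truth <- trial_events(trial, source = "TRUTH")
  if (nrow(truth) == 0L) stop_fmt("trial %s has no TRUTH events to crop around", trial$trial_id)
  T_ <- n_frames(trial)
  b <- sample(seq.int(min_buf, max_buf), 2L, replace = TRUE)
  start <- max(0L, min(truth$frame) - b[1L])           # 0-based
  end <- min(T_ - 1L, max(truth$frame) + b[2L])        # inclusive, 0-based
  keep <- (start + 1L):(end + 1L)
  markers <- lapply(trial$markers, function(m) m[keep, , drop = FALSE])
  ev <- trial$events
  ev <- ev[ev$frame >= start & ev$frame <= end, , drop = FALSE]
  ev$frame <- ev$frame - start
  gait_trial(markers, fs = trial$fs,
             events = gait_events(ev$etype, ev$side, ev$frame, ev$source),
             trial_id = trial$trial_id, subject_id = trial$subject_id,
             pathology = trial$pathology)
}

#' Min-max normalize feature channels to \[0.1, 1.1\]
#'
#' Per channel and per trial, maps the observed range over unmasked frames
#' linearly onto \[0.1, 1.1\]. Constant channels map to 0.1 everywhere;
#' masked (padded) frames stay 0, which is what the masking layer of the
#' detector keys on. Per-trial statistics make the representation invariant
#' to laboratory origin and capture-volume scale.
#'
#' @param x a `feature_tensor`, or a plain `T x C` matrix.
#' @param mask logical vector when `x` is a matrix; `TRUE` = real frame.
#' @return same type as `x`, normalized.
#' @export
normalize_features <- function(x, mask = NULL) {
  if (inherits(x, "feature_tensor")) {
    x$values <- normalize_features(x$values, x$mask)
    return(x)
  }
  m <- as.matrix(x)
  if (is.null(mask)) mask <- rep(TRUE, nrow(m))
  if (!all(is.finite(m[mask, ]))) stop_fmt("non-finite values in feature matrix")
  if (sum(mask) < 2L) stop_fmt("need at least 2 unmasked frames to normalize")
  out <- m
  out[] <- 0
  sub <- m[mask, , drop = FALSE]
  lo <- apply(sub, 2L, min)
  hi <- apply(sub, 2L, max)
  rng <- hi - lo
  for (j in seq_len(ncol(m))) {
    out[mask, j] <- if (rng[j] > 0) 0.1 + (sub[, j] - lo[j]) / rng[j] else 0.1
  }
  out
}

#' Per-frame class labels for one event type
#'
#' Frame-level 3-class targets for the detector: 0 = no event, 1 = left
#' event, 2 = right event, using only TRUTH events of the requested type.
#' Labels are single-frame; the class imbalance this creates is compensated
#' with sample weights, not label widening.
#'
#' @param trial a `gait_trial`.
#' @param etype `"IC"` or `"FO"`.
#' @return object of class `label_sequence`: list with `etype`, `classes`
#'   (length-`T` integer) and `weights` (all 1; see
#'   [make_sample_weights()]).
#' @export
make_labels <- function(trial, etype = c("IC", "FO")) {
  etype <- match.arg(etype)
  classes <- integer(n_frames(trial))
  ev <- trial_events(trial, etype = etype, source = "TRUTH")
  classes[ev$frame[ev$side == "L"] + 1L] <- 1L
  classes[ev$frame[ev$side == "R"] + 1L] <- 2L
  structure(list(etype = etype, classes = classes,
                 weights = rep(1, length(classes))),
            class = "label_sequence")
}

#' Sample weights compensating event sparsity
#'
#' Event frames get weight `w`, non-event frames weight 1 (a non-event to
#' event weight ratio of 1:`w`), padded frames weight 0. The clinical data
#' motivates this: roughly one event frame per 191 non-event frames.
#'
#' @param labels a `label_sequence`.
#' @param ratio event weight `w >= 1` (default 10, the ratio `1:10`).
#' @param mask optional logical vector; `FALSE` frames get weight 0.
#' @return the `label_sequence` with its `weights` replaced.
#' @export
make_sample_weights <- function(labels, ratio = 10, mask = NULL) {
  if (ratio < 1) stop_fmt("weight ratio must be >= 1")
  w <- ifelse(labels$classes > 0L, ratio, 1)
  if (!is.null(mask)) w[!mask] <- 0
  labels$weights <- w
  labels
}

#' Zero-pad a set of trials into one batch
#'
#' Right-pads every feature tensor and label sequence with zeros to the
#' longest trial in the batch, recording the real frames in a mask. Padded
#' frames have all-zero features, class 0 and weight 0, and are ignored by
#' the detector's masking.
#'
#' @param tensors list of `feature_tensor` with identical channel order.
#' @param labels list of `label_sequence`, parallel to `tensors`.
#' @return list with `values` (`B x Tmax x 36` array), `mask`, `classes`,
#'   `weights` (`B x Tmax` matrices), `lengths`, `fs`, `trial_ids`,
#'   `etype`.
#' @export
pad_batch <- function(tensors, labels) {
  if (length(tensors) == 0L) stop_fmt("empty batch")
  if (length(tensors) != length(labels)) stop_fmt("tensors and labels differ in length")
  ch <- tensors[[1L]]$channel_names
  for (tn in tensors) {
    if (!identical(tn$channel_names, ch)) stop_fmt("channel order mismatch in batch")
  }
  lens <- vapply(tensors, function(tn) nrow(tn$values), 0L)
  B <- length(tensors)
  Tmax <- max(lens)
  values <- array(0, dim = c(B, Tmax, length(ch)))
  mask <- matrix(FALSE, B, Tmax)
  classes <- matrix(0L, B, Tmax)
  weights <- matrix(0, B, Tmax)
  for (i in seq_len(B)) {
    ti <- lens[i]
    values[i, seq_len(ti), ] <- tensors[[i]]$values
    mask[i, seq_len(ti)] <- tensors[[i]]$mask
    classes[i, seq_len(ti)] <- labels[[i]]$classes
    weights[i, seq_len(ti)] <- labels[[i]]$weights
  }
  list(values = values, mask = mask, classes = classes, weights = weights,
       lengths = lens, fs = tensors[[1L]]$fs,
       trial_ids = vapply(tensors, function(tn) tn$trial_id, ""),
       etype = labels[[1L]]$etype)
}

#' Resample a trial to a new sampling rate
#'
#' Linearly interpolates the marker trajectories onto the new time grid and
#' maps event frames by time with nearest-frame rounding. Supports
#' frequency-mismatch experiments (e.g. applying a 150 Hz model to 100 Hz
#' captures).
#'
#' @param trial a `gait_trial`.
#' @param new_fs target sampling rate in Hz.
#' @return the resampled `gait_trial`.
#' @export
resample_trial <- function(trial, new_fs) {
  if (new_fs <= 0) stop_fmt("new_fs must be > 0")
  T_ <- n_frames(trial)
  new_T <- as.integer(floor((T_ - 1L) * new_fs / trial$fs)) + 1L
  if (new_T < 2L) stop_fmt("new_fs %.3g leaves fewer than 2 frames", new_fs)
  old_t <- (seq_len(T_) - 1L) / trial$fs
  new_t <- (seq_len(new_T) - 1L) / new_fs
  markers <- lapply(trial$markers, function(m) {
    apply(m, 2L, function(col) stats::approx(old_t, col, xout = new_t, rule = 2L)$y)
  })
  ev <- trial$events
  ev$frame <- pmin(as.integer(round(ev$frame / trial$fs * new_fs)), new_T - 1L)
  ev <- ev[!duplicated(ev[c("etype", "side", "frame", "source")]), , drop = FALSE]
  gait_trial(markers, fs = new_fs,
             events = gait_events(ev$etype, ev$side, ev$frame, ev$source),
             trial_id = trial$trial_id, subject_id = trial$subject_id,
             pathology = trial$pathology)
}

#' Full feature/label preparation for a set of trials
#'
#' Convenience pipeline used by the trainer: optional event-window crop
#' (seeded), feature assembly, per-trial normalization, labels and sample
#' weights for one event type, zero-padded into a single batch.
#'
#' @param trials list of `gait_trial`.
#' @param etype `"IC"` or `"FO"`.
#' @param weight_ratio event weight `w` (ratio 1:`w`).
#' @param crop logical; crop each trial around its TRUTH events first.
#' @param seed integer seed for the crop buffers.
#' @return a padded batch (see [pad_batch()]).
#' @export
prepare_batch <- function(trials, etype, weight_ratio = 10, crop = TRUE,
                          seed = 1L) {
  if (crop) {
    trials <- with_seed(derive_seed(seed, "crop", etype),
                        lapply(trials, crop_with_buffer))
  }
  tensors <- lapply(trials, function(tr) normalize_features(assemble_features(tr)))
  labels <- lapply(trials, function(tr) {
    make_sample_weights(make_labels(tr, etype), ratio = weight_ratio)
  })
  pad_batch(tensors, labels)
}
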
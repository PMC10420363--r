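#' Gait events table
#'
#' Builds the event table attached to a [gait_trial()]. Events are the two
#' instants that segment the gait cycle: initial contact (IC), when the foot
#' first touches the ground, and foot off (FO), when it leaves the ground.
#'
#' @param etype character vector, `"IC"` or `"FO"`.
#' @param side character vector, `"L"` or `"R"`.
#' @param frame integer vector of 0-based frame indices at the trial's
#'   sampling rate.
#' @param source provenance of each event: `"TRUTH"` (reference annotation,
#'   e.g. force plates or simulator construction), `"MODEL"` (network
#'   detector) or `"HEURISTIC"` (velocity-threshold baseline).
#' @return A `data.frame` with columns `etype`, `side`, `frame`, `source`,
#'   sorted by frame.
#' @export
gait_events <- function(etype = character(), side = character(),
                        frame = integer(), source = "TRUTH") {
  n <- length(frame)
  ev <- data.frame(
    etype = rep_len(as.character(etype), n),
    side = rep_len(as.character(side), n),
    frame = as.integer(frame),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(ev)
  if (!all(ev$etype %in% c("IC", "FO"))) stop_fmt("etype must be 'IC' or 'FO'")
  if (!all(ev$side %in% c("L", "R"))) stop_fmt("side must be 'L' or 'R'")
  if (!all(ev$source %in% c("TRUTH", "MODEL", "HEURISTIC"))) {
    stop_fmt("source must be TRUTH, MODEL or HEURISTIC")
  }
  if (any(ev$frame < 0L)) stop_fmt("event frames must be non-negative")
  ev <- ev[order(ev$frame, ev$etype, ev$side), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Motion-capture trial
#'
#' A trial is one walking recording: 3-D trajectories (mm) of the left and
#' right heel, toe and ankle markers sampled at `fs` Hz, with axis order
#' (AP, ML, V) = anterior-posterior, medio-lateral, vertical, plus annotated
#' gait events. All downstream modules (features, detector, heuristic,
#' evaluation) consume this container.
#'
#' @param markers named list of the six `T x 3` numeric matrices, names
#'   `L_HEEL, L_TOE, L_ANKLE, R_HEEL, R_TOE, R_ANKLE`; columns (AP, ML, V),
#'   units mm.
#' @param fs sampling rate in Hz (positive; clinical captures are nominally
#'   150 Hz).
#' @param events event table from [gait_events()]; frames are 0-based and
#'   must lie in `[0, T)`.
#' @param trial_id,subject_id identifier strings.
#' @param pathology class label, e.g. `"MD"`, `"CF"`, `"DF"`, `"ICP"`,
#'   `"HC"` or `"SYNTH-<profile>"` for simulated trials.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(markers, fs, events = gait_events(),
                       trial_id = "trial", subject_id = "subject",
                       pathology = "HC") {
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- AXIS_NAMES
    m
  })
  trial <- structure(
    list(
      trial_id = as.character(trial_id),
      subject_id = as.character(subject_id),
      pathology = as.character(pathology),
      fs = as.numeric(fs),
      markers = markers,
      events = events
    ),
    class = "gait_trial"
  )
  validate_trial(trial)
  trial
}

#' Validate the invariants of a gait trial
#'
#' Checks marker completeness, consistent frame counts, finite coordinates,
#' positive sampling rate, in-range sorted events and uniqueness of
#' (etype, side, frame, source) triples. Called by the constructor; exported
#' because file readers and simulators re-validate after deserialisation.
#'
#' @param trial a `gait_trial`.
#' @return `trial`, invisibly; errors on any violated invariant.
#' @export
validate_trial <- function(trial) {
  missing <- setdiff(MARKER_NAMES, names(trial$markers))
  if (length(missing)) stop_fmt("missing marker %s", missing[1L])
  T_ <- n_frames(trial)
  for (nm in MARKER_NAMES) {
    m <- trial$markers[[nm]]
    if (!is.matrix(m) || ncol(m) != 3L) stop_fmt("marker %s is not a T x 3 matrix", nm)
    if (nrow(m) != T_) stop_fmt("marker %s frame count differs (%d vs %d)", nm, nrow(m), T_)
    if (!all(is.finite(m))) stop_fmt("marker %s contains non-finite coordinates", nm)
  }
  if (T_ < 2L) stop_fmt("trial must have at least 2 frames")
  if (!is.finite(trial$fs) || trial$fs <= 0) stop_fmt("fs must be positive")
  ev <- trial$events
  if (nrow(ev)) {
    if (any(ev$frame < 0L | ev$frame >= T_)) stop_fmt("event frame outside [0, T)")
    if (is.unsorted(ev$frame)) stop_fmt("events must be sorted by frame")
    key <- paste(ev$etype, ev$side, ev$frame, ev$source)
    if (anyDuplicated(key)) stop_fmt("duplicate event (etype, side, frame)")
  }
  invisible(trial)
}

#' Number of frames in a trial
#' @param trial a `gait_trial`.
#' @return integer frame count `T`.
#' @export
n_frames <- function(trial) nrow(trial$markers[[1L]])

#' Duration of a trial in seconds
#' @param trial a `gait_trial`.
#' @return numeric seconds.
#' @export
trial_duration <- function(trial) n_frames(trial) / trial$fs

#' Subset the event table of a trial
#'
#' @param trial a `gait_trial`.
#' @param etype,side,source optional filters; `NULL` keeps all.
#' @return event `data.frame` (possibly empty), sorted by frame.
#' @export
trial_events <- function(trial, etype = NULL, side = NULL, source = NULL) {
  ev <- trial$events
  if (!is.null(etype)) ev <- ev[ev$etype %in% etype, , drop = FALSE]
  if (!is.null(side)) ev <- ev[ev$side %in% side, , drop = FALSE]
  if (!is.null(source)) ev <- ev[ev$source %in% source, , drop = FALSE]
  ev
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s (subject %s, %s)\n", x$trial_id, x$subject_id, x$pathology))
  cat(sprintf("  %d frames @ %g Hz (%.2f s), %d events (%d TRUTH)\n",
              n_frames(x), x$fs, trial_duration(x), nrow(x$events),
              sum(x$events$source == "TRUTH")))
  invisible(x)
}

#' Collection of gait trials with an optional train/val/test partition
#'
#' @param trials list of `gait_trial` objects with unique `trial_id`s.
#' @param partition optional named character vector mapping `trial_id` to
#'   `"TRAIN"`, `"VAL"` or `"TEST"`. All trials of one subject must share a
#'   partition (patient-level stratification).
#' @return An object of class `gait_dataset`.
#' @seealso [split_dataset()] to assign the partition.
#' @export
gait_dataset <- function(trials, partition = NULL) {
  ids <- vapply(trials, function(t) t$trial_id, "")
  if (anyDuplicated(ids)) stop_fmt("duplicate trial_id '%s'", ids[duplicated(ids)][1L])
  names(trials) <- ids
  ds <- structure(list(trials = trials, partition = partition),
                  class = "gait_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  ids <- names(ds$trials)
  if (!is.null(ds$partition)) {
    p <- ds$partition
    if (!setequal(names(p), ids)) stop_fmt("partition must assign every trial exactly once")
    if (!all(p %in% c("TRAIN", "VAL", "TEST"))) stop_fmt("partition values must be TRAIN/VAL/TEST")
    subj <- vapply(ds$trials, function(t) t$subject_id, "")
    for (s in unique(subj)) {
      if (length(unique(p[ids[subj == s]])) != 1L) {
        stop_fmt("subject %s spans multiple partitions", s)
      }
    }
  }
  invisible(ds)
}

#' @export
print.gait_dataset <- function(x, ...) {
  subj <- unique(vapply(x$trials, function(t) t$subject_id, ""))
  cat(sprintf("<gait_dataset> %d trials, %d subjects\n", length(x$trials), length(subj)))
  if (!is.null(x$partition)) {
    tab <- table(factor(x$partition, levels = c("TRAIN", "VAL", "TEST")))
    cat(sprintf("  partition: TRAIN %d / VAL %d / TEST %d trials\n",
                tab[["TRAIN"]], tab[["VAL"]], tab[["TEST"]]))
  }
  invisible(x)
}

#' Trials belonging to one partition
#' @param dataset a partitioned `gait_dataset`.
#' @param part `"TRAIN"`, `"VAL"` or `"TEST"`.
#' @return list of `gait_trial`.
#' @export
partition_trials <- function(dataset, part) {
  if (is.null(dataset$partition)) stop_fmt("dataset has no partition; call split_dataset() first")
  dataset$trials[names(dataset$partition)[dataset$partition == part]]
}
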
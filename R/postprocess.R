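#' Post-processing configuration
#'
#' @param threshold probability threshold for peak detection, in (0, 1).
#'   Default 0.01: a peak in the per-frame event probability must exceed it
#'   to become an event.
#' @param min_separation minimum separation between events of the same
#'   class, in frames at 150 Hz (default 25, about 167 ms — well below any
#'   physiological same-side inter-event interval). Scaled by `fs / 150`
#'   when applied.
#' @return object of class `postprocess_config`.
#' @export
postprocess_config <- function(threshold = 0.01, min_separation = 25L) {
  if (threshold <= 0 || threshold >= 1) stop_fmt("threshold must be in (0,1)")
  if (min_separation < 1) stop_fmt("min_separation must be >= 1 frame")
  structure(list(threshold = threshold, min_separation = min_separation),
            class = "postprocess_config")
}

#' Turn per-frame class probabilities into discrete gait events
#'
#' For the left (column 2) and right (column 3) event classes
#' independently: find local maxima of the class probability strictly above
#' the threshold, then enforce the minimum separation by keeping the subset
#' of peaks that maximizes the total retained probability mass (weighted
#' interval scheduling; ties resolved towards lower frames). Plateau maxima
#' are attributed to their first frame.
#'
#' @param probs `T x 3` row-stochastic matrix (columns: none, left,
#'   right).
#' @param etype `"IC"` or `"FO"`, stamped on the returned events.
#' @param config a [postprocess_config()].
#' @param fs sampling rate in Hz, used to scale `min_separation`.
#' @return event `data.frame` (source `"MODEL"`) sorted by frame (0-based).
#' @export
detect_events <- function(probs, etype = c("IC", "FO"),
                          config = postprocess_config(), fs = 150) {
  etype <- match.arg(etype)
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop_fmt("probs must have 3 columns")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6) || any(probs < -1e-9)) {
    stop_fmt("probs rows must be probability distributions")
  }
  sep <- max(1L, as.integer(round(config$min_separation * fs / 150)))
  out <- list()
  for (cls in c(1L, 2L)) {
    side <- c("L", "R")[cls]
    peaks <- local_maxima(probs[, cls + 1L], threshold = config$threshold)
    if (length(peaks)) {
      keep <- select_peaks(peaks, probs[peaks, cls + 1L], sep)
      out[[side]] <- data.frame(etype = etype, side = side,
                                frame = keep - 1L, source = "MODEL",
                                stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(gait_events())
  }
  ev <- do.call(rbind, out)
  gait_events(ev$etype, ev$side, ev$frame, ev$source)
}

## Maximum-mass subset of peaks with pairwise separation >= sep frames.
## Classic weighted-interval DP over peaks sorted by frame; on equal mass
## the solution with lexicographically smallest frames wins.
select_peaks <- function(frames, heights, sep) {
  n <- length(frames)
  if (n == 0L) return(integer(0))
  ord <- order(frames)
  frames <- frames[ord]; heights <- heights[ord]
  best <- numeric(n + 1L)       # best[i+1]: max mass using peaks 1..i
  take <- logical(n)
  prev <- integer(n)            # last peak index compatible with peak i
  for (i in seq_len(n)) {
    p <- 0L
    for (j in seq_len(i - 1L)) if (frames[i] - frames[j] >= sep) p <- j
    prev[i] <- p
    with_i <- best[p + 1L] + heights[i]
    without_i <- best[i]
    # ties favour including the earlier structure; strict > keeps the
    # earliest-frame solution deterministic
    if (with_i > without_i) {
      best[i + 1L] <- with_i
      take[i] <- TRUE
    } else {
      best[i + 1L] <- without_i
    }
  }
  keep <- integer(0)
  i <- n
  while (i > 0L) {
    if (take[i]) {
      keep <- c(i, keep)
      i <- prev[i]
    } else {
      i <- i - 1L
    }
  }
  frames[keep]
}
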
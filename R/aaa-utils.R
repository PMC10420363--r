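## Internal helpers shared across modules.

MARKER_NAMES <- c("L_HEEL", "L_TOE", "L_ANKLE", "R_HEEL", "R_TOE", "R_ANKLE")
AXIS_NAMES <- c("AP", "ML", "V")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package internals never perturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Derive a stream-specific 31-bit sub-seed from a base seed, so independent
## stochastic stages never share a stream.
derive_seed <- function(seed, ...) {
  tags <- unlist(list(...))
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    for (ch in utf8ToInt(as.character(tag))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

## Centered moving average; partial windows at the ends (mean over the
## in-range part of the window). width is forced odd.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Frames of local minima of x, plateau-aware: a maximal run of equal values
## strictly lower than both neighbouring values counts once, at its first
## frame (1-based). Runs touching the sequence ends are kept if lower than
## their single interior neighbour.
local_minima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || runs$values[i - 1L] > runs$values[i]
    right_ok <- i == k || runs$values[i + 1L] > runs$values[i]
    if (left_ok && right_ok && !(i == 1L && i == k)) out <- c(out, starts[i])
  }
  out
}

## Frames of local maxima of x strictly above `threshold`; plateau-aware,
## ties to the first frame of the plateau (1-based).
local_maxima <- function(x, threshold = -Inf) {
  idx <- local_minima(-x)
  idx[x[idx] > threshold]
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
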
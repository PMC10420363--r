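#' Evaluation configuration
#'
#' Tolerance windows of the event-matching protocol: a prediction matched
#' within `tp_window` frames of a reference event is a true positive,
#' within `fp_window` frames a false positive, otherwise the reference
#' event is a false negative. At 150 Hz the defaults are +/-26.7 ms and
#' +/-333.3 ms.
#'
#' @param tp_window true-positive window in frames (default 4).
#' @param fp_window false-positive window in frames (default 50); must
#'   exceed `tp_window`.
#' @param count_spurious_fp logical; if `TRUE`, unmatched predictions are
#'   added to the false-positive count instead of being reported only as
#'   spurious (the stricter reading of "total number of predictions").
#' @return object of class `evaluation_config`.
#' @export
evaluation_config <- function(tp_window = 4L, fp_window = 50L,
                              count_spurious_fp = FALSE) {
  if (!(tp_window > 0 && tp_window < fp_window)) {
    stop_fmt("need 0 < tp_window < fp_window")
  }
  structure(list(tp_window = as.integer(tp_window),
                 fp_window = as.integer(fp_window),
                 count_spurious_fp = isTRUE(count_spurious_fp)),
            class = "evaluation_config")
}

#' Convert frames to milliseconds
#'
#' @param frames number of frames (real).
#' @param fs sampling rate in Hz; at 150 Hz one frame is 6.7 ms.
#' @return milliseconds.
#' @export
frames_to_ms <- function(frames, fs = 150) {
  if (any(fs <= 0)) stop_fmt("fs must be > 0")
  frames * 1000 / fs
}

#' Match predicted events against reference events
#'
#' One-to-one assignment of each reference (truth) event to a prediction
#' within `fp_window` frames, maximizing the number of matched pairs and,
#' among such assignments, minimizing the total absolute error (computed
#' by non-crossing dynamic programming over the two sorted streams, which
#' attains the optimum for absolute-difference costs on a line). A matched
#' pair with |error| <= `tp_window` is a TP, otherwise an FP; unmatched
#' reference events are FNs. Unmatched predictions are reported as
#' spurious and excluded from the three counts unless
#' `config$count_spurious_fp` is set.
#'
#' Both inputs must be single (etype, side) streams; mixing streams is an
#' error because sides never cross-match.
#'
#' @param predicted,truth event `data.frame`s (columns `etype`, `side`,
#'   `frame`, `source`) restricted to one event type and side.
#' @param config an [evaluation_config()].
#' @param fs sampling rate in Hz used to express errors in ms.
#' @return object of class `match_result`: list with `per_event` (one row
#'   per reference event: `truth_frame`, `outcome`, `matched_frame`,
#'   `signed_error_ms`, `abs_error_ms`, `abs_error_frames`), counts
#'   `n_tp`, `n_fp`, `n_fn`, `spurious` (unmatched predicted frames) and
#'   `fs`.
#' @export
match_events <- function(predicted, truth, config = evaluation_config(),
                         fs = 150) {
  for (ev in list(predicted, truth)) {
    if (nrow(ev)) {
      if (length(unique(ev$etype)) > 1L || length(unique(ev$side)) > 1L) {
        stop_fmt("match_events expects a single (etype, side) stream")
      }
      if (is.unsorted(ev$frame)) stop_fmt("event streams must be sorted by frame")
    }
  }
  tf <- truth$frame
  pf <- predicted$frame
  assign_ <- assign_events(tf, pf, config$fp_window)
  n <- length(tf)
  outcome <- rep("FN", n)
  matched_frame <- rep(NA_integer_, n)
  signed_err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- assign_[i]
    if (j > 0L) {
      err <- pf[j] - tf[i]
      matched_frame[i] <- pf[j]
      signed_err[i] <- err
      outcome[i] <- if (abs(err) <= config$tp_window) "TP" else "FP"
    }
  }
  per_event <- data.frame(
    truth_frame = tf, outcome = outcome, matched_frame = matched_frame,
    signed_error_ms = frames_to_ms(signed_err, fs),
    abs_error_ms = frames_to_ms(abs(signed_err), fs),
    abs_error_frames = abs(signed_err),
    stringsAsFactors = FALSE
  )
  spurious <- pf[!seq_along(pf) %in% assign_]
  n_fp <- sum(outcome == "FP")
  if (config$count_spurious_fp) n_fp <- n_fp + length(spurious)
  structure(list(per_event = per_event,
                 n_tp = sum(outcome == "TP"),
                 n_fp = n_fp,
                 n_fn = sum(outcome == "FN"),
                 spurious = spurious, fs = fs),
            class = "match_result")
}

## Optimal one-to-one assignment between sorted truth frames t and sorted
## predicted frames p with |t - p| <= window: maximize matched count, then
## minimize total |error|. Non-crossing DP; returns for each truth index
## the matched prediction index (0 = unmatched).
assign_events <- function(t, p, window) {
  n <- length(t); m <- length(p)
  if (n == 0L) return(integer(0))
  BIG <- (n + m + 1) * (window + 1)       # one match outweighs any error sum
  f <- matrix(0, n + 1L, m + 1L)          # score, higher is better
  for (i in seq_len(n)) {
    for (j in 0:m) {
      best <- f[i, j + 1L]                # truth i unmatched
      if (j > 0L) {
        best <- max(best, f[i + 1L, j])   # prediction j unused
        d <- abs(t[i] - p[j])
        if (d <= window) best <- max(best, f[i, j] + BIG - d)
      }
      f[i + 1L, j + 1L] <- best
    }
  }
  assign_ <- integer(n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    d <- abs(t[i] - p[j])
    if (d <= window && f[i + 1L, j + 1L] == f[i, j] + BIG - d) {
      assign_[i] <- j; i <- i - 1L; j <- j - 1L
    } else if (f[i + 1L, j + 1L] == f[i + 1L, j]) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  assign_
}

#' Pool several match results into one
#'
#' @param results list of `match_result` objects (same `fs`).
#' @return a single pooled `match_result`.
#' @export
pool_matches <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) stop_fmt("no match results to pool")
  structure(list(
    per_event = do.call(rbind, lapply(results, `[[`, "per_event")),
    n_tp = sum(vapply(results, `[[`, 0L, "n_tp")),
    n_fp = sum(vapply(results, `[[`, 0L, "n_fp")),
    n_fn = sum(vapply(results, `[[`, 0L, "n_fn")),
    spurious = unlist(lapply(results, `[[`, "spurious")),
    fs = results[[1L]]$fs
  ), class = "match_result")
}

#' Detection rate
#'
#' True positives divided by the total of true positives, false positives
#' and false negatives.
#'
#' @param result a `match_result` (possibly pooled).
#' @return fraction in \[0, 1\].
#' @export
detection_rate <- function(result) {
  denom <- result$n_tp + result$n_fp + result$n_fn
  if (denom == 0L) stop_fmt("no events to evaluate")
  result$n_tp / denom
}

#' Mean absolute temporal error with confidence interval
#'
#' MAE in ms over all matched events (TPs and FPs alike; FNs carry no
#' error and are excluded), with a 95% confidence interval of the mean by
#' seeded nonparametric bootstrap (default) or normal approximation.
#'
#' @param result a `match_result` (possibly pooled).
#' @param method `"bootstrap"` or `"normal"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list with `mae_ms`, `ci_low`, `ci_high`, `n`.
#' @export
temporal_error_summary <- function(result, method = c("bootstrap", "normal"),
                                   n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  err <- result$per_event$abs_error_ms[result$per_event$outcome != "FN"]
  n <- length(err)
  if (n == 0L) stop_fmt("no matched events; MAE undefined")
  mae <- mean(err)
  if (n == 1L) {
    ci <- c(mae, mae)
  } else if (method == "bootstrap") {
    means <- with_seed(derive_seed(seed, "boot"), {
      vapply(seq_len(n_boot),
             function(b) mean(err[sample.int(n, n, replace = TRUE)]), 0)
    })
    ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  } else {
    half <- stats::qnorm(0.975) * stats::sd(err) / sqrt(n)
    ci <- c(mae - half, mae + half)
  }
  list(mae_ms = mae, ci_low = ci[1L], ci_high = ci[2L], n = n)
}

#' Cumulative detection curve
#'
#' For each tolerance `w = 0..max_window` frames, the fraction of all
#' reference events (TP + FP + FN denominator) whose matched absolute
#' error is at most `w` frames. Nondecreasing in `w`; at `w = tp_window`
#' it equals the detection rate when no matched event lies beyond the
#' window.
#'
#' @param result a `match_result` (possibly pooled).
#' @param max_window largest tolerance in frames (default 4).
#' @return named numeric vector with one entry per window width 0, 1, ...,
#'   `max_window`.
#' @export
cumulative_detection_curve <- function(result, max_window = 4L) {
  denom <- result$n_tp + result$n_fp + result$n_fn
  if (denom == 0L) stop_fmt("no events to evaluate")
  fr <- result$per_event$abs_error_frames
  fr <- fr[!is.na(fr)]
  ws <- 0:max_window
  curve <- vapply(ws, function(w) sum(fr <= w) / denom, 0)
  names(curve) <- as.character(ws)
  curve
}

#' Paired nonparametric comparison of two methods
#'
#' The comparison protocol for per-event absolute errors of two methods on
#' the same events: Shapiro-Wilk normality tests are reported as an
#' informational gate, the hypothesis test is a two-sided Wilcoxon signed
#' rank test in normal approximation with tie correction (zero differences
#' dropped), the p-value is Bonferroni corrected by `n_comparisons`, and
#' the effect size is the Pearson r, `|Z| / sqrt(N)`, with `N` the number
#' of pairs.
#'
#' @param errors_a,errors_b equal-length paired numeric vectors.
#' @param n_comparisons Bonferroni factor (default 3: three pairwise
#'   method comparisons).
#' @return list with `n_pairs`, `n_nonzero`, `shapiro_p_a`, `shapiro_p_b`,
#'   `w_statistic` (sum of positive ranks), `z`, `p_value`, `p_corrected`,
#'   `effect_size_r` and `note`.
#' @export
compare_methods <- function(errors_a, errors_b, n_comparisons = 3L) {
  if (length(errors_a) != length(errors_b)) stop_fmt("paired samples differ in length")
  N <- length(errors_a)
  if (N < 5L) stop_fmt("need at least 5 pairs")
  shapiro_p <- function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  d <- errors_a - errors_b
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(list(n_pairs = N, n_nonzero = 0L,
                shapiro_p_a = shapiro_p(errors_a), shapiro_p_b = shapiro_p(errors_b),
                w_statistic = 0, z = 0, p_value = 1, p_corrected = 1,
                effect_size_r = 0, note = "no difference"))
  }
  r_abs <- rank(abs(nz))
  w_plus <- sum(r_abs[nz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r_abs)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(n_pairs = N, n_nonzero = n,
       shapiro_p_a = shapiro_p(errors_a), shapiro_p_b = shapiro_p(errors_b),
       w_statistic = w_plus, z = z, p_value = p,
       p_corrected = min(1, p * n_comparisons),
       effect_size_r = abs(z) / sqrt(N),
       note = "")
}

#' Sensitivity of a detector configuration to the training seed
#'
#' Retrains the same configuration under each seed and reports the test
#' MAE per seed together with their standard deviation, quantifying the
#' impact of random initialization (the clinical protocol uses ten seeds;
#' any number >= 1 is accepted).
#'
#' @param config a [detector_config()].
#' @param train,val,test lists of `gait_trial`.
#' @param seeds integer vector of training seeds.
#' @param post a [postprocess_config()].
#' @param eval_config an [evaluation_config()].
#' @return list with `table` (data.frame seed, mae_ms, detection_rate) and
#'   `sd_mae_ms`.
#' @export
seed_sensitivity <- function(config, train, val, test, seeds,
                             post = postprocess_config(),
                             eval_config = evaluation_config()) {
  if (length(seeds) < 1L) stop_fmt("need at least one seed")
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fit <- train_detector(train, etype = cfg$etype, config = cfg, val = val)
    res <- evaluate_detector(fit, test, post = post, eval_config = eval_config)
    data.frame(seed = s, mae_ms = res$mae_ms,
               detection_rate = res$detection_rate)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       sd_mae_ms = if (nrow(tab) > 1L) stats::sd(tab$mae_ms) else 0)
}
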
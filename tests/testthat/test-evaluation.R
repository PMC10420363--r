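test_that("frame-to-ms conversions match the 150 Hz protocol numbers", {
  expect_equal(round(frames_to_ms(1, 150), 1), 6.7)
  expect_equal(round(frames_to_ms(4, 150), 1), 26.7)
  expect_equal(round(frames_to_ms(50, 150), 1), 333.3)
  expect_equal(frames_to_ms(0, 97), 0)
  expect_error(frames_to_ms(1, 0), "fs must be")
})

ev_stream <- function(frames, etype = "IC", side = "L", source = "TRUTH") {
  gait_events(rep(etype, length(frames)), rep(side, length(frames)),
              frames, source)
}

test_that("matching classifies TP, FP and FN by the window rules", {
  cfg <- evaluation_config()
  tp <- match_events(ev_stream(103L, source = "MODEL"), ev_stream(100L), cfg, 150)
  expect_equal(tp$per_event$outcome, "TP")
  expect_equal(tp$per_event$signed_error_ms, 20)
  fp <- match_events(ev_stream(110L, source = "MODEL"), ev_stream(100L), cfg, 150)
  expect_equal(fp$per_event$outcome, "FP")
  expect_equal(round(fp$per_event$abs_error_ms, 1), 66.7)
  fn <- match_events(ev_stream(integer(0)), ev_stream(100L), cfg, 150)
  expect_equal(fn$per_event$outcome, "FN")
  expect_equal(fn$n_fn, 1L)
  # nearest assignment with the extra prediction reported as spurious
  two <- match_events(ev_stream(c(97L, 104L), source = "MODEL"),
                      ev_stream(100L), cfg, 150)
  expect_equal(two$per_event$outcome, "TP")
  expect_equal(two$per_event$matched_frame, 97L)
  expect_equal(two$spurious, 104L)
  expect_equal(two$n_fp, 0L)
  strict <- match_events(ev_stream(c(97L, 104L), source = "MODEL"),
                         ev_stream(100L),
                         evaluation_config(count_spurious_fp = TRUE), 150)
  expect_equal(strict$n_fp, 1L)
  mixed <- rbind(ev_stream(10L), ev_stream(20L, side = "R"))
  expect_error(match_events(mixed, ev_stream(10L)), "single")
})

test_that("n_tp + n_fn always equals the number of reference events", {
  set.seed(31)
  for (i in 1:100) {
    truth <- sort(sample(0:300, sample(0:6, 1)))
    pred <- sort(sample(0:300, sample(0:6, 1)))
    m <- match_events(ev_stream(pred, source = "MODEL"), ev_stream(truth))
    # every reference event receives exactly one outcome
    expect_equal(m$n_tp + m$n_fp + m$n_fn, length(truth))
    expect_equal(nrow(m$per_event), length(truth))
  }
})

test_that("assignment equals the brute-force optimum on small instances", {
  set.seed(77)
  for (i in 1:150) {
    truth <- sort(sample(0:120, sample(1:6, 1)))
    pred <- sort(sample(0:120, sample(0:6, 1)))
    m <- match_events(ev_stream(pred, source = "MODEL"), ev_stream(truth),
                      evaluation_config(), 150)
    matched <- !is.na(m$per_event$abs_error_frames)
    got <- c(sum(matched), sum(m$per_event$abs_error_frames[matched]))
    expect_equal(got, brute_match_value(truth, pred, 50))
  }
})

test_that("detection rate follows TP / (TP + FP + FN)", {
  mk <- function(tp, fp, fn) {
    structure(list(per_event = data.frame(), n_tp = tp, n_fp = fp, n_fn = fn,
                   spurious = integer(0), fs = 150), class = "match_result")
  }
  expect_equal(detection_rate(mk(3L, 1L, 0L)), 0.75)
  expect_equal(detection_rate(mk(7L, 0L, 0L)), 1)
  expect_equal(detection_rate(mk(0L, 0L, 5L)), 0)
  expect_error(detection_rate(mk(0L, 0L, 0L)), "no events")
})

test_that("widening the TP window never lowers the detection rate", {
  set.seed(41)
  truth <- sort(sample(0:500, 12))
  pred <- sort(truth + sample(-8:8, 12, replace = TRUE))
  rates <- vapply(1:10, function(w) {
    detection_rate(match_events(ev_stream(pred, source = "MODEL"),
                                ev_stream(truth),
                                evaluation_config(tp_window = w)))
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("temporal error summary reproduces hand-computed MAE and a sane CI", {
  res <- match_events(ev_stream(c(100L, 201L, 302L), source = "MODEL"),
                      ev_stream(c(100L, 200L, 300L)), fs = 150)
  summ <- temporal_error_summary(res, seed = 2)
  expect_equal(round(summ$mae_ms, 2), round(mean(c(0, 6.7, 13.3)), 2),
               tolerance = 1e-2)
  expect_equal(summ$n, 3L)
  single <- temporal_error_summary(
    match_events(ev_stream(101L, source = "MODEL"), ev_stream(100L), fs = 150))
  expect_equal(single$ci_low, single$mae_ms)
  expect_equal(single$ci_high, single$mae_ms)
  # bootstrap CI brackets the sample MAE on a larger sample
  set.seed(7)
  truth <- sort(sample(seq(0, 5000, by = 40), 100))
  pred <- truth + sample(-4:4, 100, replace = TRUE)
  big <- match_events(ev_stream(pred, source = "MODEL"), ev_stream(truth), fs = 150)
  bs <- temporal_error_summary(big, seed = 3)
  expect_lte(bs$ci_low, bs$mae_ms)
  expect_gte(bs$ci_high, bs$mae_ms)
  nrm <- temporal_error_summary(big, method = "normal")
  expect_lt(abs(nrm$mae_ms - bs$mae_ms), 1e-12)
  expect_error(temporal_error_summary(
    match_events(ev_stream(integer(0)), ev_stream(100L))), "no matched")
})

test_that("cumulative detection curves are correct and monotone", {
  truth <- c(100L, 200L, 300L, 400L)
  pred <- c(100L, 201L, 301L, 403L)
  res <- match_events(ev_stream(pred, source = "MODEL"), ev_stream(truth), fs = 150)
  curve <- cumulative_detection_curve(res)
  expect_equal(unname(curve), c(0.25, 0.75, 0.75, 1, 1))
  expect_true(all(diff(curve) >= 0))
  # random cross-check against detection_rate at the TP window
  set.seed(17)
  for (i in 1:25) {
    tf <- sort(sample(seq(30, 2000, by = 30), 15))
    pf <- tf + sample(-3:3, 15, replace = TRUE)
    r <- match_events(ev_stream(pf, source = "MODEL"), ev_stream(tf), fs = 150)
    expect_equal(unname(cumulative_detection_curve(r)["4"]), detection_rate(r))
  }
})

test_that("method comparison reproduces a hand-computed signed-rank test", {
  # 12 paired absolute errors, hand-built without ties among |differences|
  a <- c(5.1, 7.2, 3.3, 9.8, 6.0, 4.4, 8.1, 2.2, 7.7, 5.5, 6.6, 3.9)
  b <- c(6.3, 6.1, 5.0, 9.0, 7.9, 4.0, 9.9, 3.5, 7.0, 8.0, 6.2, 5.6)
  cmp <- compare_methods(a, b, n_comparisons = 3)
  # independent rank arithmetic
  d <- a - b
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  n <- length(d)
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (w_plus - mu) / sigma
  p <- 2 * pnorm(-abs(z))
  expect_equal(cmp$w_statistic, w_plus, tolerance = 1e-8)
  expect_equal(cmp$z, z, tolerance = 1e-8)
  expect_equal(cmp$p_value, p, tolerance = 1e-8)
  expect_equal(cmp$p_corrected, min(1, 3 * p), tolerance = 1e-8)
  expect_equal(cmp$effect_size_r, abs(z) / sqrt(12), tolerance = 1e-8)
  # agreement with the reference implementation (normal approximation)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("method comparison handles degenerate inputs", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- compare_methods(x, x)
  expect_equal(same$effect_size_r, 0)
  expect_equal(same$p_corrected, 1)
  expect_equal(same$note, "no difference")
  expect_error(compare_methods(1:6, 1:5), "differ in length")
  expect_error(compare_methods(1:4, 2:5), "at least 5")
  # Bonferroni scaling: p_corrected = 3 * p (capped at 1)
  set.seed(9)
  aa <- runif(20); bb <- aa + rnorm(20, 0.05, 0.02)
  cc <- compare_methods(aa, bb)
  expect_equal(cc$p_corrected, min(1, 3 * cc$p_value))
})
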
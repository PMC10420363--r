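tiny_config <- function(etype = "IC", ...) {
  detector_config(etype, n_layers = 1L, hidden_units = 8L, dropout = 0,
                  weight_ratio = 10, epochs = 3L, batch_size = 4L, seed = 42L,
                  ...)
}

test_that("configuration bounds are enforced and defaults match the protocol", {
  dflt <- detector_config("IC")
  expect_equal(dflt$n_layers, 3L)
  expect_equal(dflt$hidden_units, 200L)
  expect_equal(dflt$dropout, 0.4)
  expect_equal(dflt$weight_ratio, 10)
  expect_error(detector_config("IC", n_layers = 0), "n_layers")
  expect_error(detector_config("IC", dropout = 1), "dropout")
  expect_error(detector_config("IC", weight_ratio = 0.3), "weight_ratio")
})

test_that("an initialized model is row-stochastic and seed-deterministic", {
  m1 <- build_detector(tiny_config(), n_channels = 36L)
  m2 <- build_detector(tiny_config(), n_channels = 36L)
  expect_identical(m1$params, m2$params)
  m3 <- build_detector(detector_config("IC", n_layers = 1, hidden_units = 8,
                                       seed = 43), n_channels = 36L)
  expect_false(identical(m1$params, m3$params))

  X <- matrix(runif(30 * 36), 30, 36)
  tensor <- structure(list(values = X, mask = rep(TRUE, 30),
                           channel_names = sprintf("c%02d", 1:36),
                           fs = 150, trial_id = "x"),
                      class = "feature_tensor")
  p <- predict_probabilities(m1, tensor)
  expect_equal(dim(p), c(30L, 3L))
  expect_equal(unname(rowSums(p)), rep(1, 30), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # inference is deterministic on repeat
  expect_identical(p, predict_probabilities(m1, tensor))
  expect_error(predict_probabilities(m1, structure(list(
    values = X[, 1:10], mask = rep(TRUE, 30), channel_names = sprintf("c%d", 1:10),
    fs = 150, trial_id = "x"), class = "feature_tensor")), "channel count")
})

test_that("the loss is the sample-weighted mean cross-entropy", {
  # hand-computed 3-frame oracle with weights (1, 10, 1)
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.25, 0.5, 0.25))
  classes <- c(0L, 1L, 2L)
  weights <- c(1, 10, 1)
  hand <- (1 * -log(0.7) + 10 * -log(0.8) + 1 * -log(0.25)) / 12
  expect_equal(weighted_cross_entropy(probs, classes, weights), hand,
               tolerance = 1e-12)
  # the C++ path computes the same formula on its own forward probabilities
  m <- build_detector(tiny_config(), n_channels = 4L)
  X <- matrix(runif(15 * 4), 15, 4)
  cls <- sample(0:2, 15, replace = TRUE)
  w <- ifelse(cls > 0, 10, 1)
  res <- gaitevents:::cpp_bilstm_run(m$params, X, as.integer(cls), w,
                                     1L, 8L, 0, FALSE, FALSE)
  expect_equal(res$loss, weighted_cross_entropy(res$probs, cls, w),
               tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(3)
  cfg <- detector_config("IC", n_layers = 2, hidden_units = 4, dropout = 0,
                         seed = 7)
  m <- build_detector(cfg, n_channels = 5L)
  X <- matrix(runif(10 * 5), 10, 5)
  cls <- sample(0:2, 10, replace = TRUE)
  w <- ifelse(cls > 0, 10, 1)
  g <- gaitevents:::cpp_bilstm_run(m$params, X, as.integer(cls), w,
                                   2L, 4L, 0, FALSE, TRUE)
  eps <- 1e-6
  for (nm in c("W1f", "U2b", "b1b", "Wo", "bo")) {
    idx <- sample(length(m$params[[nm]]), 3)
    for (i in idx) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (gaitevents:::cpp_bilstm_run(up, X, as.integer(cls), w, 2L, 4L, 0, FALSE, FALSE)$loss -
             gaitevents:::cpp_bilstm_run(dn, X, as.integer(cls), w, 2L, 4L, 0, FALSE, FALSE)$loss) / (2 * eps)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("right-padding is invisible to loss and predictions (masking)", {
  trials <- cached("detector_trials", {
    ds <- mixed_cohort(3, 2, seed = 55, duration_s = 5)
    unname(ds$trials)
  })
  batch <- prepare_batch(trials, "IC", seed = 1)
  model <- build_detector(tiny_config(), n_channels = 36L)
  loss0 <- detector_loss(model, batch)

  padded <- batch
  extra <- 20L
  d <- dim(batch$values)
  padded$values <- array(0, dim = d + c(0, extra, 0))
  padded$values[, seq_len(d[2]), ] <- batch$values
  padded$mask <- cbind(batch$mask, matrix(FALSE, d[1], extra))
  padded$classes <- cbind(batch$classes, matrix(0L, d[1], extra))
  padded$weights <- cbind(batch$weights, matrix(0, d[1], extra))
  expect_equal(detector_loss(model, padded), loss0, tolerance = 1e-6)

  tensor <- structure(list(values = batch$values[1, seq_len(batch$lengths[1]), ],
                           mask = rep(TRUE, batch$lengths[1]),
                           channel_names = sprintf("c%02d", 1:36),
                           fs = 150, trial_id = "t"), class = "feature_tensor")
  p0 <- predict_probabilities(model, tensor)
  tensor_pad <- tensor
  tensor_pad$values <- rbind(tensor$values, matrix(0, extra, 36))
  tensor_pad$mask <- c(tensor$mask, rep(FALSE, extra))
  p1 <- predict_probabilities(model, tensor_pad)
  expect_equal(p1[seq_len(nrow(p0)), ], p0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(is.na(p1[nrow(p0) + seq_len(extra), ])))
  expect_true(all(attr(p1, "masked")[nrow(p0) + seq_len(extra)]))
})

test_that("training reduces the loss and is seed-reproducible", {
  trials <- cached("detector_trials", {
    ds <- mixed_cohort(3, 2, seed = 55, duration_s = 5)
    unname(ds$trials)
  })
  fit1 <- train_detector(trials, config = tiny_config())
  expect_lt(fit1$history$train_loss[nrow(fit1$history)],
            fit1$history$train_loss[1])
  fit2 <- train_detector(trials, config = tiny_config())
  expect_identical(fit1$params, fit2$params)
  expect_error(train_detector(list(), config = tiny_config()), "empty")
})

test_that("the full hyperparameter space enumerates to 252 combinations", {
  expect_equal(nrow(enumerate_grid(grid_space())), 3L * 7L * 3L * 4L)
  expect_equal(nrow(enumerate_grid(grid_space())), 252L)
  expect_error(grid_space(n_layers = integer(0)), "empty grid")
})

test_that("grid search ranks a sane configuration above a crippled one", {
  ds <- cached("grid_cohort", mixed_cohort(4, 2, seed = 66, duration_s = 5))
  ds <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 66)
  train <- partition_trials(ds, "TRAIN")
  val <- partition_trials(ds, "VAL")
  # same model except for an absurd event weight that swamps the loss
  space <- grid_space(n_layers = 1L, hidden_units = 16L, dropout = 0,
                      weight_ratio = c(10, 100000))
  base <- detector_config("IC", epochs = 25L, batch_size = 2L,
                          learning_rate = 5e-3, seed = 5L)
  strict <- evaluation_config(count_spurious_fp = TRUE)
  gs <- grid_search(space, train, val, etype = "IC", base_config = base,
                    eval_config = strict)
  expect_equal(nrow(gs$leaderboard), 2L)
  expect_equal(gs$best_config$weight_ratio, 10)
  # deterministic on repeat
  gs2 <- grid_search(space, train, val, etype = "IC", base_config = base,
                     eval_config = strict)
  expect_identical(gs$leaderboard, gs2$leaderboard)
})

test_that("seed sensitivity reports one MAE per seed with a finite spread", {
  ds <- cached("grid_cohort", mixed_cohort(4, 2, seed = 66, duration_s = 5))
  ds <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 66)
  cfg <- detector_config("IC", n_layers = 1, hidden_units = 16, dropout = 0,
                         epochs = 6L, batch_size = 4L)
  sens <- seed_sensitivity(cfg, partition_trials(ds, "TRAIN"),
                           partition_trials(ds, "VAL"),
                           partition_trials(ds, "TEST"), seeds = c(1L, 2L))
  expect_equal(nrow(sens$table), 2L)
  expect_true(is.finite(sens$sd_mae_ms))
  one <- seed_sensitivity(cfg, partition_trials(ds, "TRAIN"),
                          partition_trials(ds, "VAL"),
                          partition_trials(ds, "TEST"), seeds = 1L)
  expect_equal(one$sd_mae_ms, 0)
  expect_equal(one$table$mae_ms[1], sens$table$mae_ms[1])
})
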
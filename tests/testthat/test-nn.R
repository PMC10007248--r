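test_that("stick-breaking probabilities follow the telescoping formula", {
  expect_equal(stick_breaking_probs(c(0, 0, 0)),
               c(0.5, 0.25, 0.125, 0.125), tolerance = 1e-12)
  # saturation: a huge first break puts all mass on class 0
  expect_equal(stick_breaking_probs(c(30, 0, 0)),
               c(1, 0, 0, 0), tolerance = 1e-9)
  set.seed(1)
  R <- matrix(rnorm(500 * 3, sd = 3), 500, 3)
  P <- stick_breaking_probs(R)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
})

test_that("stick-breaking is monotone in the first break", {
  set.seed(2)
  for (i in 1:50) {
    raw <- rnorm(3)
    p_lo <- stick_breaking_probs(raw)
    p_hi <- stick_breaking_probs(raw + c(0.5, 0, 0))
    expect_gt(p_hi[1], p_lo[1])
    expect_true(all(p_hi[2:4] <= p_lo[2:4] + 1e-12))
  }
})

test_that("analytic gradients match numerical gradients", {
  set.seed(42)
  x <- matrix(rnorm(5 * 3), 5, 3)
  y <- c(0L, 1L, 2L, 3L, 1L)
  xs <- lapply(1:4, function(i) matrix(rnorm(16 * 3), 16, 3))
  ys <- 0:3
  cases <- list(
    model_config("mlp", 3, hidden_layers = c(6, 5),
                 use_stick_breaking = FALSE, seed = 7),
    model_config("mlp", 3, hidden_layers = 4,
                 use_stick_breaking = TRUE, seed = 3),
    model_config("cnn", c(16, 3), conv_blocks = 2, kernel_size = 3,
                 n_filters = 4, hidden_layers = 5, seed = 5),
    model_config("cnn_lstm", c(16, 3), conv_blocks = 1, kernel_size = 3,
                 n_filters = 4, lstm_units = 6, hidden_layers = 5, seed = 9),
    model_config("cnn", c(16, 3), conv_blocks = 1, kernel_size = 5,
                 n_filters = 4, hidden_layers = 5, input_decimation = 2,
                 seed = 2))
  for (cfg in cases) {
    inp <- if (cfg$model_family == "mlp") x else xs
    lab <- if (cfg$model_family == "mlp") y else ys
    expect_lt(grad_check_max_rel(cfg, inp, lab), 1e-4)
  }
})

test_that("built models emit valid probability vectors", {
  cfg <- model_config("mlp", 3, hidden_layers = c(20, 20),
                      use_stick_breaking = FALSE, seed = 1)
  m <- build_model(cfg)
  p <- predict_proba(m, c(0.1, -0.5, 2))
  expect_equal(dim(p), c(1L, 4L))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # counting MLP with one 30-unit layer builds and predicts
  m30 <- build_model(model_config("mlp", 3, hidden_layers = 30L, seed = 2))
  expect_equal(sum(predict_proba(m30, c(1, 2, 3))), 1, tolerance = 1e-9)
  # untrained stick-breaking sequence model sums to 1 too
  mc <- build_model(model_config("cnn", c(32, 14), conv_blocks = 1,
                                 n_filters = 4, hidden_layers = 8, seed = 3))
  expect_equal(sum(predict_proba(mc, matrix(rnorm(32 * 14), 32, 14))), 1,
               tolerance = 1e-9)
})

test_that("identical config and seed give identical initial parameters", {
  cfg <- model_config("cnn_lstm", c(16, 4), conv_blocks = 1, n_filters = 4,
                      lstm_units = 5, hidden_layers = 6, seed = 123)
  expect_identical(build_model(cfg)$layers, build_model(cfg)$layers)
  cfg2 <- cfg; cfg2$seed <- 124L
  expect_false(identical(build_model(cfg)$layers, build_model(cfg2)$layers))
})

test_that("the hyperparameter grid restriction is enforced", {
  expect_error(model_config("cnn", c(16, 3), learning_rate = 0.005,
                            grid_check = TRUE))
  expect_silent(model_config("cnn", c(16, 3), learning_rate = 0.001,
                             kernel_size = 5, n_filters = 32,
                             hidden_layers = 64L, grid_check = TRUE))
})

test_that("early stopping halts after patience non-improving epochs", {
  # loss improves up to epoch 5, then plateaus: stop lands on epoch 25
  losses <- c(seq(1.0, 0.6, length.out = 5), rep(0.6, 95))
  st <- early_stop_init(patience = 20L)
  halted_at <- NA_integer_
  for (e in seq_along(losses)) {
    st <- early_stop_update(st, losses[e], e)
    if (st$stop) { halted_at <- e; break }
  }
  expect_identical(halted_at, 25L)
  expect_identical(st$best_epoch, 5L)
})

test_that("training drives a separable toy problem to perfect accuracy", {
  set.seed(1)
  n <- 40
  x <- rbind(matrix(rnorm(n * 3, -2), n, 3), matrix(rnorm(n * 3, 2), n, 3))
  y <- rep(c(0L, 2L), each = n)
  cfg <- model_config("mlp", 3, hidden_layers = c(20, 20),
                      use_stick_breaking = FALSE, learning_rate = 0.001,
                      max_epochs = 150, seed = 11)
  vidx <- c(1:5, n + 1:5)
  fit <- train_model(build_model(cfg), x, y, x[vidx, ], y[vidx])
  expect_equal(voxmmrc:::model_accuracy(fit$model, x, y), 1)
  # deterministic retrain
  fit2 <- train_model(build_model(cfg), x, y, x[vidx, ], y[vidx])
  expect_identical(fit$model$layers, fit2$model$layers)
})

test_that("a stick-breaking head also learns ordinal structure", {
  set.seed(3)
  n <- 30
  x <- do.call(rbind, lapply(0:3, function(k) matrix(rnorm(n * 2, 2 * k),
                                                     n, 2)))
  y <- rep(0:3, each = n)
  cfg <- model_config("mlp", 2, hidden_layers = 16,
                      use_stick_breaking = TRUE, learning_rate = 0.01,
                      max_epochs = 120, seed = 5)
  fit <- train_model(build_model(cfg), x, y, x, y)
  expect_gt(voxmmrc:::model_accuracy(fit$model, x, y), 0.8)
})

test_that("batch prediction equals per-item prediction", {
  cfg <- model_config("cnn", c(16, 3), conv_blocks = 1, n_filters = 4,
                      hidden_layers = 6, seed = 8)
  m <- build_model(cfg)
  xs <- lapply(1:5, function(i) matrix(rnorm(16 * 3), 16, 3))
  batch <- predict_proba(m, xs)
  single <- t(sapply(xs, function(xi) predict_proba(m, list(xi))))
  expect_equal(batch, single, tolerance = 1e-12)
})
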
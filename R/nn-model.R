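#' Stick-breaking ordinal probabilities
#'
#' Converts K-1 = 3 raw activations into a 4-class probability vector by
#' sequentially breaking the remaining probability mass with sigmoid
#' "breaks": with `s_k = sigmoid(raw_k)`,
#' `p_0 = s_0`, `p_1 = s_1 (1 - s_0)`, `p_2 = s_2 (1 - s_0)(1 - s_1)`,
#' `p_3 = (1 - s_0)(1 - s_1)(1 - s_2)`. The components sum to 1 exactly by
#' the telescoping construction, and the parameterization respects the
#' ordering of the mMRC classes.
#'
#' @param raw numeric vector of 3 finite reals, or an n x 3 matrix.
#' @return probability vector of length 4, or an n x 4 matrix.
#' @export
stick_breaking_probs <- function(raw) {
  if (is.null(dim(raw))) {
    stopifnot(length(raw) == 3, all(is.finite(raw)))
    s <- sigmoid(raw)
    p <- c(s[1],
           s[2] * (1 - s[1]),
           s[3] * (1 - s[1]) * (1 - s[2]),
           (1 - s[1]) * (1 - s[2]) * (1 - s[3]))
    return(p)
  }
  stopifnot(ncol(raw) == 3, all(is.finite(raw)))
  s <- sigmoid(raw)
  cbind(s[, 1],
        s[, 2] * (1 - s[, 1]),
        s[, 3] * (1 - s[, 1]) * (1 - s[, 2]),
        (1 - s[, 1]) * (1 - s[, 2]) * (1 - s[, 3]))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

GRID_LR <- c(0.1, 0.01, 0.001, 0.0001)
GRID_KERNEL <- c(3L, 5L, 7L)
GRID_FILTERS <- c(16L, 32L, 64L, 128L)
GRID_HIDDEN <- c(10L, 16L, 20L, 30L, 32L, 40L, 50L, 60L, 64L, 128L, 256L)

#' Neural classifier configuration
#'
#' Describes one of the three model families: `mlp` for the 3-dimensional
#' time-independent features, `cnn` (1-d convolutions over time, Mel
#' energies as channels) for /ae-ae/ and /sa-sa/ spectral features, and
#' `cnn_lstm` (convolutional front end followed by an LSTM whose last state
#' is read out) for the counting vocalization. `use_stick_breaking` selects
#' the ordinal output head; otherwise a plain 4-way softmax is used.
#'
#' @param model_family `"mlp"`, `"cnn"` or `"cnn_lstm"`.
#' @param input_shape integer: feature dimension for `mlp`; `c(frames,
#'   dim)` for the sequence families.
#' @param hidden_layers widths of the fully connected layers before the
#'   output head.
#' @param conv_blocks number of [conv x 2 + max-pool] blocks.
#' @param kernel_size odd convolution kernel width (frames).
#' @param n_filters convolution filters per layer.
#' @param lstm_units LSTM state dimension (`cnn_lstm` only).
#' @param input_decimation average-pool width applied to the input frames
#'   before the first convolution (1 = none); coarsens the time axis.
#' @param learning_rate Adam learning rate.
#' @param use_stick_breaking use the ordinal stick-breaking head.
#' @param max_epochs epoch cap (safety bound).
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param seed weight-initialization seed.
#' @param grid_check restrict tunable values to the hyperparameter search
#'   grid (learning rate in 0.1/0.01/0.001/0.0001, kernel in 3/5/7,
#'   filters in 16/32/64/128).
#' @return object of class `model_config`.
#' @export
model_config <- function(model_family = c("mlp", "cnn", "cnn_lstm"),
                         input_shape,
                         hidden_layers = 64L,
                         conv_blocks = 3L,
                         kernel_size = 5L,
                         n_filters = 32L,
                         lstm_units = 64L,
                         input_decimation = 1L,
                         learning_rate = NULL,
                         use_stick_breaking = NULL,
                         max_epochs = 500L,
                         batch_size = 32L,
                         patience = 20L,
                         seed = 1L,
                         grid_check = FALSE) {
  model_family <- match.arg(model_family)
  if (is.null(use_stick_breaking)) {
    use_stick_breaking <- model_family != "mlp"
  }
  if (is.null(learning_rate)) {
    learning_rate <- if (model_family == "mlp") 0.001 else 0.0001
  }
  if (grid_check) {
    stopifnot(learning_rate %in% GRID_LR,
              kernel_size %in% GRID_KERNEL,
              n_filters %in% GRID_FILTERS,
              all(hidden_layers %in% GRID_HIDDEN))
  }
  stopifnot(kernel_size %% 2 == 1, conv_blocks >= 1, n_filters >= 1,
            lstm_units >= 1, input_decimation >= 1, learning_rate > 0,
            max_epochs >= 1, batch_size >= 1, patience >= 1)
  structure(list(
    model_family = model_family,
    input_shape = as.integer(input_shape),
    hidden_layers = as.integer(hidden_layers),
    conv_blocks = as.integer(conv_blocks),
    kernel_size = as.integer(kernel_size),
    n_filters = as.integer(n_filters),
    lstm_units = as.integer(lstm_units),
    input_decimation = as.integer(input_decimation),
    learning_rate = learning_rate,
    use_stick_breaking = isTRUE(use_stick_breaking),
    max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Build a trainable classifier from a configuration
#'
#' Initial weights (Glorot uniform) are a pure function of `config$seed`.
#'
#' @param config a [model_config()].
#' @return object of class `voc_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  head_dim <- if (config$use_stick_breaking) 3L else 4L
  with_seed(config$seed, {
    layers <- list()
    if (config$model_family == "mlp") {
      d <- config$input_shape[1]
      for (h in config$hidden_layers) {
        layers <- c(layers, list(layer_dense(d, h), layer_relu()))
        d <- h
      }
      layers <- c(layers, list(layer_dense(d, head_dim)))
    } else {
      T_ <- config$input_shape[1]
      d <- config$input_shape[2]
      if (config$input_decimation > 1L) {
        layers <- c(layers, list(layer_avgpool(config$input_decimation)))
        T_ <- T_ %/% config$input_decimation
      }
      for (b in seq_len(config$conv_blocks)) {
        layers <- c(layers, list(
          layer_conv1d(d, config$n_filters, config$kernel_size),
          layer_relu(),
          layer_conv1d(config$n_filters, config$n_filters,
                       config$kernel_size),
          layer_relu(),
          layer_maxpool()))
        d <- config$n_filters
        T_ <- T_ %/% 2L
      }
      if (T_ < 1L) stop("too many pooling stages for the input length")
      if (config$model_family == "cnn") {
        layers <- c(layers, list(layer_flatten()))
        d <- T_ * d
      } else {
        layers <- c(layers, list(layer_lstm_last(d, config$lstm_units)))
        d <- config$lstm_units
      }
      for (h in config$hidden_layers) {
        layers <- c(layers, list(layer_dense(d, h), layer_relu()))
        d <- h
      }
      layers <- c(layers, list(layer_dense(d, head_dim)))
    }
    structure(list(config = config, layers = layers, n_classes = 4L),
              class = "voc_model")
  })
}

# coerce user input (matrix / vector / list of matrices / array) to the
# representation the first layer expects
as_model_input <- function(model, x) {
  if (model$config$model_family == "mlp") {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    stopifnot(ncol(x) == model$config$input_shape[1])
    return(x)
  }
  if (is.list(x) && !is.data.frame(x)) return(seq_batch(x))
  if (is.array(x) && length(dim(x)) == 3) {
    return(seq_batch(lapply(seq_len(dim(x)[1]), function(i) x[i, , ])))
  }
  if (is.matrix(x)) return(seq_batch(list(x)))
  stop("unsupported input for sequence model")
}

model_forward <- function(model, x, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x)
    x <- r$out
    if (keep_caches) caches[[i]] <- r$cache
  }
  probs <- if (model$config$use_stick_breaking) {
    stick_breaking_probs(x)
  } else {
    softmax_rows(x)
  }
  list(raw = x, probs = probs, caches = caches)
}

# cross-entropy loss and gradient w.r.t. the head's raw activations
head_loss_grad <- function(model, raw, probs, y) {
  n <- nrow(probs)
  iy <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[iy], 1e-12)))
  if (model$config$use_stick_breaking) {
    s <- sigmoid(raw)
    draw <- matrix(0, n, 3L)
    for (j in 1:3) {
      # d(-log p_y)/d raw_j: s_j for breaks consumed before class y,
      # -(1 - s_j) at the class's own break, 0 beyond it
      contrib <- ifelse(y + 1L > j, s[, j], 0)
      contrib[y + 1L == j] <- -(1 - s[y + 1L == j, j])
      draw[, j] <- contrib
    }
    draw <- draw / n
  } else {
    onehot <- matrix(0, n, 4L)
    onehot[iy] <- 1
    draw <- (probs - onehot) / n
  }
  list(loss = loss, draw = draw)
}

model_backward <- function(model, caches, draw) {
  grads <- vector("list", length(model$layers))
  d <- draw
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], d, caches[[i]])
    grads[[i]] <- r$grads
    d <- r$dx
  }
  grads
}

#' Predict class probabilities
#'
#' @param model a `voc_model`.
#' @param x features: a matrix (rows = observations) for `mlp`; a list of
#'   equally sized frames-by-dim matrices, a single matrix, or an
#'   n x frames x dim array for the sequence families.
#' @return n x 4 matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "voc_model"))
  model_forward(model, as_model_input(model, x))$probs
}

#' @export
predict.voc_model <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  max.col(p, ties.method = "first") - 1L
}

model_loss <- function(model, x, y) {
  f <- model_forward(model, x)
  head_loss_grad(model, f$raw, f$probs, y)$loss
}

model_accuracy <- function(model, x, y) {
  p <- model_forward(model, x)$probs
  mean((max.col(p, ties.method = "first") - 1L) == y)
}

## ---- early stopping ----

#' Early-stopping state machine
#'
#' Tracks the best validation loss seen so far; signals a stop after
#' `patience` consecutive epochs without improvement. Kept as a standalone
#' pure function so the stopping mechanics can be verified independently of
#' any actual training.
#'
#' @param patience non-improving epochs tolerated before stopping.
#' @return state list; update with [early_stop_update()].
#' @export
early_stop_init <- function(patience = 20L) {
  list(patience = as.integer(patience), best_loss = Inf, best_epoch = 0L,
       wait = 0L, stop = FALSE)
}

#' @rdname early_stop_init
#' @param state state from [early_stop_init()] / previous update.
#' @param loss validation loss of the epoch just finished.
#' @param epoch epoch number.
#' @export
early_stop_update <- function(state, loss, epoch) {
  if (loss < state$best_loss) {
    state$best_loss <- loss
    state$best_epoch <- as.integer(epoch)
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$stop <- state$wait >= state$patience
  state
}

#' Train a classifier with Adam, cross-entropy and early stopping
#'
#' Minimizes cross-entropy on the composed class probabilities with the
#' Adam optimizer. Training stops when the validation-1 loss has not
#' improved for `patience` consecutive epochs (or at the epoch cap) and the
#' parameters of the best validation epoch are restored. Fully
#' reproducible: minibatch order derives from `seed`.
#'
#' @param model a `voc_model` from [build_model()].
#' @param x_train,y_train training features and integer labels in 0..3.
#' @param x_val,y_val validation-1 features/labels (loss monitored here).
#' @param learning_rate,patience,max_epochs,batch_size override the values
#'   in the model's config.
#' @param seed minibatch shuffling seed (defaults to config seed).
#' @return list with `model` (best weights restored) and `history`
#'   (train/val loss per epoch, `best_epoch`, `stopped_epoch`).
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        learning_rate = NULL, patience = NULL,
                        max_epochs = NULL, batch_size = NULL, seed = NULL) {
  stopifnot(inherits(model, "voc_model"),
            length(y_train) >= 1, length(y_val) >= 1,
            all(y_train %in% 0:3), all(y_val %in% 0:3))
  cfg <- model$config
  lr <- learning_rate %||% cfg$learning_rate
  patience <- patience %||% cfg$patience
  max_epochs <- max_epochs %||% cfg$max_epochs
  batch_size <- batch_size %||% cfg$batch_size
  seed <- seed %||% cfg$seed

  is_seq <- cfg$model_family != "mlp"
  n <- if (is_seq) length(x_train) else nrow(x_train)
  stopifnot(n == length(y_train))
  take <- function(x, idx) if (is_seq) x[idx] else x[idx, , drop = FALSE]
  xv <- as_model_input(model, x_val)

  state <- adam_init(model$layers)
  es <- early_stop_init(patience)
  best_layers <- model$layers
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  t_adam <- 0L
  stopped <- max_epochs

  with_seed(derive_seed(seed, "shuffle"), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        xb <- as_model_input(model, take(x_train, idx))
        yb <- y_train[idx]
        f <- model_forward(model, xb, keep_caches = TRUE)
        hl <- head_loss_grad(model, f$raw, f$probs, yb)
        if (!is.finite(hl$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; try a lower learning rate")
        }
        grads <- model_backward(model, f$caches, hl$draw)
        t_adam <- t_adam + 1L
        r <- adam_step(model$layers, grads, state, lr, t_adam)
        model$layers <- r$layers
        state <- r$state
        ep_loss <- ep_loss + hl$loss
        n_batches <- n_batches + 1L
      }
      val_f <- model_forward(model, xv)
      val_loss <- head_loss_grad(model, val_f$raw, val_f$probs, y_val)$loss
      hist_train <- c(hist_train, ep_loss / n_batches)
      hist_val <- c(hist_val, val_loss)
      es <- early_stop_update(es, val_loss, epoch)
      if (es$wait == 0L) best_layers <- model$layers
      if (es$stop) { stopped <- epoch; break }
    }
  })
  model$layers <- best_layers
  list(model = model,
       history = list(train_loss = hist_train, val_loss = hist_val,
                      best_epoch = es$best_epoch, stopped_epoch = stopped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
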
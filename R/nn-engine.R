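# Minimal matrix-based neural network engine.
#
# Sequence minibatches use a flat layout: a (n*T) x d matrix whose row
# (i-1)*T + t holds the feature vector of sample i at frame t, carried
# around as list(M, n, T). This keeps convolutions as plain BLAS matrix
# products (one product per kernel offset) and avoids 3-d array shuffling
# in inner loops. All backward passes are checked against numerical
# gradients in the test suite.

seq_batch <- function(mats) {
  # mats: list of T x d matrices with identical dims
  T_ <- nrow(mats[[1]])
  d <- ncol(mats[[1]])
  list(M = do.call(rbind, mats), n = length(mats), T = T_, d = d)
}

# value of row (i, t + s), zero outside [1, T]
shift_rows <- function(M, n, T_, s) {
  if (s == 0) return(M)
  tt <- rep(seq_len(T_), n)
  src_t <- tt + s
  valid <- src_t >= 1L & src_t <= T_
  out <- matrix(0, n * T_, ncol(M))
  base <- rep((seq_len(n) - 1L) * T_, each = T_)
  out[which(valid), ] <- M[(base + src_t)[valid], , drop = FALSE]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## ---- layer constructors (parameters drawn from the current RNG) ----

layer_dense <- function(d_in, d_out) {
  list(type = "dense", params = list(W = glorot(d_in, d_out),
                                     b = numeric(d_out)))
}
layer_relu <- function() list(type = "relu", params = list())
layer_conv1d <- function(d_in, n_filters, kernel) {
  stopifnot(kernel %% 2L == 1L)
  W <- lapply(seq_len(kernel), function(o)
    glorot(d_in, n_filters, fan_in = kernel * d_in,
           fan_out = kernel * n_filters))
  list(type = "conv1d", kernel = kernel,
       params = list(W = W, b = numeric(n_filters)))
}
layer_maxpool <- function() list(type = "maxpool", params = list())
layer_avgpool <- function(width) {
  list(type = "avgpool", width = as.integer(width), params = list())
}
layer_flatten <- function() list(type = "flatten", params = list())
layer_lstm_last <- function(d_in, units) {
  list(type = "lstm_last", units = units, params = list(
    Wx = glorot(d_in, 4L * units, fan_in = d_in, fan_out = units),
    Wh = glorot(units, 4L * units, fan_in = units, fan_out = units),
    b = c(numeric(units), rep(1, units), numeric(2L * units)))) # forget bias 1
}

## ---- forward ----

layer_forward <- function(layer, x) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$params$W, 2, layer$params$b, `+`)
      list(out = out, cache = list(x = x))
    },
    relu = {
      if (is.list(x)) {
        mask <- x$M > 0
        x$M <- x$M * mask
        list(out = x, cache = list(mask = mask))
      } else {
        mask <- x > 0
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    conv1d = {
      k <- layer$kernel
      mid <- (k + 1L) %/% 2L
      Y <- matrix(0, nrow(x$M), length(layer$params$b))
      for (o in seq_len(k)) {
        Y <- Y + shift_rows(x$M, x$n, x$T, o - mid) %*% layer$params$W[[o]]
      }
      Y <- sweep(Y, 2, layer$params$b, `+`)
      list(out = list(M = Y, n = x$n, T = x$T, d = ncol(Y)),
           cache = list(x = x))
    },
    maxpool = {
      T2 <- x$T %/% 2L
      base <- rep((seq_len(x$n) - 1L) * x$T, each = T2)
      r1 <- base + 2L * rep(seq_len(T2), x$n) - 1L
      r2 <- r1 + 1L
      A <- x$M[r1, , drop = FALSE]
      B <- x$M[r2, , drop = FALSE]
      mask <- A >= B
      list(out = list(M = A * mask + B * (1 - mask), n = x$n, T = T2,
                      d = x$d),
           cache = list(r1 = r1, r2 = r2, mask = mask,
                        nT = nrow(x$M), d = x$d))
    },
    avgpool = {
      w <- layer$width
      Tw <- x$T %/% w
      base <- rep((seq_len(x$n) - 1L) * x$T, each = Tw)
      t0 <- w * (rep(seq_len(Tw), x$n) - 1L)
      Y <- matrix(0, x$n * Tw, x$d)
      for (j in seq_len(w)) Y <- Y + x$M[base + t0 + j, , drop = FALSE]
      list(out = list(M = Y / w, n = x$n, T = Tw, d = x$d),
           cache = list(base = base, t0 = t0, w = w, nT = nrow(x$M),
                        d = x$d))
    },
    flatten = {
      out <- matrix(as.vector(t(x$M)), nrow = x$n, byrow = TRUE)
      list(out = out, cache = list(n = x$n, T = x$T, d = x$d))
    },
    lstm_last = {
      u <- layer$units
      p <- layer$params
      H <- matrix(0, x$n, u); C <- matrix(0, x$n, u)
      steps <- vector("list", x$T)
      base <- (seq_len(x$n) - 1L) * x$T
      for (t in seq_len(x$T)) {
        Xt <- x$M[base + t, , drop = FALSE]
        A <- sweep(Xt %*% p$Wx + H %*% p$Wh, 2, p$b, `+`)
        gi <- sigmoid(A[, 1:u, drop = FALSE])
        gf <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
        gg <- tanh(A[, (2 * u + 1):(3 * u), drop = FALSE])
        go <- sigmoid(A[, (3 * u + 1):(4 * u), drop = FALSE])
        Cp <- C; Hp <- H
        C <- gf * Cp + gi * gg
        H <- go * tanh(C)
        steps[[t]] <- list(Xt = Xt, gi = gi, gf = gf, gg = gg, go = go,
                           C = C, Cp = Cp, Hp = Hp)
      }
      list(out = H, cache = list(steps = steps, base = base, x = x))
    },
    stop("unknown layer type: ", layer$type))
}

## ---- backward: returns list(dx, grads) ----

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$params$W),
           grads = list(W = t(cache$x) %*% dout, b = colSums(dout)))
    },
    relu = {
      if (is.list(dout)) {
        dout$M <- dout$M * cache$mask
        list(dx = dout, grads = list())
      } else {
        list(dx = dout * cache$mask, grads = list())
      }
    },
    conv1d = {
      k <- layer$kernel
      mid <- (k + 1L) %/% 2L
      x <- cache$x
      dY <- dout$M
      dW <- vector("list", k)
      dM <- matrix(0, nrow(x$M), ncol(x$M))
      for (o in seq_len(k)) {
        s <- o - mid
        dW[[o]] <- t(shift_rows(x$M, x$n, x$T, s)) %*% dY
        dM <- dM + shift_rows(dY %*% t(layer$params$W[[o]]), x$n, x$T, -s)
      }
      list(dx = list(M = dM, n = x$n, T = x$T, d = x$d),
           grads = list(W = dW, b = colSums(dY)))
    },
    maxpool = {
      dM <- matrix(0, cache$nT, cache$d)
      dM[cache$r1, ] <- dout$M * cache$mask
      dM[cache$r2, ] <- dout$M * (1 - cache$mask)
      list(dx = list(M = dM, n = dout$n, T = cache$nT / dout$n,
                     d = cache$d),
           grads = list())
    },
    avgpool = {
      dM <- matrix(0, cache$nT, cache$d)
      for (j in seq_len(cache$w)) {
        dM[cache$base + cache$t0 + j, ] <- dout$M / cache$w
      }
      list(dx = list(M = dM, n = dout$n, T = cache$nT / dout$n,
                     d = cache$d),
           grads = list())
    },
    flatten = {
      dM <- matrix(as.vector(t(dout)), ncol = cache$d, byrow = TRUE)
      list(dx = list(M = dM, n = cache$n, T = cache$T, d = cache$d),
           grads = list())
    },
    lstm_last = {
      u <- layer$units
      p <- layer$params
      x <- cache$x
      dH <- dout
      dC <- matrix(0, nrow(dout), u)
      dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
      dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
      db <- numeric(length(p$b))
      dM <- matrix(0, nrow(x$M), ncol(x$M))
      for (t in rev(seq_len(x$T))) {
        st <- cache$steps[[t]]
        tc <- tanh(st$C)
        dgo <- dH * tc
        dC <- dC + dH * st$go * (1 - tc^2)
        dgi <- dC * st$gg
        dgf <- dC * st$Cp
        dgg <- dC * st$gi
        dCp <- dC * st$gf
        dA <- cbind(dgi * st$gi * (1 - st$gi),
                    dgf * st$gf * (1 - st$gf),
                    dgg * (1 - st$gg^2),
                    dgo * st$go * (1 - st$go))
        dWx <- dWx + t(st$Xt) %*% dA
        dWh <- dWh + t(st$Hp) %*% dA
        db <- db + colSums(dA)
        dM[cache$base + t, ] <- dA %*% t(p$Wx)
        dH <- dA %*% t(p$Wh)
        dC <- dCp
      }
      list(dx = list(M = dM, n = x$n, T = x$T, d = x$d),
           grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    stop("unknown layer type: ", layer$type))
}

## ---- Adam optimizer over the nested parameter lists ----

adam_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) {
      if (is.list(p)) {
        lapply(p, function(q) list(m = q * 0, v = q * 0))
      } else {
        list(m = p * 0, v = p * 0)
      }
    })
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (li in seq_along(layers)) {
    for (pn in names(layers[[li]]$params)) {
      p <- layers[[li]]$params[[pn]]
      g <- grads[[li]][[pn]]
      if (is.null(g)) next
      if (is.list(p)) {
        for (j in seq_along(p)) {
          r <- upd(p[[j]], g[[j]], state[[li]][[pn]][[j]])
          layers[[li]]$params[[pn]][[j]] <- r$p
          state[[li]][[pn]][[j]] <- r$s
        }
      } else {
        r <- upd(p, g, state[[li]][[pn]])
        layers[[li]]$params[[pn]] <- r$p
        state[[li]][[pn]] <- r$s
      }
    }
  }
  list(layers = layers, state = state)
}
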
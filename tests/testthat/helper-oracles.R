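# Independent oracles used across the suite. These are deliberately naive
# re-implementations (loops, O(n^2) scans) kept separate from the package's
# code paths.

# brute-force five-rule fusion: element-wise rules, renormalize, average
oracle_five_rule <- function(vectors) {
  M <- do.call(cbind, vectors)
  outs <- list()
  for (rule in c("min", "max", "mean", "median", "product")) {
    v <- numeric(4)
    for (i in 1:4) {
      v[i] <- switch(rule,
        min = min(M[i, ]), max = max(M[i, ]), mean = mean(M[i, ]),
        median = median(M[i, ]), product = prod(M[i, ]))
    }
    outs[[rule]] <- v / sum(v)
  }
  out <- Reduce(`+`, outs) / length(outs)
  out / sum(out)
}

# O(n^2) pairwise AUC with half credit for ties
oracle_auc <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  tot / (length(pos) * length(neg))
}

random_simplex <- function(n = 4) {
  x <- rexp(n)
  x / sum(x)
}

# numerical gradient check: max relative error over a few sampled entries
# of every parameter tensor
grad_check_max_rel <- function(cfg, x, y, eps = 1e-5, per_tensor = 3L) {
  m <- build_model(cfg)
  xin <- voxmmrc:::as_model_input(m, x)
  f <- voxmmrc:::model_forward(m, xin, keep_caches = TRUE)
  hl <- voxmmrc:::head_loss_grad(m, f$raw, f$probs, y)
  gr <- voxmmrc:::model_backward(m, f$caches, hl$draw)
  loss_with <- function(li, pn, j, e, delta) {
    m2 <- m
    if (is.na(j)) {
      m2$layers[[li]]$params[[pn]][e] <-
        m2$layers[[li]]$params[[pn]][e] + delta
    } else {
      m2$layers[[li]]$params[[pn]][[j]][e] <-
        m2$layers[[li]]$params[[pn]][[j]][e] + delta
    }
    f2 <- voxmmrc:::model_forward(m2, xin)
    voxmmrc:::head_loss_grad(m2, f2$raw, f2$probs, y)$loss
  }
  worst <- 0
  for (li in seq_along(m$layers)) {
    for (pn in names(m$layers[[li]]$params)) {
      p <- m$layers[[li]]$params[[pn]]
      idx <- if (is.list(p)) seq_along(p) else NA_integer_
      for (j in idx) {
        pj <- if (is.na(j)) p else p[[j]]
        for (e in sample(length(pj), min(per_tensor, length(pj)))) {
          num <- (loss_with(li, pn, j, e, eps) -
                    loss_with(li, pn, j, e, -eps)) / (2 * eps)
          ana <- if (is.na(j)) gr[[li]][[pn]][e] else gr[[li]][[pn]][[j]][e]
          worst <- max(worst,
                       abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
        }
      }
    }
  }
  worst
}

# a tiny in-memory recording for feature tests
make_test_recording <- function(waveform, type = "ae") {
  voxmmrc:::new_recording(waveform, "T01", type, 1L, 0L)
}
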
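test_that("log spectrum has 257 bins and the expected frame count", {
  set.seed(2)
  for (len in c(400L, 1000L, 8000L, 24321L)) {
    S <- compute_log_spectrum(rnorm(len, sd = 0.1))
    expect_equal(ncol(S), 257L)
    expect_equal(nrow(S), (len - 400L) %/% 200L + 1L)
  }
  expect_error(compute_log_spectrum(rnorm(399)), "window")
})

test_that("scaling the waveform shifts log power by 2 log(10)", {
  set.seed(3)
  x <- rnorm(4000, sd = 0.05)
  S1 <- compute_log_spectrum(x)
  S10 <- compute_log_spectrum(10 * x)
  above_floor <- exp(S1) > 1e-6
  diffs <- (S10 - S1)[above_floor]
  expect_lt(max(abs(diffs - 2 * log(10))), 1e-6)
})

test_that("Mel filterbank rows are contiguous, overlapping band filters", {
  fb <- mel_filterbank(14L)
  expect_equal(dim(fb), c(14L, 257L))
  expect_true(all(fb >= 0))
  for (m in 1:14) {
    nz <- which(fb[m, ] > 0)
    expect_true(all(diff(nz) == 1)) # one contiguous band
  }
  for (m in 1:13) { # adjacent filters overlap
    expect_gt(length(intersect(which(fb[m, ] > 0), which(fb[m + 1, ] > 0))),
              0)
  }
})

test_that("Mel energies match an independently built filterbank", {
  # flat unit power spectrum: each energy equals log of the filter area
  flat <- matrix(0, 3, 257) # log(1) = 0 per bin
  E <- mel_energies(flat)
  expect_equal(dim(E), c(3L, 14L))
  # oracle: rebuild triangles point by point
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(4000), length.out = 16))
  bin_hz <- (0:256) * 8000 / 512
  areas <- sapply(1:14, function(m) {
    w <- pmin((bin_hz - edges[m]) / (edges[m + 1] - edges[m]),
              (edges[m + 2] - bin_hz) / (edges[m + 2] - edges[m + 1]))
    sum(pmax(0, w))
  })
  expect_equal(unname(E[1, ]), log(areas + 1e-10), tolerance = 1e-12)
  # zero power spectrum floors at log(eps)
  E0 <- mel_energies(matrix(-Inf, 2, 257))
  expect_true(all(E0 == log(1e-10)))
})

test_that("low-band features keep 193 bins and append exact deltas", {
  set.seed(4)
  S <- matrix(rnorm(20 * 257), 20, 257)
  F <- low_band_with_deltas(S)
  expect_equal(ncol(F), 386L)
  expect_equal(F[, 1:193], S[, 1:193])
  # finite-difference oracle with edge replication
  oracle <- matrix(0, 20, 193)
  for (t in 1:20) {
    prev <- S[max(1, t - 1), 1:193]
    nxt <- S[min(20, t + 1), 1:193]
    oracle[t, ] <- (nxt - prev) / 2
  }
  expect_equal(unname(F[, 194:386]), oracle, tolerance = 1e-14)
  # a time-constant spectrum has zero deltas
  Sc <- matrix(rep(rnorm(257), each = 5), 5, 257)
  expect_true(all(low_band_with_deltas(Sc)[, 194:386] == 0))
  expect_error(low_band_with_deltas(S[1, , drop = FALSE]), "2 frames")
})

test_that("time-independent features follow their closed forms", {
  rec <- make_test_recording(numeric(20000)) # 2.5 s
  const_track <- data.frame(time_s = seq(0.02, 2.48, by = 0.01))
  const_track$f0_hz <- 110
  const_track$voiced <- TRUE
  ti <- extract_time_independent(rec, const_track)
  expect_equal(ti$norm_slope_per_s, 0)
  expect_equal(ti$f0_sd_hz, 0)
  expect_equal(ti$duration_s, 2.5)

  rise <- data.frame(time_s = seq(0, 1, length.out = 101),
                     f0_hz = seq(100, 110, length.out = 101),
                     voiced = TRUE)
  ti2 <- extract_time_independent(make_test_recording(numeric(8000)), rise)
  expect_equal(ti2$norm_slope_per_s, 10 / 105, tolerance = 1e-10)

  ti3 <- extract_time_independent(make_test_recording(numeric(24000)),
                                  const_track)
  expect_equal(ti3$duration_s, 3.0)
})

test_that("too few voiced frames yields flagged zero F0 statistics", {
  track <- data.frame(time_s = c(0.02, 0.03), f0_hz = c(120, NA),
                      voiced = c(TRUE, FALSE))
  expect_warning(
    ti <- extract_time_independent(make_test_recording(numeric(8000)), track),
    "voiced")
  expect_true(ti$missing_f0)
  expect_equal(ti$norm_slope_per_s, 0)
  expect_equal(ti$duration_s, 1)
})

test_that("MVN normalizes the fitting set to zero mean, unit variance", {
  set.seed(6)
  X <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  st <- fit_mvn(X)
  Z <- apply_mvn(X, st)
  expect_lt(max(abs(colMeans(Z))), 1e-6)
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 1e-6)
  # constant column: floored sd, zeros out
  Xc <- cbind(X[, 1], 5)
  expect_warning(stc <- fit_mvn(Xc), "zero-variance")
  expect_true(all(apply_mvn(Xc, stc)[, 2] == 0))
  # scope semantics: stats from A applied to disjoint B differ from B's own
  B <- matrix(rnorm(200, mean = -1), 50, 4)
  expect_gt(max(abs(apply_mvn(B, st) - apply_mvn(B, fit_mvn(B)))), 0.1)
})

test_that("padding and truncation reach the reference length", {
  M <- matrix(seq_len(20 * 3), 20, 3)
  P <- pad_to_reference(M[1:10, ], 15)
  expect_equal(nrow(P), 15L)
  expect_true(all(P[11:15, ] == 0))
  expect_identical(pad_to_reference(M[1:15, ], 15), M[1:15, ])
  expect_identical(pad_to_reference(M, 15), M[1:15, ])
})

test_that("feature dimension is a pure function of vocalization type", {
  prof <- default_severity_profiles("ae")[["0"]]
  f_ae <- extract_features(synthesize_ae(prof, 1))
  expect_equal(ncol(f_ae$td), 14L)
  expect_equal(length(f_ae$ti), 3L)
  prof_c <- default_severity_profiles("counting")[["0"]]
  f_c <- extract_features(synthesize_counting(prof_c, 1))
  expect_equal(ncol(f_c$td), 386L)
})
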
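#' @title Engineered vocal features
#' @description Time-independent features summarize a whole vocalization
#'   (normalized F0 slope, F0 standard deviation, duration); time-dependent
#'   features are frame-wise spectral descriptors (14 Mel filter log
#'   energies for /ae-ae/ and /sa-sa/; the lowest 75% of log-spectrum bins
#'   plus their deltas, 386 per frame, for counting). Both kinds are
#'   mean-variance normalized with dataset-level statistics and the
#'   time-dependent matrices are zero-padded to a common reference length.
#' @name features
NULL

LOG_EPS <- 1e-10

#' Time-independent features from a pitch track
#'
#' Computes the linear slope of F0 over time across voiced frames (least
#' squares), normalized by the mean F0; the standard deviation of the
#' voiced F0 values; and the recording duration in seconds. With fewer than
#' two voiced frames the F0 statistics are unavailable and are emitted as 0
#' with a warning (`missing_f0 = TRUE`), duration is still reported.
#'
#' @param recording a `voc_recording`.
#' @param track a `pitch_track` from [estimate_f0()] on the same recording.
#' @return list with `norm_slope_per_s`, `f0_sd_hz`, `duration_s`,
#'   `missing_f0`.
#' @export
extract_time_independent <- function(recording, track) {
  stopifnot(inherits(recording, "voc_recording"))
  duration <- length(recording$waveform) / recording$sample_rate
  v <- which(track$voiced)
  if (length(v) < 2L) {
    warning("fewer than 2 voiced frames; F0 slope and sd set to 0")
    return(list(norm_slope_per_s = 0, f0_sd_hz = 0,
                duration_s = duration, missing_f0 = TRUE))
  }
  t <- track$time_s[v]
  f <- track$f0_hz[v]
  mt <- mean(t); mf <- mean(f)
  denom <- sum((t - mt)^2)
  slope <- if (denom > 0) sum((t - mt) * (f - mf)) / denom else 0
  list(norm_slope_per_s = slope / mf,
       f0_sd_hz = stats::sd(f),
       duration_s = duration,
       missing_f0 = FALSE)
}

#' Log power spectrogram (512-point FFT, 50 ms Hann windows, 50% overlap)
#'
#' 400-sample (50 ms at 8 kHz) Hann-windowed frames with a 200-sample hop,
#' zero-padded to a 512-point FFT; returns the natural log of
#' (power + 1e-10) over the 257 non-redundant bins.
#'
#' @param recording a `voc_recording` or numeric waveform at 8 kHz.
#' @return matrix (frames x 257).
#' @export
compute_log_spectrum <- function(recording) {
  x <- if (inherits(recording, "voc_recording")) recording$waveform else recording
  win_n <- 400L; hop_n <- 200L; nfft <- 512L
  if (is.null(x) || length(x) < win_n) {
    stop("waveform shorter than one 50 ms analysis window")
  }
  n_frames <- (length(x) - win_n) %/% hop_n + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_n
  idx <- outer(seq_len(win_n), starts, `+`)
  frames <- matrix(x[idx], nrow = win_n)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_n) - 1L) / (win_n - 1L))
  frames <- frames * hann
  padded <- rbind(frames, matrix(0, nfft - win_n, n_frames))
  spec <- stats::mvfft(padded)
  power <- Mod(spec[seq_len(nfft / 2L + 1L), , drop = FALSE])^2
  t(log(power + LOG_EPS))
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank matrix
#'
#' `n_mels` triangular filters with centers equally spaced on the Mel scale
#' between 0 and 4000 Hz, evaluated at the 257 FFT bin frequencies of the
#' 512-point / 8 kHz analysis.
#'
#' @param n_mels number of filters (default 14).
#' @param n_bins number of FFT bins (default 257).
#' @param sample_rate sampling rate in Hz.
#' @return matrix (n_mels x n_bins) of non-negative weights.
#' @export
mel_filterbank <- function(n_mels = 14L, n_bins = 257L, sample_rate = 8000L) {
  stopifnot(n_mels >= 1)
  nfft <- (n_bins - 1L) * 2L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / nfft
  edges <- hz_of_mel(seq(mel_of_hz(0), mel_of_hz(sample_rate / 2),
                         length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel filter log energies per frame
#'
#' Recovers linear power from the log spectrum, applies the triangular Mel
#' filterbank, and takes the natural log with a 1e-10 floor.
#'
#' @param log_spectrum matrix (frames x 257) from [compute_log_spectrum()].
#' @param n_mels number of Mel filters (default 14).
#' @return matrix (frames x n_mels).
#' @export
mel_energies <- function(log_spectrum, n_mels = 14L) {
  stopifnot(ncol(log_spectrum) == 257L, n_mels >= 1)
  fb <- mel_filterbank(n_mels, ncol(log_spectrum))
  power <- exp(log_spectrum)
  log(power %*% t(fb) + LOG_EPS)
}

#' Low-band log spectrum with delta features
#'
#' Keeps the lowest 193 of the 257 log-spectrum bins (75% of the band,
#' rounded so that twice the count gives 386 features) and appends the
#' first-order time derivative of each kept bin, computed as a symmetric
#' difference over +/- 1 frame with edge replication.
#'
#' @param log_spectrum matrix (frames x 257), at least 2 frames.
#' @return matrix (frames x 386).
#' @export
low_band_with_deltas <- function(log_spectrum) {
  stopifnot(ncol(log_spectrum) == 257L)
  if (nrow(log_spectrum) < 2L) {
    stop("delta features require at least 2 frames")
  }
  low <- log_spectrum[, 1:193, drop = FALSE]
  nT <- nrow(low)
  prev <- low[c(1L, seq_len(nT - 1L)), , drop = FALSE]
  nxt <- low[c(seq_len(nT - 1L) + 1L, nT), , drop = FALSE]
  delta <- (nxt - prev) / 2
  cbind(low, delta)
}

#' Fit dataset-level mean-variance normalization statistics
#'
#' Pools all frames (or all observations) across the supplied feature
#' matrices and computes per-dimension mean and standard deviation. The
#' `scope` label records whether the statistics came from the whole dataset
#' or from a training subset only.
#'
#' @param features a matrix, or a list of matrices with equal column count.
#' @param scope `"train"` (default) or `"all"`.
#' @param eps floor applied to the standard deviation.
#' @return object of class `mvn_stats` with `mean`, `sd`, `scope`.
#' @export
fit_mvn <- function(features, scope = c("train", "all"), eps = 1e-8) {
  scope <- match.arg(scope)
  if (is.list(features)) features <- do.call(rbind, features)
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  sds <- apply(features, 2, stats::sd)
  if (any(sds <= eps)) {
    warning("zero-variance feature dimension(s); sd floored")
  }
  structure(list(mean = colMeans(features), sd = pmax(sds, eps),
                 scope = scope), class = "mvn_stats")
}

#' Apply mean-variance normalization
#'
#' @param features matrix (rows are frames or observations).
#' @param stats an `mvn_stats` object from [fit_mvn()].
#' @return normalized matrix of the same shape.
#' @export
apply_mvn <- function(features, stats) {
  stopifnot(inherits(stats, "mvn_stats"), ncol(features) == length(stats$mean))
  sweep(sweep(features, 2, stats$mean), 2, stats$sd, `/`)
}

#' Pad or truncate a time-dependent feature matrix to a reference length
#'
#' Shorter inputs are right-padded with all-zero frames; longer inputs are
#' truncated to the first `ref_len_frames` frames (fixed-size network
#' input; the reference length is taken from the longest training utterance
#' of the same vocalization type).
#'
#' @param features matrix (frames x dim).
#' @param ref_len_frames target frame count (>= 1).
#' @return matrix (ref_len_frames x dim).
#' @export
pad_to_reference <- function(features, ref_len_frames) {
  stopifnot(ref_len_frames >= 1)
  nT <- nrow(features)
  if (nT >= ref_len_frames) {
    features[seq_len(ref_len_frames), , drop = FALSE]
  } else {
    rbind(features, matrix(0, ref_len_frames - nT, ncol(features)))
  }
}

#' Extract both feature kinds for one recording
#'
#' Convenience wrapper: pitch track + time-independent vector, and the
#' type-appropriate time-dependent matrix (14 Mel log energies for ae/sa,
#' 386 low-band + delta features for counting).
#'
#' @param recording a `voc_recording` with waveform present.
#' @return list with `ti` (numeric length 3: normalized slope, F0 sd,
#'   duration) and `td` (matrix frames x 14 or frames x 386).
#' @export
extract_features <- function(recording) {
  stopifnot(inherits(recording, "voc_recording"))
  track <- estimate_f0(recording)
  ti <- suppressWarnings(extract_time_independent(recording, track))
  spec <- compute_log_spectrum(recording)
  td <- if (recording$vocalization_type == "counting") {
    low_band_with_deltas(spec)
  } else {
    mel_energies(spec)
  }
  list(ti = c(norm_slope_per_s = ti$norm_slope_per_s,
              f0_sd_hz = ti$f0_sd_hz,
              duration_s = ti$duration_s),
       td = td)
}

#' Extract features for every recording in a manifest
#'
#' Reads each WAV referenced by the manifest (unless in-memory recordings
#' are supplied) and computes both feature kinds.
#'
#' @param manifest manifest data.frame from [read_manifest()].
#' @param recordings optional list of `voc_recording` objects with
#'   waveforms, parallel to the manifest rows (as returned by
#'   [generate_cohort()] with `write_audio = FALSE`).
#' @param progress print a dot every 50 recordings.
#' @return list (one element per manifest row) of [extract_features()]
#'   results.
#' @export
extract_manifest_features <- function(manifest, recordings = NULL,
                                      progress = FALSE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- if (!is.null(recordings) && !is.null(recordings[[i]]$waveform)) {
      recordings[[i]]
    } else {
      wav <- read_wav(manifest$path[i])
      new_recording(wav$samples, manifest$participant_id[i],
                    manifest$vocalization_type[i], manifest$repetition[i],
                    manifest$mmrc_reference[i])
    }
    if (progress && i %% 50L == 0L) cat(".")
    extract_features(rec)
  })
}
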
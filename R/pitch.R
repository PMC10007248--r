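#' Frame-wise fundamental frequency estimation by autocorrelation
#'
#' Short-term normalized autocorrelation pitch tracker: 40 ms frames with a
#' 10 ms hop; within each frame the lag of the highest normalized
#' autocorrelation peak inside the F0 search range is refined by parabolic
#' interpolation. A frame is voiced when its normalized autocorrelation peak
#' exceeds 0.45 and its energy is above a silence floor (both absolute and
#' relative to the loudest frame).
#'
#' @param recording a `voc_recording`, or a numeric waveform vector.
#' @param fmin_hz,fmax_hz F0 search range (defaults 75-500 Hz).
#' @param sample_rate used when `recording` is a bare vector.
#' @return a `pitch_track` data.frame with columns `time_s`, `f0_hz`
#'   (`NA` where unvoiced) and `voiced`.
#' @export
estimate_f0 <- function(recording, fmin_hz = 75, fmax_hz = 500,
                        sample_rate = 8000L) {
  x <- if (inherits(recording, "voc_recording")) recording$waveform else recording
  sr <- if (inherits(recording, "voc_recording")) recording$sample_rate else sample_rate
  if (is.null(x) || length(x) == 0) stop("empty waveform")
  stopifnot(fmin_hz > 0, fmin_hz < fmax_hz, fmax_hz < sr / 2)

  frame_n <- round(0.040 * sr)
  hop_n <- round(0.010 * sr)
  if (length(x) < frame_n) {
    out <- data.frame(time_s = numeric(0), f0_hz = numeric(0),
                      voiced = logical(0))
    class(out) <- c("pitch_track", "data.frame")
    return(out)
  }
  n_frames <- (length(x) - frame_n) %/% hop_n + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_n
  idx <- outer(seq_len(frame_n), starts, `+`)
  frames <- matrix(x[idx], nrow = frame_n)
  frames <- sweep(frames, 2, colMeans(frames))

  # frame-wise autocorrelation via FFT
  nfft <- 2^ceiling(log2(2L * frame_n))
  padded <- rbind(frames, matrix(0, nfft - frame_n, n_frames))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft

  r0 <- ac[1L, ]
  lag_min <- max(2L, floor(sr / fmax_hz))
  lag_max <- min(frame_n - 2L, ceiling(sr / fmin_hz))
  lags <- lag_min:lag_max
  nac <- sweep(ac[lags + 1L, , drop = FALSE], 2, pmax(r0, 1e-12), `/`)

  best <- apply(nac, 2, which.max)
  best_nac <- nac[cbind(best, seq_len(n_frames))]
  best_lag <- lags[best]

  # parabolic refinement around the peak lag
  refine <- function(j) {
    l <- best_lag[j]
    if (l <= lag_min || l >= lag_max) return(as.numeric(l))
    y0 <- ac[l, j]; y1 <- ac[l + 1L, j]; y2 <- ac[l + 2L, j]
    denom <- y0 - 2 * y1 + y2
    if (abs(denom) < 1e-12) return(as.numeric(l))
    l + 0.5 * (y0 - y2) / denom
  }
  lag_ref <- vapply(seq_len(n_frames), refine, numeric(1))

  rms <- sqrt(pmax(r0, 0) / frame_n)
  voiced <- best_nac > 0.45 & rms > 1e-4 & rms > 0.02 * max(rms)
  f0 <- sr / lag_ref
  f0[f0 < fmin_hz | f0 > fmax_hz] <- NA
  voiced <- voiced & !is.na(f0)
  f0[!voiced] <- NA

  out <- data.frame(time_s = (starts + frame_n / 2) / sr,
                    f0_hz = f0, voiced = voiced)
  class(out) <- c("pitch_track", "data.frame")
  out
}
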
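#' @title Source-filter synthesis of severity-conditioned vocalizations
#' @description Internal waveform builders. Voiced segments are produced by
#'   exciting a cascade of two second-order formant resonators with a
#'   glottal-pulse-like impulse train whose instantaneous F0 follows a slow
#'   random wander; fricatives are high-pass filtered white noise. All
#'   randomness is seeded, so every waveform is a pure function of
#'   (profile, seed).
#' @name cohort-synth
#' @keywords internal
NULL

SAMPLE_RATE <- 8000L

# slow F0 wander: frame-level white noise smoothed by a moving average,
# rescaled to the requested sd, then sample-rate interpolated
f0_wander <- function(n_samples, f0_base, jitter_sd, sr = SAMPLE_RATE) {
  frame_s <- 0.01
  n_frames <- max(2L, ceiling(n_samples / (sr * frame_s)) + 1L)
  w <- stats::rnorm(n_frames + 40L)
  w <- stats::filter(w, rep(1 / 21, 21), sides = 2)
  w <- w[!is.na(w)][seq_len(n_frames)]
  s <- stats::sd(w)
  if (is.finite(s) && s > 0) w <- w / s * jitter_sd else w <- rep(0, n_frames)
  f0 <- f0_base + w
  stats::approx(seq(0, by = frame_s, length.out = n_frames), f0,
                xout = (seq_len(n_samples) - 1) / sr, rule = 2)$y
}

# glottal-pulse-like excitation: unit impulses at each F0 period
impulse_train <- function(f0_per_sample, sr = SAMPLE_RATE) {
  phase <- cumsum(f0_per_sample / sr)
  x <- numeric(length(f0_per_sample))
  x[c(TRUE, diff(floor(phase)) >= 1)] <- 1
  x
}

# two-pole resonator at center frequency f (Hz) with bandwidth bw (Hz)
resonator <- function(x, f, bw, sr = SAMPLE_RATE) {
  r <- exp(-pi * bw / sr)
  theta <- 2 * pi * f / sr
  y <- stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive")
  as.numeric(y)
}

# voiced vowel-like segment with the given formant pair
vowel_segment <- function(f0_per_sample, formants, sr = SAMPLE_RATE) {
  src <- impulse_train(f0_per_sample, sr)
  y <- resonator(src, formants[1], 90, sr)
  y <- resonator(y, formants[2], 120, sr)
  y
}

# unvoiced fricative-like segment: white noise high-passed above 2 kHz
fricative_segment <- function(n, sr = SAMPLE_RATE) {
  noise <- stats::rnorm(n + 64L)
  bf <- signal::butter(4, 2000 / (sr / 2), type = "high")
  y <- as.numeric(signal::filter(bf, noise))
  y[(64L + 1L):(64L + n)]
}

# raised-cosine onset/offset ramps to avoid clicks at segment boundaries
apply_ramps <- function(x, ramp_s = 0.01, sr = SAMPLE_RATE) {
  n <- length(x)
  nr <- min(floor(ramp_s * sr), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  x
}

# peak-normalize to 0.5 and add white noise emulating telephone capture
finalize_waveform <- function(x, snr_db = 30) {
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 0.5
  rms <- sqrt(mean(x^2))
  if (rms > 0) {
    x <- x + stats::rnorm(length(x), sd = rms / 10^(snr_db / 20))
  }
  pmin(pmax(x, -1), 1)
}

# duration drawn around the profile budget (12% relative sd), with bounded
# retries should the draw come out non-positive
draw_duration <- function(budget_s, min_s = 0.5, max_tries = 20L) {
  if (budget_s <= 0) stop("phonation budget must be positive")
  for (i in seq_len(max_tries)) {
    d <- stats::rnorm(1, mean = budget_s, sd = 0.12 * budget_s)
    if (d >= min_s) return(d)
  }
  stop("could not draw a positive phonation duration")
}

new_recording <- function(waveform, participant_id, vocalization_type,
                          repetition, mmrc_reference, meta = list()) {
  structure(list(
    participant_id = participant_id,
    vocalization_type = vocalization_type,
    repetition = as.integer(repetition),
    mmrc_reference = as.integer(mmrc_reference),
    waveform = waveform,
    sample_rate = SAMPLE_RATE,
    path = NA_character_,
    meta = meta
  ), class = "voc_recording")
}

#' Synthesize an /ae-ae/ vocalization
#'
#' Alternating /a/-like and /e/-like voiced segments produced in one breath:
#' a glottal-pulse source at the profile's base F0 (with slow seeded wander)
#' filtered by two alternating formant settings. Total duration is drawn
#' around the profile's phonation budget.
#'
#' @param profile a [severity_profile()].
#' @param seed integer seed; the waveform is a pure function of
#'   (profile, seed).
#' @return a `voc_recording` object.
#' @export
synthesize_ae <- function(profile, seed) {
  stopifnot(inherits(profile, "severity_profile"))
  with_seed(seed, {
    sr <- SAMPLE_RATE
    dur <- draw_duration(profile$phonation_budget_s)
    n <- round(dur * sr)
    f0 <- f0_wander(n, profile$f0_base_hz, profile$f0_jitter_sd_hz)
    seg_n <- round(0.35 * sr)
    formant_a <- c(700, 1220)
    formant_e <- c(450, 1900)
    out <- numeric(n)
    start <- 1L
    k <- 0L
    while (start <= n) {
      end <- min(start + seg_n - 1L, n)
      fm <- if (k %% 2L == 0L) formant_a else formant_e
      seg <- vowel_segment(f0[start:end], fm)
      out[start:end] <- apply_ramps(seg)
      start <- end + 1L
      k <- k + 1L
    }
    new_recording(finalize_waveform(out),
                  participant_id = NA_character_,
                  vocalization_type = "ae", repetition = 1L,
                  mmrc_reference = profile$mmrc_class,
                  meta = list(duration_s = dur, n_segments = k))
  })
}

#' Synthesize a /sa-sa/ vocalization
#'
#' Alternating unvoiced /s/-like fricative segments (high-pass filtered
#' noise) and voiced /a/-like segments. The unvoiced fraction of frames is
#' therefore systematically higher than for [synthesize_ae()] under the same
#' profile.
#'
#' @inheritParams synthesize_ae
#' @return a `voc_recording` object.
#' @export
synthesize_sa <- function(profile, seed) {
  stopifnot(inherits(profile, "severity_profile"))
  with_seed(seed, {
    sr <- SAMPLE_RATE
    dur <- draw_duration(profile$phonation_budget_s)
    n <- round(dur * sr)
    f0 <- f0_wander(n, profile$f0_base_hz, profile$f0_jitter_sd_hz)
    s_n <- round(0.18 * sr)
    a_n <- round(0.30 * sr)
    out <- numeric(n)
    start <- 1L
    voiced <- FALSE
    k <- 0L
    while (start <= n) {
      len <- if (voiced) a_n else s_n
      end <- min(start + len - 1L, n)
      seg <- if (voiced) {
        vowel_segment(f0[start:end], c(700, 1220))
      } else {
        # fricatives carry less energy over the telephone channel
        0.25 * fricative_segment(end - start + 1L)
      }
      out[start:end] <- apply_ramps(seg)
      start <- end + 1L
      voiced <- !voiced
      k <- k + 1L
    }
    new_recording(finalize_waveform(out),
                  participant_id = NA_character_,
                  vocalization_type = "sa", repetition = 1L,
                  mmrc_reference = profile$mmrc_class,
                  meta = list(duration_s = dur, n_segments = k))
  })
}

#' Synthesize a one-to-thirty counting vocalization
#'
#' Emits up to 30 syllable-like voiced tokens at the profile's syllable
#' rate, with involuntary silent pauses inserted as a Poisson-like process
#' at the profile's pause rate. Token emission stops when the cumulative
#' phonated time exceeds the phonation budget (the speaker gasps for air)
#' or when 30 tokens have been produced. The number of emitted tokens and
#' pauses is recorded in the `meta` field.
#'
#' @inheritParams synthesize_ae
#' @return a `voc_recording` object.
#' @export
synthesize_counting <- function(profile, seed) {
  stopifnot(inherits(profile, "severity_profile"))
  with_seed(seed, {
    sr <- SAMPLE_RATE
    budget <- draw_duration(profile$phonation_budget_s)
    tok_s <- 0.6 / profile$syllable_rate_hz
    gap_s <- 0.4 / profile$syllable_rate_hz
    # probability that an involuntary pause follows a given token, so that
    # pauses occur at pause_rate per 10 s of speech on average
    p_pause <- min(1, profile$pause_rate * (tok_s + gap_s) / 10)
    # token-level vowel variety standing in for Spanish numeral syllables
    formant_table <- rbind(c(700, 1220), c(450, 1900), c(600, 990),
                           c(390, 2100), c(500, 1500))
    pieces <- list()
    phonated <- 0
    n_tokens <- 0L
    n_pauses <- 0L
    while (n_tokens < 30L && phonated + tok_s <= budget) {
      n_tok <- round(tok_s * sr)
      f0 <- f0_wander(n_tok, profile$f0_base_hz * stats::runif(1, 0.95, 1.1),
                      profile$f0_jitter_sd_hz)
      fm <- formant_table[sample.int(nrow(formant_table), 1L), ]
      pieces[[length(pieces) + 1L]] <- apply_ramps(vowel_segment(f0, fm))
      phonated <- phonated + tok_s
      n_tokens <- n_tokens + 1L
      gap <- gap_s
      if (stats::runif(1) < p_pause) {
        gap <- gap + stats::rexp(1, rate = 1 / max(profile$pause_len_s, 1e-3))
        n_pauses <- n_pauses + 1L
      }
      pieces[[length(pieces) + 1L]] <- numeric(round(gap * sr))
    }
    if (n_tokens == 0L) stop("phonation budget too small for a single token")
    out <- unlist(pieces, use.names = FALSE)
    new_recording(finalize_waveform(out),
                  participant_id = NA_character_,
                  vocalization_type = "counting", repetition = 1L,
                  mmrc_reference = profile$mmrc_class,
                  meta = list(duration_s = length(out) / sr,
                              n_tokens = n_tokens, n_pauses = n_pauses))
  })
}

synthesizer_for <- function(type) {
  switch(type,
    ae = synthesize_ae,
    sa = synthesize_sa,
    counting = synthesize_counting,
    stop("unknown vocalization type: ", type))
}

# per-participant perturbation of the class profile: mild lognormal scatter
# on budget and jitter, a uniform +/- 20 Hz speaker-specific F0 offset
perturb_profile <- function(profile, seed) {
  with_seed(seed, {
    severity_profile(
      mmrc_class = profile$mmrc_class,
      phonation_budget_s = profile$phonation_budget_s *
        exp(stats::rnorm(1, 0, 0.08)),
      pause_rate = profile$pause_rate * exp(stats::rnorm(1, 0, 0.15)),
      pause_len_s = profile$pause_len_s * exp(stats::rnorm(1, 0, 0.1)),
      f0_base_hz = profile$f0_base_hz + stats::runif(1, -20, 20),
      f0_jitter_sd_hz = profile$f0_jitter_sd_hz * exp(stats::rnorm(1, 0, 0.1)),
      syllable_rate_hz = profile$syllable_rate_hz * exp(stats::rnorm(1, 0, 0.05))
    )
  })
}

#' Generate a synthetic study cohort
#'
#' Synthesizes one recording per (participant, vocalization type,
#' repetition), writes each as a mono 8 kHz 16-bit PCM WAV, and writes a CSV
#' manifest with columns `participant_id, path, vocalization_type,
#' repetition, mmrc_reference`. Each participant gets a mildly perturbed
#' copy of their class profile (same perturbation across types, scaled by
#' the type's budget table), so recordings of one speaker are correlated.
#' The whole cohort is a pure function of (config, profiles, seed).
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param profiles named list `type -> list("0".."3" -> severity_profile)`;
#'   defaults to [default_severity_profiles()] per requested type.
#' @param write_audio write WAV files (default `TRUE`); when `FALSE` only
#'   the manifest is written and waveforms are kept in memory.
#' @return (invisibly) list with `manifest` (data.frame), `manifest_path`,
#'   and `recordings` (list of `voc_recording`, waveforms retained only when
#'   `write_audio = FALSE`).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir,
                            profiles = NULL, write_audio = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(profiles)) {
    profiles <- lapply(stats::setNames(nm = config$vocalization_types),
                       default_severity_profiles)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  rows <- list()
  recs <- list()
  pid_idx <- 0L
  for (cls in 0:3) {
    for (i in seq_len(config$n_per_class[cls + 1])) {
      pid_idx <- pid_idx + 1L
      pid <- sprintf("P%03d", pid_idx)
      for (type in config$vocalization_types) {
        prof <- perturb_profile(profiles[[type]][[as.character(cls)]],
                                derive_seed(config$seed, pid_idx, "prof"))
        for (rep_i in seq_len(config$repetitions)) {
          rec_seed <- derive_seed(config$seed, pid_idx, type, rep_i)
          rec <- synthesizer_for(type)(prof, rec_seed)
          rec$participant_id <- pid
          rec$repetition <- rep_i
          fname <- sprintf("%s_%s_rep%d.wav", pid, type, rep_i)
          rec$path <- file.path(out_dir, fname)
          if (write_audio) {
            write_wav(rec$waveform, rec$path)
            rec$waveform <- NULL
          }
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = pid, path = rec$path,
            vocalization_type = type, repetition = rep_i,
            mmrc_reference = cls, stringsAsFactors = FALSE)
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 recordings = recs))
}

#' Read a cohort manifest CSV
#'
#' @param path manifest CSV path.
#' @return data.frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "path", "vocalization_type",
              "repetition", "mmrc_reference")
  missing <- setdiff(needed, names(m))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  m
}
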
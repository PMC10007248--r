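#' Severity profile for synthetic vocalization generation
#'
#' A severity profile describes how a given mMRC dyspnea class modulates
#' vocalization behavior: how long phonation can be sustained on one breath,
#' how often and how long involuntary pauses occur, the speaker's mean
#' fundamental frequency and how much it wanders, and the syllable rate
#' during counting.
#'
#' @param mmrc_class integer mMRC class in 0..3.
#' @param phonation_budget_s mean exhalation-limited phonation duration (s).
#' @param pause_rate expected involuntary pauses per 10 s of speech.
#' @param pause_len_s mean pause length (s).
#' @param f0_base_hz mean fundamental frequency (Hz).
#' @param f0_jitter_sd_hz standard deviation of the slow F0 wander (Hz).
#' @param syllable_rate_hz syllables per second during counting.
#' @return an object of class `severity_profile`.
#' @export
severity_profile <- function(mmrc_class, phonation_budget_s, pause_rate,
                             pause_len_s, f0_base_hz, f0_jitter_sd_hz,
                             syllable_rate_hz = 2.5) {
  stopifnot(mmrc_class %in% 0:3, phonation_budget_s > 0, pause_rate >= 0,
            pause_len_s >= 0, f0_base_hz > 0, f0_jitter_sd_hz >= 0,
            syllable_rate_hz > 0)
  structure(list(
    mmrc_class = as.integer(mmrc_class),
    phonation_budget_s = phonation_budget_s,
    pause_rate = pause_rate,
    pause_len_s = pause_len_s,
    f0_base_hz = f0_base_hz,
    f0_jitter_sd_hz = f0_jitter_sd_hz,
    syllable_rate_hz = syllable_rate_hz
  ), class = "severity_profile")
}

#' Default severity profile table
#'
#' One profile per mMRC class (0-3) for a given vocalization type. Phonation
#' budget decreases with severity while pause rate and F0 wander increase:
#' a dyspneic speaker runs out of breath sooner, pauses more, and holds
#' pitch less steadily. The /sa-sa/ budget is 20% shorter than /ae-ae/
#' because the open glottis during /s/ spends air faster; the counting
#' budgets are slightly longer because counting admits micro-inhalations.
#'
#' @param vocalization one of `"ae"`, `"sa"`, `"counting"`.
#' @return named list of four `severity_profile` objects (`"0"`..`"3"`).
#' @export
default_severity_profiles <- function(vocalization = c("ae", "sa", "counting")) {
  vocalization <- match.arg(vocalization)
  budgets <- switch(vocalization,
    ae       = c(12, 9, 6, 4),
    sa       = c(12, 9, 6, 4) * 0.8,
    counting = c(14, 10, 7, 5))
  pause_rates <- c(0.2, 1, 2, 4)        # per 10 s
  pause_lens  <- c(0.25, 0.35, 0.45, 0.6)
  jitters     <- c(2, 4, 7, 10)
  profs <- lapply(0:3, function(k) {
    severity_profile(
      mmrc_class = k,
      phonation_budget_s = budgets[k + 1],
      pause_rate = pause_rates[k + 1],
      pause_len_s = pause_lens[k + 1],
      f0_base_hz = 120,
      f0_jitter_sd_hz = jitters[k + 1],
      syllable_rate_hz = 2.5
    )
  })
  names(profs) <- as.character(0:3)
  profs
}

#' Cohort configuration
#'
#' Describes the synthetic study cohort: participants per mMRC class,
#' repetitions per vocalization, which vocalization types to record, and the
#' (fixed) telephone sampling rate. The default replicates the study design:
#' 34 healthy participants and 19/29/22 in classes 1-3 (the two most severe
#' participants are merged into class 3), two repetitions of three
#' vocalizations each, 624 recordings in total.
#'
#' @param n_per_class integer vector of length 4: participants per class 0-3.
#' @param repetitions repetitions per (participant, vocalization).
#' @param vocalization_types subset of `c("ae", "sa", "counting")`.
#' @param sample_rate_hz fixed at 8000.
#' @param seed integer seed for cohort synthesis.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(34L, 19L, 29L, 22L),
                          repetitions = 2L,
                          vocalization_types = c("ae", "sa", "counting"),
                          sample_rate_hz = 8000L,
                          seed = 1L) {
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 0),
            repetitions >= 1,
            all(vocalization_types %in% c("ae", "sa", "counting")),
            length(vocalization_types) >= 1)
  if (sample_rate_hz != 8000L) {
    stop("sample_rate_hz is fixed at 8000 Hz (telephone bandwidth)")
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    repetitions = as.integer(repetitions),
    vocalization_types = vocalization_types,
    sample_rate_hz = 8000L,
    seed = as.integer(seed)
  ), class = "cohort_config")
}
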
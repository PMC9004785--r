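# Seedable synthetic multichannel EEG: 1/f^beta Gaussian background plus a
# P300 deflection injected at every flashing of one of the target's two
# stimulus codes. Emulates the statistical structure the downstream ERP
# analysis assumes (it does not model blinks, EMG, line noise or volume
# conduction).

ANALYZED_CHANNELS <- c("Cz", "CP1", "CP2", "P7", "P3", "Pz", "P4", "P8",
                       "O1", "Oz", "O2")

#' Default per-channel P300 spatial gains
#'
#' Parieto-occipital dominant topography with P8 strongest: parietal 0.9
#' (P8 = 1.0), occipital 0.8, central 0.7.
#'
#' @return Named numeric vector over the 11 analyzed channels.
#' @export
default_channel_gains <- function() {
  c(Cz = 0.7, CP1 = 0.7, CP2 = 0.7,
    P7 = 0.9, P3 = 0.9, Pz = 0.9, P4 = 0.9, P8 = 1.0,
    O1 = 0.8, Oz = 0.8, O2 = 0.8)
}

#' Channel layout for simulation
#'
#' @param names Ordered channel labels; default the 11 analyzed
#'   centro-parieto-occipital electrodes.
#' @param gains Non-negative per-channel P300 spatial gains, recycled or
#'   matched by name against `names`.
#' @return A `channel_layout` object.
#' @export
channel_layout <- function(names = ANALYZED_CHANNELS,
                           gains = default_channel_gains()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop_speller("invalid_layout", "channel names must be unique")
  if (!is.null(base::names(gains))) gains <- gains[names]
  gains <- rep_len(as.numeric(gains), length(names))
  if (any(is.na(gains) | gains < 0)) {
    stop_speller("invalid_layout", "gains must be defined and non-negative for every channel")
  }
  structure(list(names = names, gains = stats::setNames(gains, names)),
            class = "channel_layout")
}

#' P300 waveform model
#'
#' @param amplitude_uv Peak amplitude in microvolts (default 5).
#' @param latency_ms Mean peak latency after flash onset (default 300).
#' @param latency_sd_ms Trial-to-trial latency jitter SD (default 25).
#' @param width_ms Half-width of the deflection: the waveform is at half
#'   amplitude `width_ms` from the peak and zero beyond `2 * width_ms`
#'   (default 80).
#' @param paradigm_gain Multiplicative amplitude factor applied under the
#'   3D-C paradigm relative to 2D-RC (default 1.3).
#' @return A `p300_model` object.
#' @export
p300_model <- function(amplitude_uv = 5, latency_ms = 300,
                       latency_sd_ms = 25, width_ms = 80,
                       paradigm_gain = 1.3) {
  stopifnot(amplitude_uv >= 0, width_ms > 0, paradigm_gain > 0,
            latency_sd_ms >= 0)
  structure(list(amplitude_uv = amplitude_uv, latency_ms = latency_ms,
                 latency_sd_ms = latency_sd_ms, width_ms = width_ms,
                 paradigm_gain = paradigm_gain),
            class = "p300_model")
}

#' Background-noise model
#'
#' Gaussian noise with a 1/f^beta power spectrum, scaled per channel to a
#' common standard deviation.
#'
#' @param sd_uv Standard deviation in microvolts (default 10).
#' @param spectral_exponent Power-law exponent beta in `[0, 2]` (default 1,
#'   i.e. pink noise).
#' @return A `noise_model` object.
#' @export
noise_model <- function(sd_uv = 10, spectral_exponent = 1) {
  stopifnot(sd_uv >= 0, spectral_exponent >= 0, spectral_exponent <= 2)
  structure(list(sd_uv = sd_uv, spectral_exponent = spectral_exponent),
            class = "noise_model")
}

#' Simulated-subject profile
#'
#' @param subject_id Identifier.
#' @param p300 A [p300_model()].
#' @param noise A [noise_model()].
#' @param layout A [channel_layout()].
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id = 1L, p300 = p300_model(),
                            noise = noise_model(), layout = channel_layout()) {
  stopifnot(inherits(p300, "p300_model"), inherits(noise, "noise_model"),
            inherits(layout, "channel_layout"))
  structure(list(subject_id = subject_id, p300 = p300, noise = noise,
                 layout = layout),
            class = "subject_profile")
}

#' Evaluate the P300 template waveform
#'
#' A raised-cosine (Hann) bump: peak `amplitude_uv` at `latency_ms`,
#' half amplitude at `latency_ms +/- width_ms`, identically zero outside
#' `latency_ms +/- 2 * width_ms`.
#'
#' @param t_ms Numeric time grid in ms after flash onset.
#' @param model A [p300_model()].
#' @param latency_ms Optional latency override (used for per-trial jitter).
#' @return Numeric waveform in microvolts, same length as `t_ms`.
#' @export
#' @examples
#' t <- seq(0, 1000, by = 4)
#' w <- p300_template(t, p300_model())
#' max(w) # 5
p300_template <- function(t_ms, model = p300_model(),
                          latency_ms = model$latency_ms) {
  u <- (t_ms - latency_ms) / (2 * model$width_ms)
  w <- ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  model$amplitude_uv * w
}

# FFT-filtered Gaussian noise with power spectral density ~ 1/f^beta,
# standardized to sd = 1 (beta = 0 falls back to white noise).
pink_noise <- function(n, beta) {
  if (n == 1L) return(rnorm(1))
  white <- rnorm(n)
  if (beta == 0) return(white)
  spec <- fft(white)
  freq <- c(1, seq_len(n - 1))  # DC bin reuses the fundamental's weight
  freq <- pmin(freq, n - freq + 1)
  spec <- spec * freq^(-beta / 2)
  x <- Re(fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

run_duration_ms <- function(run, tail_ms = 1000) {
  max(run$events$onset_ms) + run$soa_ms + tail_ms
}

#' Generate a synthetic EEG recording for one session
#'
#' Background noise is per-channel independent 1/f^beta Gaussian noise at
#' `noise$sd_uv`. For every flash event whose code is one of the run
#' target's two codes, the P300 template (latency jittered per trial,
#' scaled by the channel gains and, under 3D-C, by `paradigm_gain`) is
#' added over the second following the onset; overlapping responses sum
#' linearly. Runs are laid out back to back; breaks produce no samples.
#'
#' @param session A [generate_session()] schedule.
#' @param profile A [subject_profile()].
#' @param seed Integer seed controlling noise and latency jitter.
#' @param fs_hz Sampling rate (default 250).
#' @return An `eeg_recording`: list with `fs_hz`, `data` (channels x
#'   samples matrix, microvolts, rownames = channel names), and `markers`
#'   (data frame `sample`, `code`, `phase`, `run_index`, `target_char`;
#'   `sample` is the 1-based onset sample).
#' @export
generate_recording <- function(session, profile = subject_profile(),
                               seed = NULL, fs_hz = 250) {
  stopifnot(inherits(session, "session_schedule"),
            inherits(profile, "subject_profile"))
  layout <- profile$layout
  n_ch <- length(layout$names)
  ms_per_sample <- 1000 / fs_hz

  run_ms <- vapply(session$runs, run_duration_ms, 0)
  run_offset_ms <- cumsum(c(0, run_ms[-length(run_ms)]))
  n_samples <- ceiling(sum(run_ms) / ms_per_sample)

  seeds <- derive_seeds(seed, 2L)
  data <- with_seed(seeds[1], {
    if (profile$noise$sd_uv > 0) {
      t(vapply(seq_len(n_ch), function(ch) {
        profile$noise$sd_uv *
          pink_noise(n_samples, profile$noise$spectral_exponent)
      }, numeric(n_samples)))
    } else {
      matrix(0, n_ch, n_samples)
    }
  })
  rownames(data) <- layout$names

  p300 <- profile$p300
  pgain <- if (session$paradigm == "3D-C") p300$paradigm_gain else 1
  post_t <- (seq_len(fs_hz) - 1) * ms_per_sample  # 0 .. 996 ms at 250 Hz

  markers <- vector("list", length(session$runs))
  with_seed(seeds[2], {
    for (r in seq_along(session$runs)) {
      run <- session$runs[[r]]
      tc <- target_codes(run$target, session$matrix, session$paradigm)
      ev <- run$events
      onset_sample <- round((run_offset_ms[r] + ev$onset_ms) / ms_per_sample) + 1L
      if (any(onset_sample + fs_hz - 1L > n_samples)) {
        stop_speller("duration_error", "schedule extends beyond the allocated recording")
      }
      is_target <- ev$code %in% c(tc$column_code, tc$row_code)
      for (k in which(is_target)) {
        jitter <- if (p300$latency_sd_ms > 0) rnorm(1, 0, p300$latency_sd_ms) else 0
        wave <- p300_template(post_t, p300, latency_ms = p300$latency_ms + jitter)
        idx <- onset_sample[k] + seq_len(fs_hz) - 1L
        data[, idx] <- data[, idx] + pgain * outer(layout$gains, wave)
      }
      markers[[r]] <- data.frame(
        sample = onset_sample, code = ev$code, phase = ev$phase,
        run_index = r, target_char = run$target
      )
    }
  })

  structure(
    list(fs_hz = fs_hz, data = data, markers = do.call(rbind, markers),
         units = "uV", paradigm = session$paradigm,
         subject_id = profile$subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d markers (%s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$markers),
              x$paradigm))
  invisible(x)
}

#' Simulate a cohort under both paradigms
#'
#' Each simulated subject receives one recording per paradigm with the
#' same profile; the only systematic difference is the 3D-C amplitude
#' factor `paradigm_gain`. Per-subject P300 amplitudes (hence SNRs) are
#' drawn uniformly from `amplitude_range`.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param targets Target characters per session (default: seeded draw of
#'   60 symbols from the matrix).
#' @param matrix A `character_matrix`.
#' @param n_chars,n_trials,soa_ms Session geometry (defaults 60, 15, 175).
#' @param amplitude_range Range of per-subject P300 peak amplitudes in
#'   microvolts (default `c(4, 6)`).
#' @param p300,noise Template and noise models; the drawn amplitude
#'   replaces `p300$amplitude_uv` per subject.
#' @param layout A [channel_layout()].
#' @param seed Integer seed.
#' @return List of per-subject entries, each with `profile` and one
#'   `eeg_recording` per paradigm (named `"2D-RC"`, `"3D-C"`), plus the
#'   shared `session` schedules.
#' @export
simulate_cohort <- function(n_subjects = 10, targets = NULL,
                            matrix = build_character_matrix(),
                            n_chars = 60, n_trials = 15, soa_ms = 175,
                            amplitude_range = c(4, 6),
                            p300 = p300_model(), noise = noise_model(),
                            layout = channel_layout(), seed = NULL) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, 3L + 3L * n_subjects)
  if (is.null(targets)) {
    targets <- with_seed(seeds[1], sample(as.vector(unclass(matrix)), n_chars,
                                          replace = n_chars > 36))
  }
  amps <- with_seed(seeds[2], stats::runif(n_subjects, amplitude_range[1],
                                           amplitude_range[2]))
  lapply(seq_len(n_subjects), function(s) {
    p <- p300
    p$amplitude_uv <- amps[s]
    prof <- subject_profile(s, p, noise, layout)
    base <- 3L + 3L * (s - 1L)
    sessions <- list(
      "2D-RC" = generate_session(targets, "2D-RC", matrix, n_chars = n_chars,
                                 n_trials = n_trials, soa_ms = soa_ms,
                                 seed = seeds[base + 1L]),
      "3D-C" = generate_session(targets, "3D-C", matrix, n_chars = n_chars,
                                n_trials = n_trials, soa_ms = soa_ms,
                                seed = seeds[base + 2L])
    )
    rec_seeds <- derive_seeds(seeds[base + 3L], 2L)
    list(
      subject_id = s, profile = prof, sessions = sessions,
      recordings = list(
        "2D-RC" = generate_recording(sessions[["2D-RC"]], prof, rec_seeds[1]),
        "3D-C" = generate_recording(sessions[["3D-C"]], prof, rec_seeds[2])
      )
    )
  })
}
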
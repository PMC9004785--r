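# Shared fixture builders; everything is generated in code at test time.

default_matrix <- build_character_matrix()

# Noise- and jitter-free subject so injected waveforms are exact.
quiet_profile <- function(amplitude = 5, gain = 1.3) {
  subject_profile(
    subject_id = 1L,
    p300 = p300_model(amplitude_uv = amplitude, latency_sd_ms = 0,
                      paradigm_gain = gain),
    noise = noise_model(sd_uv = 0)
  )
}

tiny_session <- function(paradigm = "2D-RC", targets = c("J", "A", "3"),
                         n_trials = 3, soa_ms = 175, seed = 42) {
  generate_session(targets, paradigm, default_matrix,
                   n_chars = length(targets), n_trials = n_trials,
                   soa_ms = soa_ms, seed = seed)
}

# Template on the post-stimulus grid used by the recorder (250 Hz, 0..996 ms).
post_template <- function(profile, gain = 1) {
  gain * p300_template((0:249) * 4, profile$p300)
}

# Hand-built averaged_epochs + session pair for classifier tests: per run,
# the two target-code rows carry the template, the rest zeros (plus
# optional noise).
synthetic_averaged <- function(n_runs = 5, channels = "P8", noise_sd = 0,
                               seed = 1) {
  targets <- rep(c("J", "A", "3", "X", "Q", "-"), length.out = n_runs)
  session <- generate_session(targets, "2D-RC", default_matrix,
                              n_chars = n_runs, n_trials = 1, seed = seed)
  prof <- quiet_profile()
  tmpl <- post_template(prof)
  n <- n_runs * 12L
  data <- array(0, c(n, length(channels), 250),
                dimnames = list(NULL, channels, NULL))
  info <- data.frame(run_index = rep(seq_len(n_runs), each = 12),
                     code = rep(1:12, n_runs), n_averaged = 1L,
                     target_char = rep(targets, each = 12))
  set.seed(seed)
  for (i in seq_len(n)) {
    tc <- target_codes(targets[info$run_index[i]], default_matrix)
    base <- if (info$code[i] %in% c(tc$column_code, tc$row_code)) tmpl else 0
    for (ch in seq_along(channels)) {
      data[i, ch, ] <- base + if (noise_sd > 0) rnorm(250, 0, noise_sd) else 0
    }
  }
  avg <- structure(list(data = data, info = info, fs_hz = 250, n_post = 250),
                   class = "averaged_epochs")
  list(avg = avg, session = session)
}
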
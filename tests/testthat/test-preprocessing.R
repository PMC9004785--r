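# Build a bare recording around a given signal matrix.
manual_recording <- function(data, markers = NULL, fs = 250) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1,
                                         dimnames = list("P8", NULL))
  if (is.null(markers)) {
    markers <- data.frame(sample = integer(0), code = integer(0),
                          phase = integer(0), run_index = integer(0),
                          target_char = character(0))
  }
  structure(list(fs_hz = fs, data = data, markers = markers, units = "uV",
                 paradigm = "2D-RC", subject_id = 1L),
            class = "eeg_recording")
}

test_that("band-pass keeps the P300 band and rejects high frequencies", {
  fs <- 250
  t <- (0:4999) / fs
  trim <- 1001:4000
  rms <- function(x) sqrt(mean(x^2))
  rec5 <- manual_recording(sin(2 * pi * 5 * t))
  out5 <- bandpass(rec5, filter_spec())
  expect_equal(rms(out5$data[1, trim]) / rms(rec5$data[1, trim]), 1,
               tolerance = 0.1)
  rec50 <- manual_recording(sin(2 * pi * 50 * t))
  out50 <- bandpass(rec50, filter_spec())
  expect_lt(rms(out50$data[1, trim]) / rms(rec50$data[1, trim]), 0.05)
  recz <- manual_recording(rep(0, 1000))
  expect_true(all(bandpass(recz)$data == 0))
  expect_error(bandpass(rec5, filter_spec(band_hz = c(0.1, 150))),
               class = "filter_spec_error")
  expect_error(filter_spec(band_hz = c(10, 0.1)), class = "filter_spec_error")
  # markers unchanged
  mk <- data.frame(sample = 500L, code = 1L, phase = 1L, run_index = 1L,
                   target_char = "A")
  expect_identical(bandpass(manual_recording(sin(t), mk))$markers, mk)
})

test_that("epoch extraction yields one 300-sample epoch per marker", {
  sess <- tiny_session(targets = "J", n_trials = 15, seed = 1)
  rec <- generate_recording(sess, quiet_profile(), seed = 2)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(180, 11, 300))
  expect_equal(ep$n_pre, 50)
  expect_equal(ep$n_post, 250)
  expect_equal(ep$info$code, rec$markers$code)
  # repetition index counts presentations of each code in order
  expect_true(all(tapply(ep$info$repetition_index,
                         ep$info$code, identical, 1:15)))

  mk <- data.frame(sample = 10L, code = 1L, phase = 1L, run_index = 1L,
                   target_char = "A")
  expect_error(extract_epochs(manual_recording(rnorm(1000), mk)),
               class = "boundary_error")

  const <- manual_recording(rep(3.5, 2000),
                            data.frame(sample = c(300L, 900L), code = 1:2,
                                       phase = 1L, run_index = 1L,
                                       target_char = "A"))
  epc <- extract_epochs(const)
  expect_true(all(epc$data == 3.5))
})

test_that("baseline correction removes the pre-stimulus mean", {
  const <- manual_recording(rep(3.5, 2000),
                            data.frame(sample = c(300L, 900L), code = 1:2,
                                       phase = 1L, run_index = 1L,
                                       target_char = "A"))
  ep <- baseline_correct(extract_epochs(const))
  expect_true(all(abs(ep$data) < 1e-12))
  expect_error(baseline_correct(ep), class = "state_error")

  # template + DC offset: correction recovers the template exactly because
  # the template is zero over the pre-stimulus span
  prof <- quiet_profile()
  tmpl <- post_template(prof)
  sig <- rep(3, 2000)
  sig[600:849] <- sig[600:849] + tmpl
  mk <- data.frame(sample = 600L, code = 4L, phase = 1L, run_index = 1L,
                   target_char = "J")
  ep2 <- baseline_correct(extract_epochs(manual_recording(sig, mk)))
  expect_equal(unname(ep2$data[1, 1, 51:300]), tmpl)

  # pre-stimulus mean of any corrected epoch is 0
  noisy <- manual_recording(rnorm(5000),
                            data.frame(sample = c(1000L, 3000L), code = 1:2,
                                       phase = 1L, run_index = 1L,
                                       target_char = "A"))
  ep3 <- baseline_correct(extract_epochs(noisy))
  expect_equal(apply(ep3$data[, , 1:50, drop = FALSE], 1, mean),
               c(0, 0), tolerance = 1e-9)
})

test_that("per-code averaging uses the first n repetitions and is linear", {
  sess <- tiny_session(targets = "J", n_trials = 15, seed = 3)
  rec <- generate_recording(sess, quiet_profile(), seed = 4)
  ep <- baseline_correct(extract_epochs(rec))
  avg <- average_by_code(ep, 15)
  expect_equal(nrow(avg$info), 12)
  expect_equal(dim(avg$data), c(12, 11, 250))
  expect_error(average_by_code(ep, 16), class = "count_error")
  expect_error(average_by_code(extract_epochs(rec), 15),
               class = "state_error")

  # averaging identical epochs returns the epoch's post-stimulus part
  const <- manual_recording(rep(2, 4000),
                            data.frame(sample = c(500L, 1500L, 2500L),
                                       code = 1L, phase = 1L, run_index = 1L,
                                       target_char = "A"))
  epc <- baseline_correct(extract_epochs(const))
  expect_true(all(abs(average_by_code(epc, 3)$data) < 1e-12))

  # linearity: scaling epochs scales the average
  ep2 <- ep
  ep2$data <- 2.5 * ep$data
  expect_equal(average_by_code(ep2, 15)$data, 2.5 * avg$data)
})

test_that("averaging reduces i.i.d. noise as 1/sqrt(n)", {
  # 400 simulated single-channel runs of 15 repetitions of pure noise
  n_runs <- 400
  n_reps <- 15
  sigma <- 2
  set.seed(99)
  data <- array(rnorm(n_runs * n_reps * 300, 0, sigma),
                c(n_runs * n_reps, 1, 300), list(NULL, "P8", NULL))
  info <- data.frame(code = 1L,
                     phase = 1L,
                     run_index = rep(seq_len(n_runs), each = n_reps),
                     repetition_index = rep(seq_len(n_reps), n_runs),
                     target_char = "A")
  ep <- structure(list(data = data, info = info, fs_hz = 250,
                       window_ms = c(-200, 1000), n_pre = 50, n_post = 250,
                       baseline_corrected = TRUE),
                  class = "epoch_set")
  for (n in c(3, 15)) {
    avg <- average_by_code(ep, n)
    expect_equal(sd(avg$data), sigma / sqrt(n), tolerance = 0.05)
  }
})
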
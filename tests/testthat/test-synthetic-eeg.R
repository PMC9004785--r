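test_that("P300 template peaks at latency and vanishes outside support", {
  t_ms <- seq(0, 1000, by = 4)
  mod <- p300_model(amplitude_uv = 5, latency_ms = 300, width_ms = 80)
  w <- p300_template(t_ms, mod)
  expect_equal(w[t_ms == 300], 5.0)
  expect_true(all(w[abs(t_ms - 300) >= 2 * 80] == 0))
  expect_true(all(w >= 0))
  # positive integral (numeric quadrature)
  expect_gt(sum(w) * 4, 0)
  expect_equal(p300_template(t_ms, p300_model(amplitude_uv = 0)),
               rep(0, length(t_ms)))
  # half amplitude at one half-width from the peak
  expect_equal(w[t_ms == 380], 2.5)
})

test_that("noiseless injection reproduces the template exactly", {
  # SOA longer than the template support, so responses do not overlap
  sess <- tiny_session(targets = c("J", "A"), n_trials = 2, soa_ms = 1200,
                       seed = 1)
  prof <- quiet_profile()
  rec <- generate_recording(sess, prof, seed = 2)
  expect_equal(nrow(rec$markers), nrow(session_events(sess)))

  tmpl <- post_template(prof)
  mk <- rec$markers
  tc <- target_codes("J", default_matrix)
  for (code in c(tc$column_code, tc$row_code)) {
    s0 <- mk$sample[mk$run_index == 1 & mk$code == code][1]
    seg <- rec$data["P8", s0:(s0 + 249)]
    expect_equal(unname(seg), tmpl)
    expect_equal(unname(rec$data["Cz", s0:(s0 + 249)]), 0.7 * tmpl)
  }
  # non-target flashings receive nothing
  other <- mk$sample[mk$run_index == 1 &
                       !(mk$code %in% c(tc$column_code, tc$row_code))]
  for (s0 in other) {
    expect_true(all(abs(rec$data[, s0:(s0 + 55)]) == 0))
  }
  # injection locality: everything outside the post-onset second of some
  # target flashing is exactly zero
  hot <- rep(FALSE, ncol(rec$data))
  for (r in 1:2) {
    tcr <- target_codes(sess$runs[[r]]$target, default_matrix)
    for (s0 in mk$sample[mk$run_index == r &
                           mk$code %in% c(tcr$column_code, tcr$row_code)]) {
      hot[s0:(s0 + 249)] <- TRUE
    }
  }
  expect_true(all(rec$data[, !hot] == 0))
})

test_that("the 3D-C paradigm gain scales injected amplitudes", {
  prof <- quiet_profile(gain = 1.3)
  sess3 <- tiny_session("3D-C", targets = c("J", "A"), n_trials = 2,
                        soa_ms = 1200, seed = 1)
  rec3 <- generate_recording(sess3, prof, seed = 2)
  tc <- target_codes("J", default_matrix, "3D-C")
  s0 <- rec3$markers$sample[rec3$markers$run_index == 1 &
                             rec3$markers$code == tc$row_code][1]
  expect_equal(unname(rec3$data["P8", s0:(s0 + 249)]),
               1.3 * post_template(prof))
})

test_that("pure-noise recordings have near-zero mean and target sd", {
  sess <- tiny_session(targets = rep(c("J", "A", "3", "X"), 3), n_trials = 15,
                       seed = 3)
  prof <- subject_profile(1, p300_model(amplitude_uv = 0),
                          noise_model(sd_uv = 1))
  rec <- generate_recording(sess, prof, seed = 4)
  expect_gte(ncol(rec$data), 1e5)
  n <- ncol(rec$data)
  for (ch in c("P8", "Cz")) {
    expect_lt(abs(mean(rec$data[ch, ])), 3 / sqrt(n))
    expect_equal(sd(rec$data[ch, ]), 1, tolerance = 0.02)
  }
})

test_that("recordings are deterministic given a seed", {
  sess <- tiny_session(seed = 5)
  prof <- subject_profile(1, p300_model(), noise_model())
  r1 <- generate_recording(sess, prof, seed = 6)
  r2 <- generate_recording(sess, prof, seed = 6)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, generate_recording(sess, prof, seed = 7)$data))
})

test_that("cohorts pair paradigms per subject and respond to amplitude", {
  cohort <- simulate_cohort(n_subjects = 2, n_chars = 2, n_trials = 2,
                            seed = 8)
  expect_length(cohort, 2)
  recs <- unlist(lapply(cohort, function(s) s$recordings), recursive = FALSE)
  expect_length(recs, 4)
  expect_setequal(names(cohort[[1]]$recordings), c("2D-RC", "3D-C"))
  # same profile within subject
  expect_identical(cohort[[1]]$profile$p300$amplitude_uv,
                   cohort[[1]]$profile$p300$amplitude_uv)
  c2 <- simulate_cohort(n_subjects = 2, n_chars = 2, n_trials = 2, seed = 8)
  expect_identical(cohort[[1]]$recordings[["2D-RC"]]$data,
                   c2[[1]]$recordings[["2D-RC"]]$data)

  # larger P300 amplitude -> larger mean target-epoch peak at fixed noise
  peak_for <- function(amp) {
    sess <- tiny_session(targets = c("J", "A"), n_trials = 3, seed = 10)
    prof <- subject_profile(1, p300_model(amplitude_uv = amp),
                            noise_model(sd_uv = 2))
    rec <- generate_recording(sess, prof, seed = 11)
    avg <- average_by_code(baseline_correct(extract_epochs(rec)), 3)
    tc <- target_codes("J", default_matrix)
    sel <- avg$info$run_index == 1 & avg$info$code %in% c(tc$column_code,
                                                          tc$row_code)
    mean(apply(avg$data[sel, "P8", , drop = FALSE], 1, max))
  }
  expect_lt(peak_for(2), peak_for(5))
  expect_lt(peak_for(5), peak_for(9))
})

test_that("averaged target epochs converge to the template as reps grow", {
  sess <- tiny_session(targets = "J", n_trials = 15, soa_ms = 1200, seed = 12)
  prof <- subject_profile(1, p300_model(latency_sd_ms = 0),
                          noise_model(sd_uv = 4))
  rec <- generate_recording(sess, prof, seed = 13)
  ep <- baseline_correct(extract_epochs(rec))
  tmpl <- post_template(quiet_profile())
  l2 <- vapply(c(1, 3, 15), function(n) {
    avg <- average_by_code(ep, n)
    sel <- which(avg$info$code == 4)
    sqrt(sum((avg$data[sel, "P8", ] - tmpl)^2))
  }, 0)
  expect_true(all(diff(l2) < 0))
})
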
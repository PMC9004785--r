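# ERP preprocessing: band-pass filtering, epoching around flash onsets,
# pre-stimulus baseline correction, and per-code repetition averaging.

#' Band-pass filter specification
#'
#' @param band_hz Length-2 numeric passband in Hz (default `c(0.1, 10)`,
#'   the P300 band).
#' @param order Overall Butterworth order; must be even (default 4).
#' @param zero_phase Apply forward-backward (zero-phase) filtering
#'   (default TRUE).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(band_hz = c(0.1, 10), order = 4, zero_phase = TRUE) {
  stopifnot(length(band_hz) == 2, order >= 2, order %% 2 == 0)
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2])) {
    stop_speller("filter_spec_error", "need 0 < low < high")
  }
  structure(list(band_hz = as.numeric(band_hz), order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass (order `spec$order`, realized as order/2 pole
#' pairs per edge by [signal::butter()]) applied per channel, forward and
#' backward when `zero_phase`. Markers are unchanged.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, spec)
  nyq <- recording$fs_hz / 2
  if (spec$band_hz[2] >= nyq) {
    stop_speller("filter_spec_error",
                 "upper band edge %g Hz is not below Nyquist (%g Hz)",
                 spec$band_hz[2], nyq)
  }
  bf <- signal::butter(spec$order / 2, spec$band_hz / nyq, type = "pass")
  apply_fun <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- recording
  out$data <- t(apply(recording$data, 1, apply_fun))
  rownames(out$data) <- rownames(recording$data)
  out
}

#' Extract flash-locked epochs
#'
#' Cuts one epoch per marker over `window_ms` relative to flash onset.
#' The sample at the onset is the first post-stimulus sample; the
#' pre-stimulus window is the 50 samples before it (at 250 Hz and the
#' default -200..+1000 ms window, 300 samples per epoch).
#'
#' @param recording An `eeg_recording`.
#' @param window_ms Length-2 window in ms around onset (default
#'   `c(-200, 1000)`).
#' @return An `epoch_set`: `data` is an array
#'   `[epoch, channel, sample]`; `info` a data frame with `code`,
#'   `phase`, `run_index`, `repetition_index` (presentation order of that
#'   code within its run), `target_char`.
#' @export
extract_epochs <- function(recording, window_ms = c(-200, 1000)) {
  stopifnot(inherits(recording, "eeg_recording"), length(window_ms) == 2,
            window_ms[1] <= 0, window_ms[2] > 0)
  fs <- recording$fs_hz
  n_pre <- round(-window_ms[1] * fs / 1000)
  n_post <- round(window_ms[2] * fs / 1000)
  mk <- recording$markers
  n_samples <- ncol(recording$data)
  bad <- mk$sample - n_pre < 1 | mk$sample + n_post - 1 > n_samples
  if (any(bad)) {
    stop_speller("boundary_error",
                 "marker at sample %d (run %d, code %d) is too close to the record edge",
                 mk$sample[which(bad)[1]], mk$run_index[which(bad)[1]],
                 mk$code[which(bad)[1]])
  }
  n_ch <- nrow(recording$data)
  n_ep <- nrow(mk)
  len <- n_pre + n_post
  data <- array(0, c(n_ep, n_ch, len),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (e in seq_len(n_ep)) {
    idx <- (mk$sample[e] - n_pre):(mk$sample[e] + n_post - 1L)
    data[e, , ] <- recording$data[, idx]
  }
  rep_index <- stats::ave(seq_len(n_ep), mk$run_index, mk$code,
                          FUN = seq_along)
  structure(
    list(data = data,
         info = data.frame(code = mk$code, phase = mk$phase,
                           run_index = mk$run_index,
                           repetition_index = rep_index,
                           target_char = mk$target_char),
         fs_hz = fs, window_ms = window_ms, n_pre = n_pre, n_post = n_post,
         baseline_corrected = FALSE),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g..%g ms)%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$window_ms[1], x$window_ms[2],
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Per epoch and channel, subtracts the scalar mean of the pre-stimulus
#' samples (the 200 ms before onset at the defaults) from the whole
#' epoch, so the pre-stimulus mean of the output is zero.
#'
#' @param epochs An `epoch_set` not yet corrected.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$baseline_corrected) {
    stop_speller("state_error", "epochs are already baseline-corrected")
  }
  if (epochs$n_pre < 1) {
    stop_speller("state_error", "no pre-stimulus samples to estimate a baseline from")
  }
  pre <- seq_len(epochs$n_pre)
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over sample dim
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Average epochs per stimulus code
#'
#' Within each run, the first `n_reps` presentations of each code (in
#' presentation order) are averaged element-wise and cropped to the
#' post-stimulus second, yielding 12 averaged responses per run.
#'
#' @param epochs A baseline-corrected `epoch_set`.
#' @param n_reps Repetitions entering the average (1, 3, or 15 in the
#'   standard protocol; any count up to the available repetitions works).
#' @return An `averaged_epochs` object: `data` is
#'   `[run * code, channel, post-stimulus sample]`; `info` has
#'   `run_index`, `code`, `n_averaged`, `target_char`.
#' @export
average_by_code <- function(epochs, n_reps = 15) {
  stopifnot(inherits(epochs, "epoch_set"), is_count(n_reps))
  if (!epochs$baseline_corrected) {
    stop_speller("state_error", "baseline-correct epochs before averaging")
  }
  info <- epochs$info
  post <- epochs$n_pre + seq_len(epochs$n_post)
  keys <- unique(info[, c("run_index", "code")])
  keys <- keys[order(keys$run_index, keys$code), ]
  n_ch <- dim(epochs$data)[2]
  out <- array(0, c(nrow(keys), n_ch, epochs$n_post),
               dimnames = list(NULL, dimnames(epochs$data)[[2]], NULL))
  tgt <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- which(info$run_index == keys$run_index[i] &
                   info$code == keys$code[i] &
                   info$repetition_index <= n_reps)
    if (length(sel) < n_reps) {
      stop_speller("count_error",
                   "run %d code %d has %d repetitions, need %d",
                   keys$run_index[i], keys$code[i], length(sel), n_reps)
    }
    seg <- epochs$data[sel, , post, drop = FALSE]
    out[i, , ] <- colMeans(seg)  # averages over the repetition dimension
    tgt[i] <- info$target_char[sel[1]]
  }
  structure(
    list(data = out,
         info = data.frame(run_index = keys$run_index, code = keys$code,
                           n_averaged = n_reps, target_char = tgt),
         fs_hz = epochs$fs_hz, n_post = epochs$n_post),
    class = "averaged_epochs"
  )
}

#' @export
print.averaged_epochs <- function(x, ...) {
  cat(sprintf("<averaged_epochs> %d averages (%d reps) x %d channels x %d samples\n",
              dim(x$data)[1], x$info$n_averaged[1], dim(x$data)[2],
              dim(x$data)[3]))
  invisible(x)
}

#' Run the standard preprocessing chain
#'
#' Band-pass filter, epoch, baseline-correct.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [filter_spec()], or NULL to skip filtering.
#' @param window_ms Epoch window.
#' @return A baseline-corrected `epoch_set`.
#' @export
preprocess <- function(recording, spec = filter_spec(),
                       window_ms = c(-200, 1000)) {
  if (!is.null(spec)) recording <- bandpass(recording, spec)
  baseline_correct(extract_epochs(recording, window_ms))
}
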
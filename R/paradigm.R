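# Flashing-schedule generation for the 2D row-column (2D-RC) and 3D
# column-only (3D-C) speller paradigms.
#
# Stimulus codes share one code space across both paradigms:
#   1..6  = columns left-to-right (phase 1 in 3D-C),
#   7..12 = rows top-to-bottom (2D-RC) or transposed-row columns (3D-C
#           phase 2, where former row r flashes as column code 6 + r).

PARADIGMS <- c("2D-RC", "3D-C")

#' Default 36-symbol speller alphabet
#'
#' Row-major A--Z, digits 1--9, and '-' arranged on a 6x6 grid, so that
#' 'J' sits in row 2, column 4.
#'
#' @return Character vector of 36 distinct symbols.
#' @export
#' @examples
#' default_speller_alphabet()
default_speller_alphabet <- function() {
  c(LETTERS, as.character(1:9), "-")
}

#' Build a 6x6 speller character matrix
#'
#' @param symbols Ordered character vector of exactly 36 distinct printable
#'   symbols, filled row-major onto the 6x6 grid.
#' @return A `character_matrix` object (a 6x6 character matrix).
#' @export
#' @examples
#' m <- build_character_matrix()
#' matrix_lookup(m, row = 2, col = 4) # "J"
build_character_matrix <- function(symbols = default_speller_alphabet()) {
  symbols <- as.character(symbols)
  if (length(symbols) != 36L || anyDuplicated(symbols) ||
      any(is.na(symbols)) || any(nchar(symbols) != 1L)) {
    stop_speller("invalid_alphabet",
                 "a speller alphabet needs 36 distinct single-character symbols (got %d)",
                 length(unique(symbols)))
  }
  m <- matrix(symbols, nrow = 6, ncol = 6, byrow = TRUE)
  class(m) <- c("character_matrix", class(m))
  m
}

#' Look up the symbol at a grid position
#'
#' @param matrix A `character_matrix`.
#' @param row,col Grid indices in 1..6.
#' @return The symbol at `(row, col)`.
#' @export
matrix_lookup <- function(matrix, row, col) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!is_count(row) || !is_count(col) || row > 6 || col > 6) {
    stop_speller("invalid_position", "row and col must be integers in 1..6")
  }
  matrix[row, col]
}

#' Find the grid position of a symbol
#'
#' @param matrix A `character_matrix`.
#' @param symbol A single symbol present in the matrix.
#' @return Named integer vector `c(row =, col =)`.
#' @export
matrix_position <- function(matrix, symbol) {
  stopifnot(inherits(matrix, "character_matrix"))
  idx <- which(unclass(matrix) == symbol)
  if (length(idx) != 1L) {
    stop_speller("unknown_target", "symbol '%s' is not in the character matrix", symbol)
  }
  c(row = as.integer((idx - 1L) %% 6L) + 1L,
    col = as.integer((idx - 1L) %/% 6L) + 1L)
}

#' Stimulus codes that carry the P300 for a target character
#'
#' For both paradigms the target elicits P300s at exactly two codes: its
#' column (codes 1--6) and its row (codes 7--12). Under 3D-C the row code
#' is flashed in phase 2, after the grid transposition, as column `row`.
#'
#' @param target Target symbol.
#' @param matrix A `character_matrix`.
#' @param paradigm `"2D-RC"` or `"3D-C"`.
#' @return List with `column_code`, `row_code`, and `phases` (the phase in
#'   which each code is flashed: `c(1, 1)` for 2D-RC, `c(1, 2)` for 3D-C).
#' @export
#' @examples
#' target_codes("J", build_character_matrix(), "2D-RC") # column 4, row code 8
target_codes <- function(target, matrix, paradigm = c("2D-RC", "3D-C")) {
  paradigm <- match.arg(paradigm)
  pos <- matrix_position(matrix, target)
  list(
    column_code = unname(pos["col"]),
    row_code    = unname(pos["row"]) + 6L,
    phases      = if (paradigm == "3D-C") c(1L, 2L) else c(1L, 1L)
  )
}

new_run_schedule <- function(paradigm, target, events, n_trials, soa_ms,
                             lead_in_ms, pause_ms = NA_real_) {
  structure(
    list(paradigm = paradigm, target = target, events = events,
         n_trials = n_trials, soa_ms = soa_ms, lead_in_ms = lead_in_ms,
         pause_ms = pause_ms),
    class = "run_schedule"
  )
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("<run_schedule> paradigm %s, target '%s', %d events (%d trials, SOA %g ms)\n",
              x$paradigm, x$target, nrow(x$events), x$n_trials, x$soa_ms))
  invisible(x)
}

# One block = one random permutation of the given codes.
permutation_blocks <- function(codes, n_blocks) {
  unlist(lapply(seq_len(n_blocks), function(i) sample(codes)), use.names = FALSE)
}

check_schedule_args <- function(n_trials, soa_ms) {
  if (!is_count(n_trials)) stop_speller("invalid_schedule", "n_trials must be a positive integer")
  if (!is.numeric(soa_ms) || soa_ms <= 0) stop_speller("invalid_schedule", "soa_ms must be > 0")
}

#' Generate a 2D-RC run schedule
#'
#' One run flashes each of the 12 row/column stimuli `n_trials` times, in
#' `n_trials` consecutive blocks each holding an independent uniform random
#' permutation of codes 1..12. Consecutive onsets are `soa_ms` apart
#' (100 ms flash + 75 ms inter-stimulus interval at the defaults). The
#' target is displayed alone for `lead_in_ms` before flashing starts.
#'
#' @param target Target symbol (metadata; does not influence the timing).
#' @param matrix A `character_matrix` containing `target`.
#' @param n_trials Repetitions per code (default 15, i.e. 180 flashings).
#' @param soa_ms Onset-to-onset spacing in ms (default 175).
#' @param flash_ms Intensification duration in ms (default 100).
#' @param lead_in_ms Target display time before the first flash (default 5000).
#' @param seed Integer seed; equal seeds give identical schedules.
#' @return A `run_schedule` whose `events` data frame has columns
#'   `onset_ms`, `code`, `phase`, `flash_duration_ms`.
#' @export
#' @examples
#' s <- generate_rc_schedule("J", seed = 1)
#' nrow(s$events) # 180
generate_rc_schedule <- function(target, matrix = build_character_matrix(),
                                 n_trials = 15, soa_ms = 175, flash_ms = 100,
                                 lead_in_ms = 5000, seed = NULL) {
  check_schedule_args(n_trials, soa_ms)
  matrix_position(matrix, target)  # validates target
  codes <- with_seed(seed, permutation_blocks(1:12, n_trials))
  n <- length(codes)
  events <- data.frame(
    onset_ms = lead_in_ms + (seq_len(n) - 1) * soa_ms,
    code = codes,
    phase = 1L,
    flash_duration_ms = flash_ms
  )
  new_run_schedule("2D-RC", target, events, n_trials, soa_ms, lead_in_ms)
}

#' Generate a 3D-C run schedule
#'
#' Phase 1 flashes the six columns (codes 1--6) in `n_trials` permutation
#' blocks. The grid is then transposed and the target re-displayed for
#' `pause_ms`; phase 2 flashes the transposed rows as columns (codes
#' 7--12) in another `n_trials` permutation blocks.
#'
#' @inheritParams generate_rc_schedule
#' @param pause_ms Target display time at the transposition (default 5000).
#' @return A `run_schedule`; `phase` is 1 or 2 per event.
#' @export
#' @examples
#' s <- generate_3dc_schedule("J", seed = 1)
#' table(s$events$phase) # 90 and 90
generate_3dc_schedule <- function(target, matrix = build_character_matrix(),
                                  n_trials = 15, soa_ms = 175, flash_ms = 100,
                                  pause_ms = 5000, lead_in_ms = 5000,
                                  seed = NULL) {
  check_schedule_args(n_trials, soa_ms)
  if (!is.numeric(pause_ms) || pause_ms < 0) {
    stop_speller("invalid_schedule", "pause_ms must be >= 0")
  }
  matrix_position(matrix, target)
  seeds <- derive_seeds(seed, 2L)
  p1 <- with_seed(seeds[1], permutation_blocks(1:6, n_trials))
  p2 <- with_seed(seeds[2], permutation_blocks(7:12, n_trials))
  n1 <- length(p1)
  onset1 <- lead_in_ms + (seq_len(n1) - 1) * soa_ms
  # phase 2 starts after the last phase-1 flash completes its SOA slot plus
  # the transposed-target display pause
  start2 <- lead_in_ms + n1 * soa_ms + pause_ms
  onset2 <- start2 + (seq_len(n1) - 1) * soa_ms
  events <- data.frame(
    onset_ms = c(onset1, onset2),
    code = c(p1, p2),
    phase = rep(c(1L, 2L), each = n1),
    flash_duration_ms = flash_ms
  )
  new_run_schedule("3D-C", target, events, n_trials, soa_ms, lead_in_ms,
                   pause_ms)
}

#' Generate a full speller session schedule
#'
#' A session presents 60 target characters (60 runs); a 3-minute break
#' follows every 15th run. Breaks are schedule metadata only -- they carry
#' no events and no EEG.
#'
#' @param targets Character vector of target symbols, one per run
#'   (default length 60; other lengths raise a session-size error unless
#'   `n_chars` is lowered to match).
#' @param paradigm `"2D-RC"` or `"3D-C"`.
#' @param matrix A `character_matrix`.
#' @param n_chars Required number of runs (default 60).
#' @param break_every Runs between breaks (default 15).
#' @param seed Integer seed; per-run randomization streams are derived
#'   from it so equal seeds give identical sessions.
#' @inheritParams generate_rc_schedule
#' @inheritParams generate_3dc_schedule
#' @return A `session_schedule`: list of `run_schedule`s plus metadata.
#' @export
generate_session <- function(targets, paradigm = c("2D-RC", "3D-C"),
                             matrix = build_character_matrix(),
                             n_chars = 60, n_trials = 15, soa_ms = 175,
                             flash_ms = 100, pause_ms = 5000,
                             lead_in_ms = 5000, break_every = 15,
                             seed = NULL) {
  paradigm <- match.arg(paradigm)
  targets <- as.character(targets)
  if (length(targets) != n_chars) {
    stop_speller("session_size",
                 "a session needs exactly %d targets (got %d)",
                 n_chars, length(targets))
  }
  run_seeds <- derive_seeds(seed, length(targets))
  runs <- lapply(seq_along(targets), function(i) {
    if (paradigm == "2D-RC") {
      generate_rc_schedule(targets[i], matrix, n_trials, soa_ms, flash_ms,
                           lead_in_ms, seed = run_seeds[i])
    } else {
      generate_3dc_schedule(targets[i], matrix, n_trials, soa_ms, flash_ms,
                            pause_ms, lead_in_ms, seed = run_seeds[i])
    }
  })
  structure(
    list(paradigm = paradigm, runs = runs, matrix = matrix,
         break_after = seq_len((length(runs) - 1) %/% break_every) * break_every,
         n_trials = n_trials, soa_ms = soa_ms, seed = seed),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> paradigm %s, %d runs, %d events total\n",
              x$paradigm, length(x$runs),
              sum(vapply(x$runs, function(r) nrow(r$events), 0L))))
  invisible(x)
}

#' Flatten a session schedule to one event table
#'
#' @param session A `session_schedule`.
#' @return Data frame with columns `run_index`, `target_char`, `onset_ms`,
#'   `code`, `phase`, `flash_duration_ms` (onsets are run-relative).
#' @export
session_events <- function(session) {
  stopifnot(inherits(session, "session_schedule"))
  do.call(rbind, lapply(seq_along(session$runs), function(i) {
    ev <- session$runs[[i]]$events
    cbind(data.frame(run_index = i, target_char = session$runs[[i]]$target),
          ev)
  }))
}

#' Write / read a session schedule as TSV
#'
#' The event table is written tab-separated with a header; paradigm, seed,
#' SOA and the alphabet go to a key-value sidecar (`<path>.meta`).
#'
#' @param session A `session_schedule`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(session, path) {
  ev <- session_events(session)
  ev <- ev[, c("onset_ms", "code", "phase", "run_index", "target_char")]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(
    paradigm = session$paradigm,
    seed = if (is.null(session$seed)) "NA" else as.character(session$seed),
    soa_ms = as.character(session$soa_ms),
    n_trials = as.character(session$n_trials),
    alphabet = paste(t(unclass(session$matrix)), collapse = "")
  )
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("numeric", "integer", "integer",
                                  "integer", "character"))
  meta_lines <- strsplit(readLines(paste0(path, ".meta")), "\t")
  meta <- stats::setNames(vapply(meta_lines, `[`, "", 2),
                          vapply(meta_lines, `[`, "", 1))
  list(events = ev, paradigm = unname(meta["paradigm"]),
       soa_ms = as.numeric(meta["soa_ms"]),
       n_trials = as.integer(meta["n_trials"]),
       alphabet = strsplit(unname(meta["alphabet"]), "")[[1]])
}
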
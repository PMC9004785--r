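# End-to-end study orchestration: simulate a cohort under both paradigms,
# run the preprocessing / detection / decoding pipeline over every
# electrode set and flashing count, and assemble the report tables
# (detection accuracies, ACRC, character counts, improvements, paired
# significance tests), plus recording serialization and fixture bundles.

#' Study configuration
#'
#' Defaults reproduce the reference protocol geometry: 10 subjects, 60
#' characters per session, 15 trials per code at a 175 ms SOA, 250 Hz,
#' flashing counts 1/3/15, the 15 electrode sets, 70/15/15 splits
#' repeated 20 times.
#'
#' @param n_subjects,n_chars,n_trials,soa_ms,fs_hz Cohort and session
#'   geometry.
#' @param flashing_counts Repetition counts evaluated (default
#'   `c(1, 3, 15)`).
#' @param electrode_sets Named list of channel sets (default
#'   [electrode_sets()]: 11 singles + 4 groups).
#' @param amplitude_range Per-subject P300 amplitude range, microvolts.
#' @param p300,noise Simulation models (see [p300_model()],
#'   [noise_model()]).
#' @param train A [train_config()].
#' @param filter A [filter_spec()], or NULL to skip filtering.
#' @param seed Master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 10, n_chars = 60, n_trials = 15,
                         soa_ms = 175, fs_hz = 250,
                         flashing_counts = c(1, 3, 15),
                         electrode_sets = speller3d::electrode_sets(),
                         amplitude_range = c(4, 6),
                         p300 = p300_model(), noise = noise_model(),
                         train = train_config(), filter = filter_spec(),
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_chars >= 1, n_trials >= 1,
            all(flashing_counts >= 1), all(flashing_counts <= n_trials))
  structure(as.list(environment()), class = "study_config")
}

#' Run the full simulated study
#'
#' Simulates `n_subjects` paired sessions (2D-RC and 3D-C), preprocesses
#' each recording, and for every subject x paradigm x flashing count x
#' electrode set evaluates P300 detection; per subject, paradigm and
#' flashing count the 15 electrode-set accuracies form a radar profile
#' whose ACRC is reported; character recognition runs 3-fold CV on the
#' Group 4 features. Mean summaries, relative improvements and paired
#' tests compare the paradigms.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return A `study_report`: list of data frames `detection` (subject,
#'   paradigm, flashings, electrode_set, accuracy, sd), `acrc`
#'   (subject, paradigm, flashings, acrc), `characters` (subject,
#'   paradigm, flashings, fold columns, mean), `summary`, `improvements`,
#'   `significance`.
#' @export
run_study <- function(config = study_config(), verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  seeds <- derive_seeds(config$seed, 2L)

  say("simulating cohort (%d subjects, %d chars, seed %d)",
      config$n_subjects, config$n_chars, config$seed)
  cohort <- simulate_cohort(
    n_subjects = config$n_subjects, n_chars = config$n_chars,
    n_trials = config$n_trials, soa_ms = config$soa_ms,
    amplitude_range = config$amplitude_range, p300 = config$p300,
    noise = config$noise, seed = seeds[1]
  )

  set_names <- names(config$electrode_sets)
  detection <- list()
  acrc_rows <- list()
  char_rows <- list()
  eval_seeds <- derive_seeds(seeds[2], config$n_subjects)

  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    sseeds <- derive_seeds(eval_seeds[s],
                           2L * length(config$flashing_counts) *
                             (length(set_names) + 1L))
    k <- 0L
    for (paradigm in c("2D-RC", "3D-C")) {
      say("subject %d, %s: preprocessing", s, paradigm)
      epochs <- preprocess(subj$recordings[[paradigm]], config$filter)
      session <- subj$sessions[[paradigm]]
      for (fl in config$flashing_counts) {
        avg <- average_by_code(epochs, fl)
        accs <- numeric(length(set_names))
        for (i in seq_along(set_names)) {
          k <- k + 1L
          ds <- build_dataset(avg, session, set_names[i])
          res <- evaluate_detection(ds, config$train, seed = sseeds[k])
          accs[i] <- res$mean_accuracy
          detection[[length(detection) + 1L]] <- data.frame(
            subject = s, paradigm = paradigm, flashings = fl,
            electrode_set = set_names[i], accuracy = res$mean_accuracy,
            sd = res$sd_accuracy
          )
        }
        if (identical(set_names, radar_labels())) {
          acrc_rows[[length(acrc_rows) + 1L]] <- data.frame(
            subject = s, paradigm = paradigm, flashings = fl,
            acrc = acrc(accs / 100)
          )
        }
        k <- k + 1L
        if ("Group4" %in% set_names &&
            config$n_chars %% 3 == 0 && config$n_chars >= 3) {
          ds4 <- build_dataset(avg, session, "Group4")
          cr <- character_cv(ds4, session, config$train, seed = sseeds[k])
          char_rows[[length(char_rows) + 1L]] <- data.frame(
            subject = s, paradigm = paradigm, flashings = fl,
            mean_correct = cr$mean_correct, n_test = cr$per_fold$n_test[1],
            percent = cr$mean_percent
          )
        }
      }
    }
  }

  detection <- do.call(rbind, detection)
  acrc_tab <- if (length(acrc_rows)) do.call(rbind, acrc_rows) else NULL
  characters <- if (length(char_rows)) do.call(rbind, char_rows) else NULL

  report <- structure(
    list(detection = detection, acrc = acrc_tab, characters = characters,
         config = config),
    class = "study_report"
  )
  report$summary <- summarize_study(report)
  report$improvements <- study_improvements(report)
  report$significance <- study_significance(report)
  report
}

# Mean/sd over subjects for each measured table.
summarize_study <- function(report) {
  out <- list()
  agg <- function(df, value, table) {
    do.call(rbind, lapply(split(df, df[c("paradigm", "flashings")], drop = TRUE),
                          function(g) {
      s <- summarize_table(g[[value]])
      data.frame(table = table, paradigm = g$paradigm[1],
                 flashings = g$flashings[1], mean = s$mean_raw, sd = s$sd_raw)
    }))
  }
  if (!is.null(report$acrc)) out$acrc <- agg(report$acrc, "acrc", "acrc")
  for (set in intersect(c("P8", "Group4"), unique(report$detection$electrode_set))) {
    out[[set]] <- agg(report$detection[report$detection$electrode_set == set, ],
                      "accuracy", set)
  }
  if (!is.null(report$characters)) {
    out$characters <- agg(report$characters, "percent", "characters")
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Relative improvement of 3D-C over 2D-RC per table and flashing count.
study_improvements <- function(report) {
  sm <- report$summary
  do.call(rbind, lapply(split(sm, sm[c("table", "flashings")], drop = TRUE),
                        function(g) {
    b <- g$mean[g$paradigm == "2D-RC"]
    p <- g$mean[g$paradigm == "3D-C"]
    if (!length(b) || !length(p) || b <= 0) return(NULL)
    data.frame(table = g$table[1], flashings = g$flashings[1],
               baseline_mean = b, proposed_mean = p,
               improvement_pct = relative_improvement(b, p))
  }))
}

# Paired per-subject tests of 3D-C vs 2D-RC.
study_significance <- function(report) {
  rows <- list()
  test_block <- function(df, value, table) {
    lapply(split(df, df$flashings), function(g) {
      a <- g[[value]][g$paradigm == "2D-RC"][order(g$subject[g$paradigm == "2D-RC"])]
      b <- g[[value]][g$paradigm == "3D-C"][order(g$subject[g$paradigm == "3D-C"])]
      if (length(a) < 2 || length(a) != length(b)) return(NULL)
      pt <- tryCatch(paired_test(a, b), error = function(e) NULL)
      if (is.null(pt)) return(NULL)  # degenerate (near-constant) differences
      data.frame(table = table, flashings = g$flashings[1], t_stat = pt$t_stat,
                 df = pt$df, p_value = pt$p_value,
                 significant_05 = pt$significant_05,
                 significant_01 = pt$significant_01)
    })
  }
  if (!is.null(report$acrc)) {
    rows <- c(rows, test_block(report$acrc, "acrc", "acrc"))
  }
  for (set in intersect(c("P8", "Group4"), unique(report$detection$electrode_set))) {
    rows <- c(rows, test_block(report$detection[report$detection$electrode_set == set, ],
                               "accuracy", set))
  }
  if (!is.null(report$characters)) {
    rows <- c(rows, test_block(report$characters, "percent", "characters"))
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, %d detection cells\n",
              x$config$n_subjects, nrow(x$detection)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write a study report as tab-separated tables
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("detection", "acrc", "characters", "summary",
               "improvements", "significance")) {
    if (!is.null(report[[nm]])) {
      write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Write / read an EEG recording as plain text
#'
#' The signal goes to `<path>` as a tab-separated channels x samples
#' numeric table (row names = channel labels), the markers to
#' `<path>.markers.tsv`, and sampling metadata to `<path>.meta`.
#'
#' @param recording An `eeg_recording`.
#' @param path Output path.
#' @return `path` invisibly; `read_recording_tsv()` returns the
#'   `eeg_recording`.
#' @export
write_recording_tsv <- function(recording, path) {
  write.table(recording$data, path, sep = "\t", quote = FALSE,
              col.names = FALSE)
  write.table(recording$markers, paste0(path, ".markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- c(fs_hz = recording$fs_hz, units = recording$units,
            paradigm = recording$paradigm,
            subject_id = recording$subject_id)
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, row.names = 1)
  data <- as.matrix(raw)
  colnames(data) <- NULL
  markers <- read.table(paste0(path, ".markers.tsv"), sep = "\t",
                        header = TRUE,
                        colClasses = c("integer", "integer", "integer",
                                       "integer", "character"))
  meta_lines <- strsplit(readLines(paste0(path, ".meta")), "\t")
  meta <- stats::setNames(vapply(meta_lines, `[`, "", 2),
                          vapply(meta_lines, `[`, "", 1))
  structure(
    list(fs_hz = as.numeric(meta["fs_hz"]), data = data, markers = markers,
         units = unname(meta["units"]), paradigm = unname(meta["paradigm"]),
         subject_id = as.integer(meta["subject_id"])),
    class = "eeg_recording"
  )
}

#' Generate a small deterministic fixture bundle
#'
#' Writes schedules, recordings, and the expected noise-free decodings
#' for a miniature cohort, plus a manifest with MD5 checksums. Intended
#' for tests and examples; regeneration under the same seed is
#' byte-identical.
#'
#' @param dir Output directory.
#' @param scale `"tiny"` (2 subjects x 6 characters, 3 trials) or
#'   `"default"` (2 subjects x 12 characters, 5 trials).
#' @param seed Integer seed.
#' @return List with `dir`, `manifest` (data frame `file`, `md5`), and
#'   the expected `decodings`.
#' @export
make_fixtures <- function(dir, scale = c("tiny", "default"), seed = 1L) {
  scale <- match.arg(scale)
  n_chars <- if (scale == "tiny") 6L else 12L
  n_trials <- if (scale == "tiny") 3L else 5L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # noise- and jitter-free so the expected decodings are exact
  cohort <- simulate_cohort(
    n_subjects = 2, n_chars = n_chars, n_trials = n_trials,
    amplitude_range = c(5, 5),
    p300 = p300_model(latency_sd_ms = 0), noise = noise_model(sd_uv = 0),
    seed = seed
  )
  files <- character(0)
  decodings <- list()
  for (subj in cohort) {
    for (paradigm in c("2D-RC", "3D-C")) {
      stem <- sprintf("subject%d_%s", subj$subject_id,
                      if (paradigm == "2D-RC") "2drc" else "3dc")
      spath <- file.path(dir, paste0(stem, "_schedule.tsv"))
      write_schedule_tsv(subj$sessions[[paradigm]], spath)
      rpath <- file.path(dir, paste0(stem, "_recording.tsv"))
      write_recording_tsv(subj$recordings[[paradigm]], rpath)
      files <- c(files, spath, paste0(spath, ".meta"), rpath,
                 paste0(rpath, ".markers.tsv"), paste0(rpath, ".meta"))
      decodings[[stem]] <- vapply(subj$sessions[[paradigm]]$runs,
                                  function(r) r$target, "")
    }
  }
  dpath <- file.path(dir, "expected_decodings.json")
  jsonlite::write_json(decodings, dpath, auto_unbox = FALSE)
  files <- c(files, dpath)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(dir = dir, manifest = manifest, decodings = decodings)
}
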
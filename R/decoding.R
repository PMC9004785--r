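# Character decoding: combine the detector's 12 per-code scores of a run
# into one spelled character, and the 3-fold character cross-validation
# protocol.

#' Decode one character from 12 per-code scores
#'
#' The predicted column is the argmax over codes 1--6 and the predicted
#' row the argmax over codes 7--12 (both paradigms share this rule; under
#' 3D-C codes 7--12 are the transposed rows flashed as columns). Ties
#' break toward the lowest code. Because only the argmax matters, the
#' decoding is invariant to any strictly monotone transform of the
#' scores.
#'
#' @param scores Numeric vector of 12 scores, named or ordered by code
#'   1..12.
#' @param matrix A `character_matrix`.
#' @return The decoded symbol.
#' @export
#' @examples
#' s <- rep(0.1, 12); s[4] <- 0.9; s[8] <- 0.8
#' decode_character(s, build_character_matrix()) # "J"
decode_character <- function(scores, matrix = build_character_matrix()) {
  if (!is.null(names(scores))) {
    scores <- scores[as.character(1:12)]
  }
  if (length(scores) != 12L || any(is.na(scores))) {
    stop_speller("incomplete_scores", "decoding needs scores for all 12 codes")
  }
  col <- which.max(scores[1:6])          # which.max keeps the lowest index on ties
  row <- which.max(scores[7:12])
  matrix_lookup(matrix, row, col)
}

#' Character-recognition 3-fold cross-validation
#'
#' The 60 runs are shuffled (seed-controlled) and partitioned into three
#' folds of 20. Per fold the detector is trained from scratch on that
#' fold's 240 feature vectors (an internal stratified train/validation
#' split drives early stopping) and the 40 held-out runs are scored and
#' decoded; a run counts as correct when the decoded symbol equals its
#' target. Correct counts out of 40 and their percentage are reported
#' per fold.
#'
#' @param dataset A `speller_dataset` over all 60 runs (12 averaged
#'   epochs per run).
#' @param session The originating `session_schedule` (supplies targets
#'   and the character matrix).
#' @param config A [train_config()]; `split[1:2]` (renormalized) set the
#'   within-fold train/validation proportions.
#' @param n_folds Number of folds (default 3: train on one, test on two).
#' @param seed Master seed.
#' @return A `character_result`: `per_fold` data frame (`fold`,
#'   `n_correct`, `n_test`, `percent`), `mean_correct`, `mean_percent`,
#'   and `per_run` decode details.
#' @export
character_cv <- function(dataset, session, config = train_config(),
                         n_folds = 3, seed = config$seed) {
  stopifnot(inherits(dataset, "speller_dataset"),
            inherits(session, "session_schedule"))
  runs <- sort(unique(dataset$info$run_index))
  n_runs <- length(runs)
  if (n_runs != length(session$runs)) {
    stop_speller("protocol_error",
                 "dataset covers %d runs but the session has %d",
                 n_runs, length(session$runs))
  }
  if (n_runs %% n_folds != 0) {
    stop_speller("protocol_error", "%d runs cannot be split into %d equal folds",
                 n_runs, n_folds)
  }
  seeds <- derive_seeds(seed, 1L + 2L * n_folds)
  shuffled <- with_seed(seeds[1], sample(runs))
  fold_of <- rep(seq_len(n_folds), each = n_runs / n_folds)
  targets <- vapply(session$runs, function(r) r$target, "")

  tr_frac <- config$split[1] / (config$split[1] + config$split[2])
  per_fold <- vector("list", n_folds)
  per_run <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_runs <- shuffled[fold_of == f]
    test_runs <- setdiff(runs, train_runs)
    tr_idx <- which(dataset$info$run_index %in% train_runs)
    parts <- with_seed(seeds[1L + 2L * f - 1L],
                       stratified_split(dataset$y[tr_idx],
                                        c(tr_frac, 1 - tr_frac, 0)))
    model <- train_ann(dataset$x[tr_idx[parts$train], , drop = FALSE],
                       dataset$y[tr_idx[parts$train]],
                       dataset$x[tr_idx[parts$val], , drop = FALSE],
                       dataset$y[tr_idx[parts$val]],
                       config, seed = seeds[1L + 2L * f])
    decoded <- vapply(test_runs, function(r) {
      sel <- which(dataset$info$run_index == r)
      sc <- ann_forward(model, dataset$x[sel, , drop = FALSE])
      names(sc) <- dataset$info$code[sel]
      decode_character(sc, session$matrix)
    }, "")
    correct <- decoded == targets[test_runs]
    per_fold[[f]] <- data.frame(fold = f, n_correct = sum(correct),
                                n_test = length(test_runs),
                                percent = 100 * mean(correct))
    per_run[[f]] <- data.frame(fold = f, run_index = test_runs,
                               predicted = decoded,
                               truth = targets[test_runs],
                               correct = correct)
  }
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(per_fold = per_fold,
         mean_correct = mean(per_fold$n_correct),
         mean_percent = mean(per_fold$percent),
         per_run = do.call(rbind, per_run)),
    class = "character_result"
  )
}

#' @export
print.character_result <- function(x, ...) {
  cat(sprintf("<character_result> mean %.1f/%d correct (%.1f%%) over %d folds\n",
              x$mean_correct, x$per_fold$n_test[1], x$mean_percent,
              nrow(x$per_fold)))
  invisible(x)
}
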
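# Two-layer neural network P300 detector.
#
# Architecture: d inputs -> M tan-sigmoid hidden units -> single linear
# output, squashed through a logistic for the cross-entropy loss and the
# 0.5 decision threshold. Training is deterministic full-batch gradient
# descent with momentum and an adaptive ("bold driver") step size, early
# stopped on validation loss.

ELECTRODE_GROUPS <- list(
  Group1 = c("Cz", "CP1", "CP2"),
  Group2 = c("P7", "P3", "Pz", "P4", "P8"),
  Group3 = c("O1", "Oz", "O2"),
  Group4 = c("Cz", "CP1", "CP2", "P7", "P3", "Pz", "P4", "P8",
             "O1", "Oz", "O2")
)

#' Electrode sets used for evaluation
#'
#' The 11 single centro-parieto-occipital electrodes plus the four
#' groups: Group1 = central (Cz, CP1, CP2), Group2 = parietal (P7, P3,
#' Pz, P4, P8), Group3 = occipital (O1, Oz, O2), Group4 = all 11.
#'
#' @return Named list of channel-name vectors, in canonical radar order.
#' @export
electrode_sets <- function() {
  c(stats::setNames(as.list(ANALYZED_CHANNELS), ANALYZED_CHANNELS),
    ELECTRODE_GROUPS)
}

#' Resolve an electrode-set name to channel names
#'
#' @param channels Either a vector of channel names or one of the set
#'   names `"Group1"`..`"Group4"`.
#' @param available Channel names present in the data.
#' @return Character vector of channel names.
#' @export
resolve_channels <- function(channels, available = ANALYZED_CHANNELS) {
  if (length(channels) == 1L && channels %in% names(ELECTRODE_GROUPS)) {
    channels <- ELECTRODE_GROUPS[[channels]]
  }
  if (!all(channels %in% available)) {
    stop_speller("channel_error", "unknown channel(s): %s",
                 paste(setdiff(channels, available), collapse = ", "))
  }
  channels
}

#' Build a labelled feature dataset from averaged epochs
#'
#' Each averaged epoch becomes one feature vector: the selected channels'
#' post-stimulus signals concatenated (d = 250 x n_channels at 250 Hz).
#' The label is 1 iff the epoch's code is one of its run target's two
#' codes, so each 12-code run contributes 2 positives and 10 negatives.
#'
#' @param averaged An `averaged_epochs` object.
#' @param session The `session_schedule` the epochs came from (supplies
#'   the target codes per run).
#' @param channels Channel names or a group name (see [resolve_channels()]).
#' @return A `speller_dataset`: list with `x` (n x d matrix), `y` (0/1),
#'   and `info` (run_index, code, n_averaged).
#' @export
build_dataset <- function(averaged, session, channels = "P8") {
  stopifnot(inherits(averaged, "averaged_epochs"),
            inherits(session, "session_schedule"))
  channels <- resolve_channels(channels, dimnames(averaged$data)[[2]])
  tc <- lapply(session$runs, function(r) {
    z <- target_codes(r$target, session$matrix, session$paradigm)
    c(z$column_code, z$row_code)
  })
  info <- averaged$info
  y <- vapply(seq_len(nrow(info)), function(i) {
    as.numeric(info$code[i] %in% tc[[info$run_index[i]]])
  }, 0)
  sel <- match(channels, dimnames(averaged$data)[[2]])
  n <- nrow(info)
  d <- length(sel) * dim(averaged$data)[3]
  x <- matrix(0, n, d)
  for (i in seq_len(n)) {
    x[i, ] <- as.vector(t(averaged$data[i, sel, , drop = TRUE]))
  }
  structure(list(x = x, y = y, info = info, channels = channels),
            class = "speller_dataset")
}

#' @export
print.speller_dataset <- function(x, ...) {
  cat(sprintf("<speller_dataset> %d samples x %d features (%d positive), channels: %s\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Initialize a two-layer network
#'
#' Weights are drawn uniformly from `[-r, r]` with `r = 1/sqrt(fan-in)`.
#'
#' @param d Input dimension.
#' @param M Hidden units (default 50).
#' @param seed Integer seed for the initialization draw.
#' @return An `ann_model` with fields `W1` (M x d), `b1`, `w2` (M), `b2`.
#' @export
ann_init <- function(d, M = 50, seed = NULL) {
  with_seed(seed, {
    r1 <- 1 / sqrt(d)
    r2 <- 1 / sqrt(M)
    structure(
      list(d = as.integer(d), M = as.integer(M),
           W1 = matrix(stats::runif(M * d, -r1, r1), M, d),
           b1 = stats::runif(M, -r1, r1),
           w2 = stats::runif(M, -r2, r2),
           b2 = stats::runif(1, -r2, r2)),
      class = "ann_model"
    )
  })
}

logistic <- function(a) 1 / (1 + exp(-a))

#' Forward pass
#'
#' Computes `sigma(w2' tanh(W1 x + b1) + b2)`: tan-sigmoid hidden layer,
#' linear output unit squashed through a logistic so scores live in
#' (0, 1) and threshold at 0.5.
#'
#' @param model An `ann_model`.
#' @param x Feature matrix (n x d) or a single length-d vector.
#' @return Numeric vector of n scores in (0, 1).
#' @export
ann_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d) {
    stop_speller("shape_error", "input has %d features, model expects %d",
                 ncol(x), model$d)
  }
  h <- tanh(sweep(x %*% t(model$W1), 2, model$b1, "+"))
  as.numeric(logistic(h %*% model$w2 + model$b2))
}

#' Cross-entropy loss
#'
#' `J = -(1/N) sum[y log p + (1 - y) log(1 - p)]`, with scores clipped
#' away from 0 and 1 by 1e-12.
#'
#' @param scores Predicted scores in (0, 1).
#' @param y Binary labels.
#' @return Scalar loss.
#' @export
cross_entropy <- function(scores, y) {
  if (length(y) == 0) stop_speller("empty_data", "empty dataset")
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname cross_entropy
#' @param model An `ann_model`.
#' @param x Feature matrix.
#' @export
ann_loss <- function(model, x, y) cross_entropy(ann_forward(model, x), y)

# Analytic gradient of the mean cross-entropy wrt all parameters.
ann_gradients <- function(model, x, y) {
  n <- nrow(x)
  z1 <- sweep(x %*% t(model$W1), 2, model$b1, "+")
  h <- tanh(z1)
  p <- logistic(as.numeric(h %*% model$w2 + model$b2))
  delta_out <- (p - y) / n                       # dJ/da for the linear output
  dh <- outer(delta_out, model$w2) * (1 - h^2)   # back through tanh
  list(W1 = t(dh) %*% x, b1 = colSums(dh),
       w2 = as.numeric(t(h) %*% delta_out), b2 = sum(delta_out))
}

#' Training configuration
#'
#' @param split Train/validation/test fractions, summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param n_repeats Number of repeated random splits whose test
#'   accuracies are averaged (default 20).
#' @param max_epochs Gradient-descent epochs cap (default 500).
#' @param learn_rate Initial step size (default 0.5; adapted during
#'   training).
#' @param momentum Momentum coefficient (default 0.9).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 25).
#' @param M Hidden units (default 50).
#' @param seed Integer seed controlling splits and initializations.
#' @return A `train_config` list.
#' @export
train_config <- function(split = c(0.70, 0.15, 0.15), n_repeats = 20,
                         max_epochs = 500, learn_rate = 0.5,
                         momentum = 0.9, patience = 25, M = 50,
                         seed = NULL) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8, all(split >= 0),
            n_repeats >= 1)
  structure(list(split = split, n_repeats = n_repeats,
                 max_epochs = max_epochs, learn_rate = learn_rate,
                 momentum = momentum, patience = patience, M = M,
                 seed = seed),
            class = "train_config")
}

#' Train the detector network
#'
#' Full-batch gradient descent with momentum on the cross-entropy loss.
#' The step size grows 5% after an improving epoch and halves (with the
#' step undone) after a worsening one, which keeps the procedure
#' deterministic while removing the need to hand-tune the rate. Training
#' stops at `max_epochs` or when the validation loss has not improved
#' for `patience` epochs; the weights with the best validation loss are
#' returned.
#'
#' @param x,y Training features and binary labels.
#' @param x_val,y_val Validation set for early stopping; when NULL, the
#'   training loss is used instead.
#' @param config A [train_config()].
#' @param seed Seed for weight initialization (defaults to
#'   `config$seed`).
#' @return The trained `ann_model`, with a `history` attribute (per-epoch
#'   train/validation losses).
#' @export
train_ann <- function(x, y, x_val = NULL, y_val = NULL,
                      config = train_config(), seed = config$seed) {
  if (length(unique(y)) < 2) {
    stop_speller("degenerate_data", "training split contains a single class")
  }
  model <- ann_init(ncol(x), config$M, seed = seed)
  vel <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
              w2 = model$w2 * 0, b2 = 0)
  lr <- config$learn_rate
  mom <- config$momentum
  has_val <- !is.null(x_val)
  prev_loss <- ann_loss(model, x, y)
  best_val <- if (has_val) ann_loss(model, x_val, y_val) else prev_loss
  best <- model
  wait <- 0L
  hist_train <- hist_val <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    g <- ann_gradients(model, x, y)
    cand <- model
    for (nm in c("W1", "b1", "w2", "b2")) {
      vel[[nm]] <- mom * vel[[nm]] - lr * g[[nm]]
      cand[[nm]] <- model[[nm]] + vel[[nm]]
    }
    loss <- ann_loss(cand, x, y)
    if (is.finite(loss) && loss <= prev_loss * 1.0001) {
      model <- cand
      prev_loss <- loss
      lr <- lr * 1.05
    } else {
      # undo: keep the old weights, damp the step, reset momentum
      vel <- lapply(vel, function(v) v * 0)
      lr <- lr / 2
      loss <- prev_loss
      if (lr < 1e-10) break
    }
    vloss <- if (has_val) ann_loss(model, x_val, y_val) else prev_loss
    hist_train <- c(hist_train, prev_loss)
    hist_val <- c(hist_val, vloss)
    if (vloss < best_val - 1e-9) {
      best_val <- vloss
      best <- model
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  attr(best, "history") <- data.frame(epoch = seq_along(hist_train),
                                      train_loss = hist_train,
                                      val_loss = hist_val)
  best
}

# Stratified index split into train/validation/test by class.
stratified_split <- function(y, split) {
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    n <- length(idx)
    n_tr <- round(split[1] * n)
    n_va <- round(split[2] * n)
    n_tr <- min(n_tr, n - 2)  # keep at least one sample for val and test
    parts$train <- c(parts$train, idx[seq_len(n_tr)])
    parts$val <- c(parts$val, idx[n_tr + seq_len(min(n_va, n - n_tr - 1))])
    parts$test <- c(parts$test, idx[setdiff(seq_len(n), seq_len(n_tr + min(n_va, n - n_tr - 1)))])
  }
  parts
}

#' Repeated-split P300 detection evaluation
#'
#' For each of `n_repeats` repetitions: a fresh stratified
#' train/validation/test split, training from a fresh initialization,
#' scores thresholded at 0.5, and the test-set classification accuracy.
#'
#' @param dataset A `speller_dataset` from [build_dataset()].
#' @param config A [train_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return A `detection_result`: list with `mean_accuracy` and
#'   `sd_accuracy` (percent) and `per_repeat` (data frame `repeat_index`,
#'   `accuracy`).
#' @export
evaluate_detection <- function(dataset, config = train_config(),
                               seed = config$seed) {
  stopifnot(inherits(dataset, "speller_dataset"))
  seeds <- derive_seeds(seed, 2L * config$n_repeats)
  acc <- vapply(seq_len(config$n_repeats), function(r) {
    parts <- with_seed(seeds[2L * r - 1L],
                       stratified_split(dataset$y, config$split))
    model <- train_ann(dataset$x[parts$train, , drop = FALSE],
                       dataset$y[parts$train],
                       dataset$x[parts$val, , drop = FALSE],
                       dataset$y[parts$val],
                       config, seed = seeds[2L * r])
    scores <- ann_forward(model, dataset$x[parts$test, , drop = FALSE])
    pred <- as.numeric(scores > 0.5)
    truth <- dataset$y[parts$test]
    100 * accuracy(confusion_counts(pred, truth))
  }, 0)
  structure(
    list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
         per_repeat = data.frame(repeat_index = seq_along(acc),
                                 accuracy = acc)),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> mean accuracy %.2f%% (sd %.2f, %d repeats)\n",
              x$mean_accuracy, x$sd_accuracy, nrow(x$per_repeat)))
  invisible(x)
}

#' Serialize / restore a trained network as JSON text
#'
#' @param model An `ann_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_ann_json()` returns the model.
#' @export
write_ann_json <- function(model, path) {
  obj <- list(d = model$d, M = model$M, W1 = model$W1, b1 = model$b1,
              w2 = model$w2, b2 = model$b2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ann_json
#' @export
read_ann_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(d = as.integer(obj$d), M = as.integer(obj$M),
                 W1 = matrix(obj$W1, obj$M, obj$d, byrow = FALSE),
                 b1 = as.numeric(obj$b1), w2 = as.numeric(obj$w2),
                 b2 = as.numeric(obj$b2)),
            class = "ann_model")
}
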
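# Performance metrics: classification accuracy, the radar-polygon area
# statistic (ACRC), improvement summaries, and the paired significance
# test used for subject-level comparisons.

#' Canonical radar-profile ordering
#'
#' The 15 evaluation conditions in fixed order: the 11 single electrodes
#' then Group1..Group4. ACRC depends on adjacency, so this order is part
#' of the metric's contract.
#'
#' @return Character vector of 15 labels.
#' @export
radar_labels <- function() {
  c(ANALYZED_CHANNELS, paste0("Group", 1:4))
}

#' Confusion counts from predictions and truth
#'
#' @param pred,truth Binary (0/1) vectors.
#' @return A `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  structure(list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop_speller("undefined_metric", "accuracy of zero counts is undefined")
  (counts$tp + counts$tn) / total
}

#' Area covered by the radar curve (ACRC)
#'
#' The radar polygon over N = 15 ordered classification accuracies
#' (fractions in `[0, 1]`) is decomposed into triangles at the origin
#' with central angle 24 degrees; the summed area
#' `sum 0.5 CA_i CA_{i+1} sin(24deg)` (cyclic, `CA_16 = CA_1`) is
#' normalized by its all-ones maximum `15 * 0.5 * sin(24deg)` so the
#' statistic lies in `[0, 1]`: 1 when every accuracy is 1, `c^2` for a
#' constant profile `c`.
#'
#' @param values Numeric vector of 15 accuracies in `[0, 1]`, ordered as
#'   [radar_labels()].
#' @return Normalized area in `[0, 1]`.
#' @export
#' @examples
#' acrc(rep(1, 15))   # 1
#' acrc(rep(0.8, 15)) # 0.64
acrc <- function(values) {
  n <- length(values)
  if (n != 15L) {
    stop_speller("profile_error", "a radar profile has 15 values (got %d)", n)
  }
  if (any(!is.finite(values) | values < 0 | values > 1)) {
    stop_speller("profile_error", "radar values must be fractions in [0, 1]")
  }
  alpha <- 24 * pi / 180
  nxt <- c(values[-1], values[1])
  raw <- sum(0.5 * values * nxt * sin(alpha))
  raw / (n * 0.5 * sin(alpha))
}

#' Mean and sample standard deviation of per-subject values
#'
#' @param values Numeric vector (one value per subject).
#' @param digits Rounding for the reported values (default 2, matching
#'   tabular reporting).
#' @return Named list `mean`, `sd` (rounded), plus `mean_raw`, `sd_raw`.
#' @export
summarize_table <- function(values, digits = 2) {
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  list(mean = round(m, digits), sd = round(s, digits),
       mean_raw = m, sd_raw = s)
}

#' Relative improvement of a proposed condition over a baseline
#'
#' `100 * (proposed - baseline) / baseline`, in percent.
#'
#' @param baseline,proposed Scalar summary values; `baseline` must be
#'   positive.
#' @return Percent improvement.
#' @export
#' @examples
#' relative_improvement(78.74, 86.37) # 9.69
relative_improvement <- function(baseline, proposed) {
  if (!is.numeric(baseline) || baseline <= 0) {
    stop_speller("undefined_improvement", "baseline must be positive")
  }
  100 * (proposed - baseline) / baseline
}

#' Paired subject-level significance test
#'
#' Two-tailed paired t test on the per-subject differences (df = n - 1;
#' 9 for the standard 10-subject cohort), with significance flags at
#' alpha 0.05 and 0.01.
#'
#' @param a,b Equal-length per-subject metric vectors (baseline,
#'   proposed).
#' @return A `paired_comparison`: `t_stat`, `p_value`, `df`,
#'   `mean_difference`, `significant_05`, `significant_01`.
#' @export
paired_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  if (all(d == 0)) {
    # identical vectors: no evidence of a difference
    return(structure(
      list(t_stat = 0, p_value = 1, df = length(d) - 1L,
           mean_difference = 0, significant_05 = FALSE,
           significant_01 = FALSE),
      class = "paired_comparison"
    ))
  }
  if (stats::sd(d) == 0) {
    stop_speller("degenerate_test", "paired differences have zero variance")
  }
  ht <- stats::t.test(b, a, paired = TRUE, alternative = "two.sided")
  structure(
    list(t_stat = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), mean_difference = mean(d),
         significant_05 = ht$p.value < 0.05,
         significant_01 = ht$p.value < 0.01),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  stars <- if (x$significant_01) "**" else if (x$significant_05) "*" else ""
  cat(sprintf("<paired_comparison> t(%d) = %.3f, p = %.4g%s (mean diff %.3f)\n",
              x$df, x$t_stat, x$p_value, stars, x$mean_difference))
  invisible(x)
}
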
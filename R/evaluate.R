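#' Confusion counts at a probability threshold
#'
#' Predicted positive iff `y_hat >= threshold`.
#'
#' @param predictions data.frame with columns `y` (0/1) and `y_hat`.
#' @param threshold decision threshold (default 0.5).
#' @return list with `tp`, `fp`, `tn`, `fn` (a partition of the predictions).
#' @export
confusion <- function(predictions, threshold = 0.5) {
  if (!nrow(predictions)) stop_nf("predictions must be non-empty")
  pred <- predictions$y_hat >= threshold
  y <- predictions$y == 1
  list(tp = sum(pred & y), fp = sum(pred & !y),
       tn = sum(!pred & !y), fn = sum(!pred & y))
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy `(tp + tn) / N`, sensitivity (true positive rate) `tp / (tp +
#' fn)`, specificity (true negative rate) `tn / (tn + fp)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion()] list.
#' @param percent report as percentages (default TRUE).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(counts, percent = TRUE) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  acc <- (counts$tp + counts$tn) / n
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
          else NA_real_
  spec <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp)
          else NA_real_
  out <- c(accuracy = acc, sensitivity = sens, specificity = spec)
  if (percent) out * 100 else out
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — the exact, tie-aware
#' Mann-Whitney formulation, equal to trapezoidal integration of the
#' empirical ROC curve.
#'
#' @param predictions data.frame with columns `y` and `y_hat`; both classes
#'   must be present.
#' @param percent report as a percentage (default FALSE).
#' @return AUC.
#' @export
auc <- function(predictions, percent = FALSE) {
  y <- predictions$y
  s <- predictions$y_hat
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_nf("auc requires both classes")
  r <- rank(s, ties.method = "average")
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (percent) a * 100 else a
}

#' Aggregate slice-level predictions to scan level
#'
#' For 2D models, slices of one scan are predicted independently; this
#' regroups them by scan provenance into one prediction per scan, either by
#' the mean of slice probabilities (default) or by majority vote (the scan
#' probability is then the fraction of positive slices).
#'
#' @param predictions slice-level prediction data.frame with a `scan_id`
#'   column.
#' @param method `"mean"` or `"vote"`.
#' @return scan-level prediction data.frame.
#' @export
scan_level_aggregate <- function(predictions, method = c("mean", "vote")) {
  method <- match.arg(method)
  if (any(is.na(predictions$scan_id)))
    stop_nf("scan provenance (scan_id) required for aggregation")
  agg <- function(df) {
    p <- if (method == "mean") mean(df$y_hat) else mean(df$y_hat >= 0.5)
    data.frame(y = df$y[1], y_hat = p, subject_id = df$subject_id[1],
               scan_id = df$scan_id[1], slice_index = NA_integer_,
               modality = df$modality[1])
  }
  out <- do.call(rbind, lapply(split(predictions, predictions$scan_id), agg))
  rownames(out) <- NULL
  out
}

#' Results table over model variants
#'
#' One row per model with accuracy, sensitivity, specificity and AUC (all
#' as percentages by default), sorted in ascending order of accuracy.
#' Values are rounded only for display, never in computation.
#'
#' @param prediction_sets named list of prediction data.frames (name =
#'   model label).
#' @param threshold decision threshold.
#' @param percent report percentages (default TRUE).
#' @return data.frame `model`, `accuracy`, `sensitivity`, `specificity`,
#'   `auc`.
#' @export
results_table <- function(prediction_sets, threshold = 0.5, percent = TRUE) {
  rows <- lapply(names(prediction_sets), function(nm) {
    p <- prediction_sets[[nm]]
    m <- metrics(confusion(p, threshold), percent = percent)
    data.frame(model = nm, accuracy = m[["accuracy"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               auc = auc(p, percent = percent))
  })
  out <- do.call(rbind, rows)
  out[order(out$accuracy), , drop = FALSE]
}

#' Render a results table as Markdown
#'
#' @param tab a [results_table()] output.
#' @param digits decimal places for display (default 2).
#' @return character vector of Markdown lines.
#' @export
format_results_md <- function(tab, digits = 2) {
  num <- vapply(tab[-1], function(col) sprintf(paste0("%.", digits, "f"), col),
                character(nrow(tab)))
  num <- matrix(num, nrow = nrow(tab))
  c("| Model | Accuracy | Sensitivity | Specificity | AUC |",
    "|---|---|---|---|---|",
    apply(cbind(tab$model, num), 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |")))
}
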
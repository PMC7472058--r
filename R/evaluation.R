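# Leave-one-subject-out evaluation, F-scores, confusion matrices, and
# inter-observer agreement.
#
# Metrics are computed on predictions pooled across all LOSO folds (not
# averaged per fold); per-subject tables are kept in the report so per-fold
# summaries remain available.

#' Build a confusion matrix in the canonical orientation
#'
#' Rows are predicted classes, columns observed classes, both in the fixed
#' order of \code{\link{activity_classes}}.
#'
#' @param observed,predicted Character vectors of equal length with values in
#'   \code{\link{activity_classes}}.
#' @return 5 x 5 integer matrix of counts.
#' @export
confusion_matrix <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  cls <- activity_classes()
  tab <- table(factor(predicted, levels = cls),
               factor(observed, levels = cls))
  m <- matrix(as.integer(tab), length(cls), length(cls),
              dimnames = list(predicted = cls, observed = cls))
  m
}

#' Per-class precision, recall and F-score, plus the weighted average
#'
#' Precision is TP over the row (predicted) total, recall TP over the column
#' (observed) total, and F the harmonic mean \eqn{2PR/(P+R)}.  A zero
#' denominator yields 0 for the affected component.  The weighted average
#' F-score weights each class by its observed support; classes with zero
#' support are excluded from the average.
#'
#' @param cm Confusion matrix from \code{\link{confusion_matrix}}.
#' @return List with \code{per_class} (data frame: class, support, precision,
#'   recall, f) and \code{weighted_f}.
#' @export
f_scores <- function(cm) {
  if (sum(cm) == 0) stop("confusion matrix is all zero", call. = FALSE)
  cls <- rownames(cm)
  tp <- diag(cm)
  pred_tot <- rowSums(cm)
  obs_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(obs_tot > 0, tp / obs_tot, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  support <- obs_tot
  keep <- support > 0
  weighted_f <- sum(f[keep] * support[keep]) / sum(support[keep])
  list(per_class = data.frame(class = cls, support = as.integer(support),
                              precision = as.numeric(precision),
                              recall = as.numeric(recall), f = as.numeric(f),
                              row.names = NULL, stringsAsFactors = FALSE),
       weighted_f = weighted_f)
}

#' Cohen's unweighted kappa for two coders
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} over the
#' six-code observation alphabet (five activity classes plus OUT_OF_VIEW).
#'
#' @param coder1,coder2 Equal-length label sequences.
#' @return A single number (1 is perfect agreement, 0 chance-level).
#' @export
cohens_kappa <- function(coder1, coder2) {
  if (length(coder1) != length(coder2)) {
    stop("coder sequences must have equal length", call. = FALSE)
  }
  if (length(coder1) < 1L) stop("empty label sequences", call. = FALSE)
  codes <- union(event_codes(), union(unique(coder1), unique(coder2)))
  tab <- table(factor(coder1, levels = codes), factor(coder2, levels = codes))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    stop("expected agreement is 1; kappa undefined", call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Leave-one-subject-out evaluation of a model specification
#'
#' For each subject in turn, fits the model on all other subjects' windows
#' and predicts the held-out subject's windows; predictions are pooled
#' across folds before any metric is computed, so every usable window is
#' predicted exactly once by a model that never saw its subject.
#'
#' @param table Feature table for the whole cohort (one placement /
#'   feature-set / window cell).
#' @param spec A \code{\link{model_spec}}.
#' @return A \code{pa_report}: per-window predictions, the confusion matrix,
#'   per-class and weighted F-scores, the mixed-window fraction, and the spec.
#' @export
loso_evaluate <- function(table, spec) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L) {
    stop("LOSO evaluation needs at least 2 subjects", call. = FALSE)
  }
  preds <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    held <- subjects[k]
    train <- table[table$subject_id != held, , drop = FALSE]
    test <- table[table$subject_id == held, , drop = FALSE]
    if (nrow(test) == 0L) {
      warning("subject ", held, " has no usable windows; skipped",
              call. = FALSE)
      next
    }
    fold_spec <- spec
    fold_spec$seed <- spec$seed + 1000L * k
    model <- tune_and_fit(train, fold_spec)
    preds[[k]] <- data.frame(subject_id = held,
                             window_index = test$window_index,
                             observed = test$label,
                             predicted = predict(model, test),
                             mixed = test$mixed,
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  cm <- confusion_matrix(predictions$observed, predictions$predicted)
  scores <- f_scores(cm)
  structure(list(spec = spec, predictions = predictions,
                 confusion = cm, per_class = scores$per_class,
                 weighted_f = scores$weighted_f,
                 mixed_fraction = mean(predictions$mixed)),
            class = "pa_report")
}

#' @export
print.pa_report <- function(x, ...) {
  cat(sprintf("<pa_report> %s / %s / %g s: weighted F = %.3f over %d windows\n",
              x$spec$placement, x$spec$feature_set, x$spec$window_s,
              x$weighted_f, nrow(x$predictions)))
  print(x$per_class)
  invisible(x)
}

#' Column-normalised percentage confusion matrix
#'
#' Expresses each cell as the percentage of its observed (column) class, the
#' layout used for heat-map style reporting; columns with zero support are
#' rendered as zeros.
#'
#' @param cm Count confusion matrix.
#' @return Numeric matrix of percentages; each non-empty column sums to 100.
#' @export
normalize_confusion <- function(cm) {
  tot <- colSums(cm)
  pct <- sweep(cm, 2L, ifelse(tot > 0, tot, 1), "/") * 100
  pct[, tot == 0] <- 0
  pct
}

#' Write an evaluation report to disk
#'
#' Writes \code{<stem>_metrics.csv} (per-class precision/recall/F, weighted
#' F and mixed fraction with the model spec echoed), and
#' \code{<stem>_confusion.csv} (column-normalised percentages, predicted
#' classes as rows and observed as columns).
#'
#' @param report A \code{pa_report}.
#' @param stem Output path stem (directory must exist).
#' @return Character vector of the two file paths, invisibly.
#' @export
report_render <- function(report, stem) {
  metrics <- data.frame(placement = report$spec$placement,
                        feature_set = report$spec$feature_set,
                        window_s = report$spec$window_s,
                        report$per_class,
                        weighted_f = report$weighted_f,
                        mixed_fraction = report$mixed_fraction,
                        stringsAsFactors = FALSE)
  metrics_path <- paste0(stem, "_metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE, quote = FALSE)
  pct <- round(normalize_confusion(report$confusion), 1)
  conf_path <- paste0(stem, "_confusion.csv")
  utils::write.csv(data.frame(predicted = rownames(pct), pct,
                              check.names = FALSE),
                   conf_path, row.names = FALSE, quote = FALSE)
  invisible(c(metrics_path, conf_path))
}
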
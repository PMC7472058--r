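# Random-forest activity classifiers.
#
# One model per placement x feature-set x window-size cell.  mtry is tuned by
# out-of-bag error over a small grid (no inner CV split needed); the number
# of trees stays fixed.  Mixed windows are retained in training and testing.

#' Model specification
#'
#' @param placement \code{"hip"}, \code{"wrist"} or \code{"hip_wrist"}.
#' @param feature_set \code{"base"} (20 features per placement) or
#'   \code{"lag_lead"} (base plus the 5 temporal features).
#' @param window_s Window duration in seconds.
#' @param n_trees Number of trees in the forest (default 500).
#' @param mtry_grid Candidate values for the number of features sampled at
#'   each split; \code{NULL} uses \code{floor(sqrt(p))}, \code{floor(p/3)}
#'   and \code{floor(p/2)} for p features.
#' @param seed Integer seed driving every stochastic component.
#' @return A \code{pa_model_spec} list.
#' @export
model_spec <- function(placement = c("hip", "wrist", "hip_wrist"),
                       feature_set = c("base", "lag_lead"),
                       window_s = 10, n_trees = 500L, mtry_grid = NULL,
                       seed = 1L) {
  placement <- match.arg(placement)
  feature_set <- match.arg(feature_set)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(placement = placement, feature_set = feature_set,
                 window_s = window_s, n_trees = as.integer(n_trees),
                 mtry_grid = mtry_grid, seed = as.integer(seed)),
            class = "pa_model_spec")
}

.default_mtry_grid <- function(p) {
  sort(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2)))))
}

#' Tune mtry by out-of-bag error and fit the final forest
#'
#' Fits one forest per grid value, keeps the mtry with the lowest out-of-bag
#' error (ties go to the smaller value), then refits at the winner with the
#' full tree count.  Deterministic given \code{spec$seed}.
#'
#' @param table Feature table (see \code{\link{build_feature_table}}) with a
#'   \code{label} column; must contain at least two classes and no missing
#'   feature values.
#' @param spec A \code{\link{model_spec}}.
#' @return A \code{pa_model}: the fitted forest plus the spec, selected mtry,
#'   feature names and class order.
#' @export
tune_and_fit <- function(table, spec) {
  feats <- feature_columns(table)
  for (fc in feats) {
    if (anyNA(table[[fc]]) || any(!is.finite(table[[fc]]))) {
      stop("non-finite value in feature column '", fc, "'", call. = FALSE)
    }
  }
  classes_present <- intersect(activity_classes(), unique(table$label))
  if (length(classes_present) < 2L) {
    stop("training table must contain at least two activity classes",
         call. = FALSE)
  }
  y <- factor(table$label, levels = classes_present)
  x <- as.matrix(table[feats])
  p <- length(feats)
  grid <- spec$mtry_grid %||% .default_mtry_grid(p)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1L) || any(grid > p)) {
    stop("mtry values must lie in [1, ", p, "]", call. = FALSE)
  }
  oob <- rep(NA_real_, length(grid))
  if (length(grid) > 1L) {
    for (k in seq_along(grid)) {
      set.seed(spec$seed + k)
      fit <- randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                        mtry = grid[k])
      oob[k] <- fit$err.rate[spec$n_trees, "OOB"]
    }
    selected <- grid[which.min(oob)]
  } else {
    selected <- grid
  }
  set.seed(spec$seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                       mtry = selected)
  structure(list(spec = spec, forest = forest, selected_mtry = selected,
                 oob_by_mtry = stats::setNames(oob, grid),
                 feature_names = feats, class_order = activity_classes()),
            class = "pa_model")
}

#' @export
print.pa_model <- function(x, ...) {
  cat(sprintf("<pa_model> %s / %s / %g s windows: %d trees, mtry = %d\n",
              x$spec$placement, x$spec$feature_set, x$spec$window_s,
              x$spec$n_trees, x$selected_mtry))
  invisible(x)
}

#' Predict activity classes for a feature table
#'
#' Columns are aligned by name, so column order need not match training.
#' Each row gets the class with the most tree votes; exact vote ties are
#' broken by the canonical class order.
#'
#' @param object A \code{pa_model}.
#' @param table Feature table containing at least the model's feature
#'   columns.
#' @param ... Unused.
#' @return Character vector of predicted classes, one per row, drawn from
#'   \code{\link{activity_classes}}.
#' @export
predict.pa_model <- function(object, table, ...) {
  missing_cols <- setdiff(object$feature_names, names(table))
  if (length(missing_cols) > 0L) {
    stop("table lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(table[object$feature_names])
  votes <- stats::predict(object$forest, x, type = "vote", norm.votes = FALSE)
  # order vote columns canonically so which.max's first-max rule implements
  # the class-order tie-break
  cls <- intersect(object$class_order, colnames(votes))
  votes <- votes[, cls, drop = FALSE]
  cls[apply(votes, 1L, which.max)]
}
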
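#' Metrics from a binary confusion tally
#'
#' Direct substitution into the standard formulas: accuracy
#' (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall TP/(TP+FN) and the
#' F1 harmonic mean.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return named list `accuracy`, `precision`, `recall`, `f1` (NA where a
#'   denominator is zero).
#' @examples
#' tally_metrics(tp = 3, tn = 5, fp = 1, fn = 1)  # accuracy 0.8
#' @export
tally_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(accuracy = (tp + tn) / (tp + tn + fp + fn), precision = precision,
       recall = recall, f1 = f1)
}

#' Multiclass classification metrics
#'
#' Computes accuracy, precision, recall and F1 over integer label vectors.
#' The default micro averaging pools the one-vs-rest (instance, class)
#' decisions over all classes before applying the binary formulas; for
#' single-label multiclass input this makes precision, recall and F1 all
#' equal to accuracy, which is why a model's metric columns coincide.
#' Macro averaging (unweighted mean of per-class metrics) is available
#' behind the `averaging` flag.
#'
#' @param y_true,y_pred equal-length integer (or factor) label vectors.
#' @param averaging `"micro"` (default) or `"macro"`.
#' @return list with `accuracy`, `precision`, `recall`, `f1` and the
#'   `averaging` tag.
#' @export
classification_metrics <- function(y_true, y_pred,
                                   averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(c(y_true, y_pred)))
  per_class <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- length(y_true) - tp - fp - fn
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  })
  acc <- mean(y_true == y_pred)
  if (averaging == "micro") {
    pooled <- Reduce(`+`, per_class)
    m <- tally_metrics(pooled["tp"], pooled["tn"], pooled["fp"],
                       pooled["fn"])
    list(accuracy = acc, precision = unname(m$precision),
         recall = unname(m$recall), f1 = unname(m$f1),
         averaging = "micro")
  } else {
    ms <- lapply(per_class, function(t) {
      tally_metrics(t["tp"], t["tn"], t["fp"], t["fn"])
    })
    mean_of <- function(field) {
      mean(vapply(ms, function(m) unname(m[[field]]), 0), na.rm = TRUE)
    }
    list(accuracy = acc, precision = mean_of("precision"),
         recall = mean_of("recall"), f1 = mean_of("f1"),
         averaging = "macro")
  }
}

#' Regression metrics: MSE, MAE and R-squared
#'
#' `r2 = 1 - mse / var(y_true)` with the population (biased) variance. With
#' a constant `y_true` the ratio is undefined; `r2` is then NA and
#' `r2_defined` is FALSE rather than silently reporting 0.
#'
#' @param y_true,y_pred equal-length numeric vectors, n >= 2.
#' @return list `mse`, `mae`, `r2`, `r2_defined`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least two observations",
                                call. = FALSE)
  mse <- mean((y_true - y_pred)^2)
  mae <- mean(abs(y_true - y_pred))
  v <- mean((y_true - mean(y_true))^2)
  if (v > 0) {
    list(mse = mse, mae = mae, r2 = 1 - mse / v, r2_defined = TRUE)
  } else {
    list(mse = mse, mae = mae, r2 = NA_real_, r2_defined = FALSE)
  }
}

#' Micro-averaged multiclass ROC curve and AUC
#'
#' Labels are binarized one-vs-rest, all (label, score) pairs are pooled
#' across classes, and a single ROC curve is swept over the pooled score
#' thresholds (ties grouped). The AUC is the trapezoidal integral. The
#' curve starts at (0, 0), ends at (1, 1) and is monotone non-decreasing.
#'
#' @param y_true integer (or factor) labels.
#' @param scores numeric score matrix, one row per instance, one named
#'   column per class; every observed class must be covered.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`) and
#'   `auc_micro`.
#' @export
roc_micro <- function(y_true, scores) {
  y_true <- as.character(y_true)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true)) {
    stop("score matrix rows do not match labels", call. = FALSE)
  }
  if (is.null(colnames(scores))) {
    stop("score matrix needs class column names", call. = FALSE)
  }
  missing <- setdiff(unique(y_true), colnames(scores))
  if (length(missing) > 0L) {
    stop("class '", missing[1], "' absent from the score matrix",
         call. = FALSE)
  }
  labels <- as.vector(vapply(colnames(scores), function(cl) y_true == cl,
                             logical(length(y_true))))
  s <- as.vector(scores)
  pos <- sum(labels)
  neg <- length(labels) - pos
  if (pos == 0L || neg == 0L) {
    stop("pooled labels are single-class; ROC undefined", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  labels <- labels[ord]
  # group threshold ties
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(labels)[last_of_tie]
  fp <- cumsum(!labels)[last_of_tie]
  pts <- data.frame(fpr = c(0, fp / neg), tpr = c(0, tp / pos))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(roc_points = pts, auc_micro = auc)
}

#' Aggregate true/predicted pairs for scatter re-plotting
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return data.frame `true`, `predicted`, `count` with counts summing to
#'   the input length; empty input yields an empty frame.
#' @export
scatter_export <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (length(y_true) == 0L) {
    return(data.frame(true = integer(0), predicted = integer(0),
                      count = integer(0)))
  }
  tab <- as.data.frame(table(true = y_true, predicted = y_pred),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  out <- data.frame(true = utils::type.convert(tab$true, as.is = TRUE),
                    predicted = utils::type.convert(tab$predicted,
                                                    as.is = TRUE),
                    count = tab$Freq)
  out <- out[order(out$true, out$predicted), ]
  rownames(out) <- NULL
  out
}

#' Evaluate a trained model on a labelled dataset
#'
#' Convenience wrapper producing the metrics block of a report: multiclass
#' micro metrics for classifiers (plus the pooled one-vs-rest AUC),
#' MSE/MAE/R2 for regressors, and the scatter aggregation for both.
#'
#' @param model a `dl_model`.
#' @param test a `dl_dataset` carrying targets for the model's rule.
#' @return list with `metrics`, `scatter` and, for classifiers, `roc`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "dl_model"), inherits(test, "dl_dataset"))
  y_true <- test$targets[[model$spec$rule]]
  if (is.null(y_true)) {
    stop("test set has no targets for rule '", model$spec$rule, "'",
         call. = FALSE)
  }
  y_pred <- predict_counts(model, test)
  if (model$spec$task == "classifier") {
    m <- classification_metrics(y_true, y_pred)
    roc <- roc_micro(y_true, vote_scores(model, test))
    m$auc_micro <- roc$auc_micro
    list(metrics = m, roc = roc, scatter = scatter_export(y_true, y_pred))
  } else {
    list(metrics = regression_metrics(y_true, y_pred),
         scatter = scatter_export(y_true, y_pred))
  }
}
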
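#' Specification of a Random Forest surrogate model
#'
#' @param task `"classifier"` or `"regressor"`.
#' @param rule rule name the model predicts violation counts for.
#' @param n_trees ensemble size. The study protocol uses 10, 20 or 30;
#'   other values are accepted but flagged `parity = FALSE` in the
#'   returned object.
#' @param representation `"descriptors"` or `"fingerprints"`.
#' @param seed seed for tree construction (passed to ranger; the R RNG is
#'   untouched).
#' @param hyperparameters named list of ranger overrides (e.g. `mtry`,
#'   `min.node.size`); empty by default -- the protocol found library
#'   defaults best.
#' @return a `dl_model_spec`.
#' @export
model_spec <- function(task = c("classifier", "regressor"), rule,
                       n_trees = 10L,
                       representation = c("descriptors", "fingerprints"),
                       seed = 1L, hyperparameters = list()) {
  task <- match.arg(task)
  representation <- match.arg(representation)
  if (!is.numeric(n_trees) || length(n_trees) != 1L || n_trees < 1) {
    stop("'n_trees' must be a positive integer", call. = FALSE)
  }
  structure(list(task = task, rule = rule, n_trees = as.integer(n_trees),
                 representation = representation, seed = as.integer(seed),
                 hyperparameters = hyperparameters,
                 parity = as.integer(n_trees) %in% c(10L, 20L, 30L)),
            class = "dl_model_spec")
}

#' Train a Random Forest surrogate on a labelled dataset
#'
#' Fits a ranger forest of `spec$n_trees` trees on the dataset's features
#' against the violation counts of `spec$rule`. Classifiers are trained on
#' the count as a factor with levels `0..max_violations` (so every class is
#' representable even if absent from the training rows); regressors on the
#' numeric count. Library-default hyperparameters are used unless
#' overridden in the spec.
#'
#' @param train a `dl_dataset`.
#' @param spec a [model_spec()].
#' @return a `dl_model`: the fitted ensemble plus metadata (spec, feature
#'   names, thresholds fingerprint of the labelling rule set, training
#'   provenance).
#' @export
train_model <- function(train, spec) {
  stopifnot(inherits(train, "dl_dataset"), inherits(spec, "dl_model_spec"))
  if (dataset_nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (!spec$rule %in% names(train$targets)) {
    stop("rule '", spec$rule, "' has no targets in the dataset (available: ",
         paste(names(train$targets), collapse = ", "), ")", call. = FALSE)
  }
  if (spec$representation != train$representation) {
    stop("spec expects ", spec$representation, " but the dataset is ",
         train$representation, call. = FALSE)
  }
  y <- train$targets[[spec$rule]]
  if (length(y) != nrow(train$features)) {
    stop("feature/target length mismatch", call. = FALSE)
  }
  maxv <- train$rule_info[[spec$rule]]$max_violations
  if (spec$task == "classifier") {
    y <- factor(y, levels = 0:maxv)
    if (length(unique(y)) == 1L) {
      warning("single-class training target for rule '", spec$rule, "'",
              call. = FALSE)
    }
  } else {
    y <- as.numeric(y)
  }
  args <- c(list(x = train$features, y = y, num.trees = spec$n_trees,
                 seed = spec$seed, num.threads = 1L),
            spec$hyperparameters)
  # the full level set 0..max is passed on purpose; ranger's note about
  # unused levels is expected whenever a class is absent from the rows
  fit <- withCallingHandlers(
    do.call(ranger::ranger, args),
    warning = function(w) {
      if (grepl("Dropped unused factor level", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    spec = spec,
    fit = fit,
    feature_names = train$feature_names,
    max_violations = maxv,
    thresholds_fingerprint =
      train$rule_info[[spec$rule]]$thresholds_fingerprint,
    provenance = list(n_train = dataset_nrow(train),
                      rule_variant = train$rule_info[[spec$rule]]$variant,
                      dataset_provenance = train$provenance)
  ), class = "dl_model")
}

#' @export
print.dl_model <- function(x, ...) {
  cat("<RF ", x$spec$task, "> rule ", x$spec$rule, " (",
      x$provenance$rule_variant, "), ", x$spec$n_trees, " trees, ",
      length(x$feature_names), " ", x$spec$representation, " features\n",
      sep = "")
  invisible(x)
}

check_features <- function(model, features) {
  if (inherits(features, "dl_dataset")) features <- features$features
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  extra <- setdiff(names(features), model$feature_names)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("feature layout mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(utils::head(extra, 5),
                                         collapse = ", ")),
         call. = FALSE)
  }
  features[model$feature_names]
}

#' Round regressor output to integer violation counts
#'
#' Half-away-from-zero rounding followed by clipping to
#' `[0, max_violations]`: 2.5 becomes 3, -0.3 becomes 0.
#'
#' @param x numeric predictions.
#' @param max_violations upper clip bound.
#' @return integer vector.
#' @export
round_counts <- function(x, max_violations) {
  r <- sign(x) * floor(abs(x) + 0.5)
  as.integer(pmin(pmax(r, 0), max_violations))
}

#' Predict integer violation counts
#'
#' Classifiers return the majority-vote class computed from the per-tree
#' votes, with ties resolved deterministically in favour of the smaller
#' count (ranger's own aggregation breaks ties randomly, which would make
#' predictions depend on RNG state); regressor output is rounded
#' half-away-from-zero and clipped to the rule's valid range. The result is
#' always an integer in `0..max_violations`, identical across repeated
#' calls and invariant to row order.
#'
#' @param model a `dl_model`.
#' @param features feature rows (data.frame or `dl_dataset`) matching the
#'   model's feature layout (order-insensitive; missing or extra columns
#'   are an error).
#' @return integer vector of predicted violation counts.
#' @export
predict_counts <- function(model, features) {
  stopifnot(inherits(model, "dl_model"))
  if (model$spec$task == "classifier") {
    scores <- vote_scores(model, features)
    cls <- colnames(scores)[max.col(scores, ties.method = "first")]
    as.integer(cls)
  } else {
    features <- check_features(model, features)
    pred <- stats::predict(model$fit, data = features, num.threads = 1L,
                           seed = 1L)$predictions
    round_counts(pred, model$max_violations)
  }
}

#' Per-class vote fractions of a classifier
#'
#' The fraction of trees voting for each class, used as the per-class score
#' for ROC construction.
#'
#' @param model a classifier `dl_model`.
#' @param features feature rows.
#' @return numeric matrix, one row per input row, one column per class
#'   (`"0" .. "max"`), rows summing to 1.
#' @export
vote_scores <- function(model, features) {
  stopifnot(inherits(model, "dl_model"))
  if (model$spec$task != "classifier") {
    stop("vote scores are defined for classifiers", call. = FALSE)
  }
  features <- check_features(model, features)
  votes <- stats::predict(model$fit, data = features, num.threads = 1L,
                          seed = 1L, predict.all = TRUE)$predictions
  lev <- model$fit$forest$levels
  scores <- vapply(seq_along(lev), function(k) rowMeans(votes == k),
                   numeric(nrow(features)))
  if (nrow(features) == 1L) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- lev
  scores
}

## ---- persistence -----------------------------------------------------------

#' Save a trained model with a human-readable metadata sidecar
#'
#' The ensemble is serialized to `path`; `<path>.meta.json` records the
#' spec, feature names, thresholds fingerprint, provenance and an MD5 of
#' the serialized ensemble so that tampered or mismatched artifacts are
#' rejected at load time.
#'
#' @param model a `dl_model`.
#' @param path artifact path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dl_model"))
  saveRDS(model, path, version = 2L)
  meta <- list(spec = unclass(model$spec),
               feature_names = model$feature_names,
               max_violations = model$max_violations,
               thresholds_fingerprint = model$thresholds_fingerprint,
               provenance = model$provenance,
               ensemble_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path artifact path.
#' @return a `dl_model`.
#' @export
load_model <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing model sidecar '", meta_path, "'", call. = FALSE)
  }
  meta <- tryCatch(jsonlite::fromJSON(meta_path),
                   error = function(e) {
                     stop("corrupted model sidecar '", meta_path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (is.null(meta$ensemble_md5) ||
      !identical(unname(tools::md5sum(path)), meta$ensemble_md5)) {
    stop("model integrity error: ensemble checksum does not match sidecar",
         call. = FALSE)
  }
  model <- readRDS(path)
  if (!inherits(model, "dl_model") ||
      !identical(model$spec$n_trees, as.integer(meta$spec$n_trees))) {
    stop("model integrity error: metadata/ensemble mismatch", call. = FALSE)
  }
  model
}
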
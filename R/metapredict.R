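# Meta-models: random forest regressors predicting a DA method's
# sensitivity or specificity from the signature vector of the observed
# counts alone.

#' Train one accuracy meta-model
#'
#' Joins signatures to accuracy records by `dataset_id`, restricts to
#' one method and one target, splits 80/20 (seeded, unstratified),
#' fits a random forest regressor and reports held-out R-squared
#' (1 - SSE/SST) together with normalized gain importance.
#'
#' @param signatures data.frame with `dataset_id` plus registry
#'   features.
#' @param records accuracy records with `dataset_id`, `method` and the
#'   target column.
#' @param method DA method name to model.
#' @param target `"sensitivity"` or `"specificity"`.
#' @param n_trees ensemble size (>= 50; default 500).
#' @param train_fraction fraction of rows used for training (0.8).
#' @param seed split/fit seed.
#' @param min_rows minimum joined rows required.
#' @return object of class `da_predictor`: list with the fitted
#'   `model`, `r2_holdout`, `importance`, `target`, `method` and the
#'   held-out row ids.
#' @export
train_predictor <- function(signatures, records, method,
                            target = c("sensitivity", "specificity"),
                            n_trees = 500L, train_fraction = 0.8,
                            seed = 1L, min_rows = 50L) {
  target <- match.arg(target)
  stopifnot(n_trees >= 50L, train_fraction > 0, train_fraction < 1)
  r <- records[records$method == method, c("dataset_id", target)]
  d <- merge(signatures, r, by = "dataset_id")
  d <- d[is.finite(d[[target]]), , drop = FALSE]
  if (nrow(d) < min_rows) {
    stop("need at least ", min_rows, " joined rows; got ", nrow(d))
  }
  y <- d[[target]]
  if (stats::sd(y) == 0) stop("target is constant; nothing to model")
  feats <- intersect(signature_registry()$name, names(d))
  X <- d[, feats, drop = FALSE]

  fit_and_eval <- function() {
    set.seed(seed)
    n <- nrow(d)
    train <- sample.int(n, floor(train_fraction * n))
    model <- randomForest::randomForest(x = X[train, , drop = FALSE],
                                        y = y[train], ntree = n_trees)
    pred <- stats::predict(model, X[-train, , drop = FALSE])
    sse <- sum((y[-train] - pred)^2)
    sst <- sum((y[-train] - mean(y[-train]))^2)
    list(model = model, r2 = 1 - sse / sst, holdout = d$dataset_id[-train])
  }
  fit <- with_private_seed(seed, fit_and_eval())
  structure(list(model = fit$model, method = method, target = target,
                 r2_holdout = fit$r2,
                 importance = gain_importance(fit$model),
                 holdout_ids = fit$holdout, features = feats),
            class = "da_predictor")
}

#' @export
print.da_predictor <- function(x, ...) {
  cat(sprintf("da_predictor: %s ~ signatures (%s), holdout R^2 = %.3f\n",
              x$target, x$method, x$r2_holdout))
  top <- sort(x$importance, decreasing = TRUE)[seq_len(min(5, length(x$importance)))]
  cat("  top features:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Train the full set of per-method meta-models
#'
#' One model per combination of DA method and accuracy target (10
#' models for the five rescaling strategies).
#'
#' @inheritParams train_predictor
#' @param methods DA method names (default the five rescaling
#'   strategies).
#' @param targets accuracy targets to model.
#' @return named list of `da_predictor` objects
#'   (`<method>.<target>`).
#' @export
train_meta_models <- function(signatures, records,
                              methods = rescaling_methods(),
                              targets = c("sensitivity", "specificity"),
                              n_trees = 500L, train_fraction = 0.8,
                              seed = 1L, min_rows = 50L) {
  out <- list()
  for (m in methods) {
    for (tg in targets) {
      out[[paste(m, tg, sep = ".")]] <-
        train_predictor(signatures, records, m, tg, n_trees = n_trees,
                        train_fraction = train_fraction, seed = seed,
                        min_rows = min_rows)
    }
  }
  out
}

#' Predict accuracy with per-tree predictive intervals
#'
#' Point prediction is the ensemble mean; the 50% and 90% bands are the
#' 25/75 and 5/95 percentiles of the per-tree predictions, clipped to
#' \[0, 1\].
#'
#' @param predictor a `da_predictor`.
#' @param signatures data.frame (or named vector) of registry features.
#' @return data.frame with `point`, `lo50`, `hi50`, `lo90`, `hi90`.
#' @export
predict_with_intervals <- function(predictor, signatures) {
  stopifnot(inherits(predictor, "da_predictor"))
  if (is.null(dim(signatures))) {
    signatures <- as.data.frame(as.list(signatures))
  }
  missing <- setdiff(predictor$features, names(signatures))
  if (length(missing)) {
    stop("missing signature features: ", paste(missing, collapse = ", "))
  }
  X <- signatures[, predictor$features, drop = FALSE]
  pr <- stats::predict(predictor$model, X, predict.all = TRUE)
  ind <- pr$individual
  clip <- function(x) pmin(pmax(x, 0), 1)
  data.frame(
    point = clip(rowMeans(ind)),
    lo50 = clip(apply(ind, 1, stats::quantile, 0.25)),
    hi50 = clip(apply(ind, 1, stats::quantile, 0.75)),
    lo90 = clip(apply(ind, 1, stats::quantile, 0.05)),
    hi90 = clip(apply(ind, 1, stats::quantile, 0.95)))
}

#' Normalized gain importance of a fitted forest
#'
#' Node-impurity gain per feature, normalized to sum to 1.
#'
#' @param model a `randomForest` regression model or a `da_predictor`.
#' @return named non-negative numeric vector summing to 1.
#' @export
gain_importance <- function(model) {
  if (inherits(model, "da_predictor")) model <- model$model
  imp <- randomForest::importance(model)
  v <- pmax(imp[, 1], 0)
  if (sum(v) == 0) v[] <- 1
  v / sum(v)
}
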
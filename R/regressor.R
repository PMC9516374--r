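# Pluggable value regressors behind a minimal fit/predict interface.
# The Q-function is a regression of a continuous composite outcome on
# history features plus the encoded action.

#' Regressor configuration for the stage Q-models
#'
#' `gbm_hist` (default) is gradient boosting with histogram-binned tree
#' growth, suited to many covariates with interactions and native missing
#' value handling; `random_forest` and `linear` are alternatives (missing
#' covariates are median-imputed for these, with imputation values stored at
#' fit time); `tabular_mean` predicts the sample mean of its exact
#' feature-cell and is the transparent reference model for discrete state
#' spaces.
#'
#' @param method one of `"gbm_hist"`, `"random_forest"`, `"linear"`,
#'   `"tabular_mean"`.
#' @param nrounds,eta,max_depth boosting rounds, learning rate and tree depth
#'   for `gbm_hist`.
#' @param num_trees trees for `random_forest`.
#' @param seed integer seed fixed into the fit for determinism.
#' @return object of class `regressor_config`.
#' @export
regressor_config <- function(method = c("gbm_hist", "random_forest",
                                        "linear", "tabular_mean"),
                             nrounds = 100, eta = 0.1, max_depth = 3,
                             num_trees = 300, seed = 1L) {
  structure(list(method = match.arg(method), nrounds = nrounds, eta = eta,
                 max_depth = max_depth, num_trees = num_trees,
                 seed = as.integer(seed)),
            class = "regressor_config")
}

median_impute <- function(x, medians = NULL) {
  if (is.null(medians))
    medians <- apply(x, 2, function(col) {
      m <- stats::median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    })
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- medians[j]
  list(x = x, medians = medians)
}

fit_regressor <- function(x, y, config) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (nrow(x) == 0L) stop("empty training set")
  fit <- switch(config$method,
    gbm_hist = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = config$eta,
                      max_depth = config$max_depth, tree_method = "hist",
                      nthread = 1, seed = config$seed),
        data = dtrain, nrounds = config$nrounds, verbose = 0)
    },
    random_forest = {
      imp <- median_impute(x)
      df <- as.data.frame(imp$x)
      df$.y <- y
      list(model = ranger::ranger(.y ~ ., data = df,
                                  num.trees = config$num_trees,
                                  seed = config$seed, num.threads = 1),
           medians = imp$medians)
    },
    linear = {
      imp <- median_impute(x)
      list(model = stats::lm(y ~ ., data = as.data.frame(imp$x)),
           medians = imp$medians)
    },
    tabular_mean = {
      key <- apply(x, 1, paste, collapse = "\r")
      list(means = tapply(y, key, mean), global = mean(y))
    })
  structure(list(fit = fit, method = config$method, config = config,
                 features = colnames(x)),
            class = "qc_regressor")
}

predict_regressor <- function(object, x) {
  stopifnot(inherits(object, "qc_regressor"), is.matrix(x))
  if (!is.null(object$features)) x <- x[, object$features, drop = FALSE]
  switch(object$method,
    gbm_hist = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(x))),
    random_forest = {
      xi <- median_impute(x, object$fit$medians)$x
      as.numeric(stats::predict(object$fit$model, data = as.data.frame(xi),
                                num.threads = 1)$predictions)
    },
    linear = {
      xi <- median_impute(x, object$fit$medians)$x
      as.numeric(stats::predict(object$fit$model,
                                newdata = as.data.frame(xi)))
    },
    tabular_mean = {
      key <- apply(x, 1, paste, collapse = "\r")
      v <- object$fit$means[key]
      v[is.na(v)] <- object$fit$global
      as.numeric(v)
    })
}
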
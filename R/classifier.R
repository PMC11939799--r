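# Gradient-boosted tree classifier: training, prediction, grid search.

#' Gradient-boosting hyperparameters
#'
#' Defaults are the tuned operating point used throughout:
#' `colsample_bytree = 0.8`, `learning_rate = 0.2`, `max_depth = 7`,
#' `n_estimators = 300`, `reg_alpha = 0.1`, `reg_lambda = 1`,
#' `subsample = 0.8`.
#'
#' @param colsample_bytree column subsample ratio per tree.
#' @param learning_rate shrinkage (eta).
#' @param max_depth maximum tree depth.
#' @param n_estimators number of boosting rounds.
#' @param reg_alpha,reg_lambda L1/L2 regularisation.
#' @param subsample row subsample ratio.
#' @param seed RNG seed for the booster.
#' @param nthread training threads (1 keeps runs bitwise reproducible).
#' @return named list of class `model_params`.
#' @export
model_params <- function(colsample_bytree = 0.8, learning_rate = 0.2,
                         max_depth = 7L, n_estimators = 300L,
                         reg_alpha = 0.1, reg_lambda = 1,
                         subsample = 0.8, seed = 1L, nthread = 1L) {
  structure(
    list(colsample_bytree = colsample_bytree, learning_rate = learning_rate,
         max_depth = max_depth, n_estimators = n_estimators,
         reg_alpha = reg_alpha, reg_lambda = reg_lambda,
         subsample = subsample, seed = seed, nthread = nthread),
    class = "model_params"
  )
}

#' Train the staging classifier
#'
#' Fits a multiclass gradient-boosted tree ensemble (softmax objective) on
#' the feature columns of `data`. Deterministic given `params$seed`.
#'
#' @param data feature tibble with a label column.
#' @param features feature column names; default [feature_names()].
#' @param stage label column name.
#' @param params a [model_params()].
#' @return object of class `sleep_stager`: list with `booster`, `features`,
#'   `levels`, `params`.
#' @export
fit_stager <- function(data, features = NULL, stage = "stage",
                       params = model_params()) {
  features <- features %||% feature_names(data)
  y <- data[[stage]]
  lev <- if (is.factor(y)) levels(droplevels(y)) else {
    present <- unique(as.character(y))
    c(intersect(stage_levels(), present), setdiff(sort(present), stage_levels()))
  }
  if (length(lev) < 2L) stop("training data has fewer than two classes", call. = FALSE)
  X <- as.matrix(data[features])
  if (!all(is.finite(X))) stop("non-finite feature values in training data", call. = FALSE)
  ylab <- match(as.character(y), lev) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = ylab)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "multi:softprob",
      num_class = length(lev),
      eta = params$learning_rate,
      max_depth = params$max_depth,
      subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      alpha = params$reg_alpha,
      lambda = params$reg_lambda,
      nthread = params$nthread,
      seed = params$seed
    ),
    data = dtrain,
    nrounds = params$n_estimators,
    verbose = 0
  )
  structure(
    list(booster = booster, features = features, levels = lev, params = params),
    class = "sleep_stager"
  )
}

#' Predict sleep stages
#'
#' @param object a `sleep_stager` from [fit_stager()].
#' @param newdata feature tibble; columns are aligned to the training
#'   feature names (order-insensitive), missing columns are an error.
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix.
#' @param ... unused.
#' @return character vector of stage labels, or a probability matrix.
#' @export
predict.sleep_stager <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[object$features])
  prob <- predict(object$booster, xgboost::xgb.DMatrix(X))
  if (!is.matrix(prob)) {
    prob <- matrix(prob, ncol = length(object$levels), byrow = TRUE)
  }
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  object$levels[max.col(prob, ties.method = "first")]
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat("Gradient-boosted sleep stager: ", length(x$features), " features, ",
      "classes ", paste(x$levels, collapse = "/"), ", ",
      x$params$n_estimators, " rounds\n", sep = "")
  invisible(x)
}

#' @export
tidy.sleep_stager <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain,
                 cover = imp$Cover, frequency = imp$Frequency)
}

#' @export
glance.sleep_stager <- function(x, ...) {
  tibble::as_tibble(x$params[c("learning_rate", "max_depth", "n_estimators",
                               "subsample", "colsample_bytree",
                               "reg_alpha", "reg_lambda")]) |>
    dplyr::mutate(n_features = length(x$features),
                  n_classes = length(x$levels))
}

#' Hyperparameter grid search
#'
#' Exhaustively evaluates every combination of the supplied candidate
#' values (other parameters stay at their [model_params()] values), trains
#' on the learning split and scores accuracy on the validation split.
#' Ties are broken in favour of the earlier combination in grid order.
#'
#' @param learn,validate feature tibbles.
#' @param grid named list mapping parameter names to candidate vectors,
#'   e.g. `list(learning_rate = c(0.1, 0.2, 0.3), max_depth = c(5, 7, 9))`.
#' @param stage label column name.
#' @param base [model_params()] supplying the fixed parameters.
#' @param features feature column names.
#' @return list with `best` (a [model_params()]) and `results` (a tibble of
#'   all combinations with their validation accuracy).
#' @export
grid_search <- function(learn, validate, grid, stage = "stage",
                        base = model_params(), features = NULL) {
  if (length(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- base
    for (nm in names(combos)) p[[nm]] <- combos[[nm]][i]
    fit <- fit_stager(learn, features = features, stage = stage, params = p)
    pred <- predict(fit, validate)
    acc[i] <- mean(pred == validate[[stage]])
  }
  best_i <- which.max(acc)  # first maximum wins ties
  best <- base
  for (nm in names(combos)) best[[nm]] <- combos[[nm]][best_i]
  list(
    best = best,
    results = dplyr::bind_cols(tibble::as_tibble(combos),
                               tibble::tibble(accuracy = 100 * acc))
  )
}

#' Default tuning grid
#'
#' Candidate values searched around the tuned operating point:
#' learning rate 0.1/0.2/0.3, depth 5/7/9, 100 or 300 rounds.
#'
#' @return named list suitable for [grid_search()].
#' @export
default_grid <- function() {
  list(learning_rate = c(0.1, 0.2, 0.3),
       max_depth = c(5L, 7L, 9L),
       n_estimators = c(100L, 300L))
}
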
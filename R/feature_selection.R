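# Two-step feature selection: Fisher-score prefilter followed by
# boosted-tree importance ranking.

#' Fisher scores of feature columns
#'
#' For each feature k, the between-class variance
#' \eqn{S_B = \sum_i (n_i/n)(m_i - m)^2}, the pooled within-class variance
#' \eqn{S_W = (1/n)\sum_i \sum_{x \in \omega_i} (x - m_i)^2}, and the Fisher
#' score \eqn{J = S_B / S_W}. These satisfy the law of total variance:
#' population variance = `s_w + s_b`. `J` is 0 when both components vanish
#' (uninformative constant feature) and `Inf` when `s_w = 0 < s_b`
#' (trivially separating feature).
#'
#' @param data data frame whose feature columns are numeric.
#' @param stage column name (string) holding the class labels.
#' @param features feature column names; default every numeric column except
#'   the label and metadata columns.
#' @return tibble with columns `feature`, `s_b`, `s_w`, `j`.
#' @export
fisher_scores <- function(data, stage = "stage", features = NULL) {
  y <- data[[stage]]
  if (dplyr::n_distinct(y) < 2L) {
    stop("Fisher scores require at least two classes", call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c("night", "epoch_index"))
  }
  X <- as.matrix(data[features])
  n <- nrow(X)
  cls <- split(seq_len(n), y)
  m_all <- colMeans(X)
  s_b <- numeric(ncol(X))
  s_w <- numeric(ncol(X))
  for (rows in cls) {
    Xi <- X[rows, , drop = FALSE]
    mi <- colMeans(Xi)
    s_b <- s_b + (length(rows) / n) * (mi - m_all)^2
    s_w <- s_w + colSums(sweep(Xi, 2L, mi)^2) / n
  }
  j <- ifelse(s_w > 0, s_b / s_w, ifelse(s_b > 0, Inf, 0))
  tibble::tibble(feature = features, s_b = unname(s_b), s_w = unname(s_w),
                 j = unname(j))
}

#' Fisher-score prefilter
#'
#' Keeps features whose score is at least `threshold` (a score exactly at
#' the threshold survives; only scores strictly below it are discarded). If
#' nothing survives, the 10 highest-scoring features are kept with a
#' warning.
#'
#' @param scores tibble from [fisher_scores()].
#' @param threshold minimum Fisher score.
#' @return logical vector aligned with `scores`.
#' @export
prefilter_features <- function(scores, threshold = 0.1) {
  mask <- scores$j >= threshold
  if (!any(mask)) {
    warning("no feature reaches the Fisher threshold; keeping the top 10",
            call. = FALSE)
    mask <- rank(-scores$j, ties.method = "first") <= 10L
  }
  mask
}

#' Boosted-tree importance ranking
#'
#' Fits a gradient-boosted tree ensemble on the given data and ranks
#' features by mean split gain, descending; features the ensemble never
#' splits on get gain 0. Ties are broken by column order.
#'
#' @param data feature tibble (rows = epochs).
#' @param features feature column names to rank.
#' @param stage label column name.
#' @param params [model_params()] for the ranking model.
#' @return tibble `feature`, `gain`, `rank` (1 = most important).
#' @export
importance_rank <- function(data, features, stage = "stage",
                            params = model_params()) {
  fit <- fit_stager(data, features = features, stage = stage, params = params)
  imp <- xgboost::xgb.importance(model = fit$booster)
  gain <- stats::setNames(rep(0, length(features)), features)
  gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, seq_along(features))
  tibble::tibble(
    feature = features[ord],
    gain = unname(gain[ord]),
    rank = seq_along(features)
  )
}

#' Top-k of a ranking
#'
#' @param ranking tibble from [importance_rank()] (ordered by `rank`).
#' @param k number of features to keep; clamped to the ranking length.
#' @return character vector of selected feature names.
#' @export
select_top_k <- function(ranking, k = 25L) {
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  ranking$feature[seq_len(min(k, nrow(ranking)))]
}

#' Two-step feature selection
#'
#' Computes Fisher scores on `data`, discards features scoring below the
#' threshold, ranks the survivors by boosted-tree importance (trained on
#' `rank_data` if given, e.g. an inner learning split, else on `data`), and
#' keeps the top `k`.
#'
#' @param data feature tibble used for Fisher scoring.
#' @param config a [stager_config()] (threshold, k, model parameters).
#' @param stage label column name.
#' @param rank_data optional tibble for the importance-ranking fit.
#' @return object of class `feature_selection`: list with `scores`
#'   (per-feature tibble), `selected` (character vector), `threshold`, `k`.
#' @export
select_features <- function(data, config = stager_config(), stage = "stage",
                            rank_data = NULL) {
  fs_tbl <- fisher_scores(data, stage = stage)
  mask <- prefilter_features(fs_tbl, config$fisher_threshold)
  survivors <- fs_tbl$feature[mask]
  rk <- importance_rank(rank_data %||% data, survivors, stage = stage,
                        params = config$model)
  selected <- select_top_k(rk, config$top_k)
  scores <- fs_tbl |>
    dplyr::mutate(survived = mask) |>
    dplyr::left_join(rk, by = "feature") |>
    dplyr::mutate(selected = .data$feature %in% selected)
  structure(
    list(scores = scores, selected = selected,
         threshold = config$fisher_threshold, k = config$top_k),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Two-step feature selection: ", sum(x$scores$survived), "/",
      nrow(x$scores), " past Fisher >= ", x$threshold, "; ",
      length(x$selected), " selected (k = ", x$k, ")\n", sep = "")
  cat("top features:", paste(utils::head(x$selected, 6), collapse = ", "),
      "...\n")
  invisible(x)
}

#' @export
tidy.feature_selection <- function(x, ...) x$scores

#' Validation accuracy as a function of feature count
#'
#' For each `k` in `k_grid`, trains on the learning rows using the top-k
#' features of `ranking` and reports accuracy on the validation rows.
#'
#' @param learn,validate feature tibbles.
#' @param ranking tibble from [importance_rank()].
#' @param k_grid integer vector of feature counts.
#' @param stage label column name.
#' @param params [model_params()].
#' @return tibble `k`, `accuracy` (percent).
#' @export
accuracy_vs_k_curve <- function(learn, validate, ranking,
                                k_grid = c(5, 10, 25, 50, 76),
                                stage = "stage", params = model_params()) {
  k_grid <- pmin(k_grid, nrow(ranking))
  purrr::map_dfr(unique(k_grid), function(k) {
    feats <- select_top_k(ranking, k)
    fit <- fit_stager(learn, features = feats, stage = stage, params = params)
    pred <- predict(fit, validate)
    tibble::tibble(k = k, accuracy = 100 * mean(pred == validate[[stage]]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
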
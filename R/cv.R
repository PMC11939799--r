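# Subject-wise cross-validation: fold planning and orchestration.

#' Subject-wise fold plan
#'
#' Randomly partitions subjects into `k` near-equal test folds and, within
#' each fold's training complement, splits subjects into a learning and a
#' validation group (`inner_val_fraction` of the training subjects go to
#' validation). Every night of a subject travels with the subject, so no
#' subject ever appears on both sides of a split.
#'
#' @param subject_ids character vector of distinct subject identifiers.
#' @param k number of folds.
#' @param inner_val_fraction fraction of each training set assigned to the
#'   inner validation group (default 1/3, i.e. 40 learning / 20 validation
#'   out of a 60-subject training set).
#' @param seed RNG seed.
#' @return tibble `fold`, `subject_id`, `role` with role in
#'   test/learning/validation; `k * length(subject_ids)` rows.
#' @export
make_folds <- function(subject_ids, k = 5L, inner_val_fraction = 1 / 3,
                       seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (k > n) stop("more folds than subjects", call. = FALSE)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  plan <- withr_seed({
    shuffled <- sample(subject_ids)
    fold_of <- stats::setNames(rep(seq_len(k), length.out = n), shuffled)
    purrr::map_dfr(seq_len(k), function(f) {
      test <- shuffled[fold_of[shuffled] == f]
      train <- setdiff(shuffled, test)
      n_val <- max(1L, round(length(train) * inner_val_fraction))
      val <- sample(train, n_val)
      tibble::tibble(
        fold = f,
        subject_id = c(test, setdiff(train, val), val),
        role = c(rep("test", length(test)),
                 rep("learning", length(train) - n_val),
                 rep("validation", n_val))
      )
    })
  })
  audit_fold_plan(plan)
  plan
}

#' Leakage audit of a fold plan
#'
#' Asserts that within every fold the test subjects are disjoint from the
#' learning and validation subjects, learning and validation are disjoint,
#' and the folds' test sets partition the subject set.
#'
#' @param plan tibble from [make_folds()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
audit_fold_plan <- function(plan) {
  for (f in unique(plan$fold)) {
    p <- plan[plan$fold == f, ]
    test <- p$subject_id[p$role == "test"]
    train <- p$subject_id[p$role != "test"]
    if (length(intersect(test, train)) > 0L) {
      stop("leakage: subject(s) on both sides of fold ", f, call. = FALSE)
    }
    lrn <- p$subject_id[p$role == "learning"]
    val <- p$subject_id[p$role == "validation"]
    if (length(intersect(lrn, val)) > 0L) {
      stop("leakage: learning/validation overlap in fold ", f, call. = FALSE)
    }
  }
  tests <- plan$subject_id[plan$role == "test"]
  if (anyDuplicated(tests) || !setequal(tests, unique(plan$subject_id))) {
    stop("test sets do not partition the subject set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run subject-wise cross-validated staging
#'
#' For each fold: the two-step feature selection is fitted on the training
#' subjects only (Fisher scores on the whole training fold, importance
#' ranking on its learning split); optionally the hyperparameters are
#' re-tuned by grid search on the learning/validation split; the final
#' model is trained on the full training fold and evaluated on the held-out
#' test subjects. No test-fold information enters selection or tuning.
#'
#' @param features feature tibble from [build_feature_matrix()].
#' @param config a [stager_config()].
#' @param k number of folds.
#' @param seed RNG seed for the fold plan and boosters.
#' @param tune if `TRUE`, grid-search the hyperparameters per fold
#'   (default uses the tuned operating point as-is).
#' @param grid tuning grid for `tune = TRUE`.
#' @param plan optional pre-built fold plan.
#' @return object of class `sleep_cv`: list with `folds` (per-fold
#'   `stage_eval`s), `pooled` (`stage_eval` over all test predictions),
#'   `selections` (per-fold `feature_selection`s), `plan`, `predictions`
#'   (tibble of per-epoch truth/estimate).
#' @export
run_cv <- function(features, config = stager_config(), k = 5L, seed = 1L,
                   tune = FALSE, grid = default_grid(), plan = NULL) {
  plan <- plan %||% make_folds(unique(features$subject_id), k = k,
                               inner_val_fraction = 1 / 3, seed = seed)
  audit_fold_plan(plan)
  folds <- sort(unique(plan$fold))
  evals <- list()
  selections <- list()
  preds <- list()
  for (f in folds) {
    p <- plan[plan$fold == f, ]
    subj <- function(role) p$subject_id[p$role %in% role]
    test_df <- features[features$subject_id %in% subj("test"), ]
    train_df <- features[features$subject_id %in% subj(c("learning", "validation")), ]
    learn_df <- features[features$subject_id %in% subj("learning"), ]
    val_df <- features[features$subject_id %in% subj("validation"), ]
    stopifnot(length(intersect(test_df$subject_id, train_df$subject_id)) == 0L)

    cfg <- config
    cfg$model$seed <- seed + f  # per-fold booster seed stream
    sel <- select_features(train_df, cfg, rank_data = learn_df)
    params <- cfg$model
    if (tune) {
      gs <- grid_search(learn_df, val_df, grid, base = params,
                        features = sel$selected)
      params <- gs$best
    }
    fit <- fit_stager(train_df, features = sel$selected, params = params)
    est <- predict(fit, test_df)
    evals[[f]] <- evaluate_staging(test_df$stage, est)
    selections[[f]] <- sel
    preds[[f]] <- tibble::tibble(
      fold = f, subject_id = test_df$subject_id,
      epoch_index = test_df$epoch_index,
      truth = test_df$stage, estimate = est
    )
  }
  predictions <- dplyr::bind_rows(preds)
  pooled <- evaluate_staging(predictions$truth, predictions$estimate)
  structure(
    list(folds = evals, pooled = pooled, selections = selections,
         plan = plan, predictions = predictions),
    class = "sleep_cv"
  )
}

#' @export
print.sleep_cv <- function(x, ...) {
  cat("Subject-wise ", length(x$folds), "-fold cross-validation, ",
      x$pooled$n, " test epochs\n", sep = "")
  cat(sprintf("pooled: accuracy %.2f%%  macro-F1 %.2f  kappa %.3f\n",
              x$pooled$accuracy, x$pooled$macro_f1, x$pooled$kappa))
  invisible(x)
}

#' @describeIn run_cv per-fold and pooled overall metrics, one row each.
#' @param x a `sleep_cv` object.
#' @param ... unused.
#' @export
tidy.sleep_cv <- function(x, ...) {
  per_fold <- purrr::imap_dfr(x$folds, function(ev, f) {
    dplyr::mutate(glance(ev), fold = as.character(f), .before = 1L)
  })
  dplyr::bind_rows(per_fold,
                   dplyr::mutate(glance(x$pooled), fold = "pooled", .before = 1L))
}

#' @describeIn run_cv pooled metrics plus the fold-averaged accuracy.
#' @export
glance.sleep_cv <- function(x, ...) {
  fold_acc <- vapply(x$folds, function(ev) ev$accuracy, numeric(1))
  dplyr::mutate(glance(x$pooled),
                mean_fold_accuracy = mean(fold_acc),
                n_folds = length(x$folds))
}
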
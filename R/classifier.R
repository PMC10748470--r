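#' Stratified train / validation split
#'
#' Splits a labeled feature table into disjoint, exhaustive training and
#' validation sets (default 75% / 25%), preserving class proportions within
#' rounding. Reproducible given `seed`.
#'
#' @param data Tibble with a binary label column and feature columns.
#' @param fraction Training fraction in `(0, 1]`; `1` yields an empty
#'   validation set with a warning.
#' @param seed Integer seed.
#' @param stratify Preserve class proportions (default `TRUE`).
#' @param label_col Name of the 0/1 label column.
#' @return A list with elements `train` and `validation`.
#' @export
split_train_validation <- function(data, fraction = 0.75, seed = 1L,
                                   stratify = TRUE, label_col = "label") {
  check_labels(data, label_col)
  if (fraction <= 0 || fraction > 1) {
    stop_invalid("`fraction` must be in (0, 1].")
  }
  if (fraction == 1) {
    warn("`fraction` = 1: validation set is empty.")
  }
  idx <- withr::with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(seq_len(nrow(data)), data[[label_col]]), function(i) {
        sample(i, round(fraction * length(i)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(data)), round(fraction * nrow(data)))
    }
  })
  list(train = data[sort(idx), , drop = FALSE],
       validation = data[setdiff(seq_len(nrow(data)), idx), , drop = FALSE])
}

check_labels <- function(data, label_col) {
  if (!label_col %in% names(data)) {
    stop_invalid("no label column `", label_col, "` in data.")
  }
  lab <- data[[label_col]]
  if (!all(lab %in% c(0, 1))) stop_invalid("labels must be 0/1.")
  if (length(unique(lab)) < 2) {
    stop_invalid("both classes (singing = 1, background = 0) must be present.")
  }
  invisible(lab)
}

#' Fit a singing / background classifier
#'
#' Trains a binary classifier on clip feature vectors. The default learner
#' is an ensemble of decision trees (random forest, 500 trees); a single
#' classification tree (`"cart"`) and k-nearest-neighbours (`"knn"`) are
#' available for learner comparisons. Exact 0.5 ensemble votes are scored
#' as singing (favouring sensitivity). Deterministic given `seed`.
#'
#' @inheritParams split_train_validation
#' @param train Labeled feature tibble.
#' @param learner `"rf"`, `"cart"` or `"knn"`.
#' @param n_trees Trees in the forest (rf only).
#' @param knn_k Neighbours (knn only; odd values avoid vote ties).
#' @return A `song_classifier` object.
#' @export
fit_song_classifier <- function(train, learner = c("rf", "cart", "knn"),
                                n_trees = 500, knn_k = 5, seed = 1L,
                                label_col = "label") {
  learner <- match.arg(learner)
  check_labels(train, label_col)
  features <- setdiff(names(train), label_col)
  if (length(features) == 0) stop_invalid("no feature columns in `train`.")
  x <- train[features]
  y <- factor(train[[label_col]], levels = c(0, 1))
  model <- switch(
    learner,
    rf = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = n_trees,
      probability = TRUE, seed = seed, num.threads = 1
    ),
    cart = withr::with_seed(seed, {
      df <- as.data.frame(x); df$.label <- y
      rpart::rpart(.label ~ ., data = df, method = "class")
    }),
    knn = list(x = as.data.frame(x), y = y, k = knn_k)
  )
  structure(
    list(model = model, learner = learner, feature_names = features,
         config = list(n_trees = n_trees, knn_k = knn_k, seed = seed)),
    class = "song_classifier"
  )
}

#' @export
print.song_classifier <- function(x, ...) {
  cat("<song_classifier> learner:", x$learner, "| features:",
      paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Predict singing labels for new clips
#'
#' @param object A fitted [fit_song_classifier()] model.
#' @param newdata Feature tibble with exactly the model's training features.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per clip.
#' @export
predict.song_classifier <- function(object, newdata, ...) {
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f) > 0) {
    stop_invalid("newdata lacks model feature(s): ",
                 paste(missing_f, collapse = ", "))
  }
  x <- as.data.frame(newdata[object$feature_names])
  p1 <- switch(
    object$learner,
    rf = stats::predict(object$model, data = x,
                        num.threads = 1)$predictions[, "1"],
    cart = stats::predict(object$model, newdata = x, type = "prob")[, "1"],
    knn = {
      pred <- withr::with_seed(object$config$seed, {
        class::knn(object$model$x, x, object$model$y, k = object$model$k,
                   prob = TRUE)
      })
      pw <- attr(pred, "prob")
      ifelse(pred == "1", pw, 1 - pw)
    }
  )
  as.integer(p1 >= 0.5) # exact ties scored as singing
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginals. When the marginals are degenerate (`p_e = 1`) kappa is defined
#' as 1 for perfect observed agreement and `NaN` (flagged with a warning)
#' otherwise.
#'
#' @param confusion 2x2 count matrix (rows = truth, columns = predicted).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(matrix(c(40, 5, 10, 45), 2)) # 0.70
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) stop_invalid("confusion matrix has no counts.")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) return(1)
    warn("degenerate marginals (p_e = 1); kappa undefined.")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Exact binomial (Clopper-Pearson) confidence interval for accuracy
#'
#' @param confusion 2x2 count matrix, or a single number of correct
#'   classifications (then `n` must be given).
#' @param n Total count when `confusion` is a scalar.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`, a subset of `[0, 1]`.
#' @export
accuracy_ci <- function(confusion, n = NULL, level = 0.95) {
  if (is.matrix(confusion) || length(confusion) == 4) {
    m <- as.matrix(confusion)
    correct <- sum(diag(m)); n <- sum(m)
  } else {
    correct <- confusion
    if (is.null(n)) stop_invalid("`n` required with scalar `confusion`.")
  }
  if (n <= 0) stop_invalid("total count must be positive.")
  ci <- stats::binom.test(correct, n, conf.level = level)$conf.int
  c(lo = ci[1], hi = ci[2])
}

new_eval_report <- function(confusion, per_fold = NULL) {
  acc <- sum(diag(confusion)) / sum(confusion)
  structure(
    list(confusion = confusion, accuracy = acc,
         kappa = cohens_kappa(confusion),
         accuracy_ci = accuracy_ci(confusion),
         per_fold = per_fold),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> accuracy %.3f [%.3f, %.3f], kappa %.3f (n = %d)\n",
    x$accuracy, x$accuracy_ci["lo"], x$accuracy_ci["hi"], x$kappa,
    sum(x$confusion)))
  invisible(x)
}

#' Evaluate predictions against truth
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return An `eval_report`: confusion matrix (rows = truth, columns =
#'   predicted), accuracy, Cohen's kappa, exact binomial 95% CI.
#' @export
evaluate_predictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion <- table(factor(truth, levels = c(0, 1)),
                     factor(predicted, levels = c(0, 1)))
  new_eval_report(unclass(as.matrix(confusion)))
}

#' Stratified k-fold cross-validation
#'
#' Evaluates a learner by stratified k-fold cross-validation (default
#' k = 10): folds preserve class balance, each clip is predicted exactly once
#' out-of-fold, and the pooled confusion matrix over all out-of-fold
#' predictions summarises performance (with per-fold accuracies retained).
#'
#' @inheritParams fit_song_classifier
#' @param data Labeled feature tibble.
#' @param k Number of folds (>= 2, at most the size of the rarer class).
#' @return An `eval_report` with a `per_fold` tibble (`fold`, `n`,
#'   `accuracy`).
#' @export
cross_validate <- function(data, k = 10, learner = "rf", n_trees = 500,
                           knn_k = 5, seed = 1L, label_col = "label") {
  lab <- check_labels(data, label_col)
  if (k < 2) stop_invalid("`k` must be at least 2.")
  if (k > min(table(lab))) {
    stop_invalid("`k` exceeds the size of the rarer class.")
  }
  fold <- integer(nrow(data))
  fold_assign <- withr::with_seed(seed, {
    lapply(split(seq_len(nrow(data)), lab), function(i) {
      sample(rep(seq_len(k), length.out = length(i)))
    })
  })
  for (cls in names(fold_assign)) {
    fold[split(seq_len(nrow(data)), lab)[[cls]]] <- fold_assign[[cls]]
  }
  pred <- integer(nrow(data))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- fold == f
    model <- fit_song_classifier(data[!hold, , drop = FALSE],
                                 learner = learner, n_trees = n_trees,
                                 knn_k = knn_k, seed = seed + f,
                                 label_col = label_col)
    pred[hold] <- predict(model, data[hold, , drop = FALSE])
    per_fold[[f]] <- tibble(fold = f, n = sum(hold),
                            accuracy = mean(pred[hold] == lab[hold]))
  }
  confusion <- unclass(as.matrix(table(factor(lab, levels = c(0, 1)),
                                       factor(pred, levels = c(0, 1)))))
  new_eval_report(confusion, per_fold = bind_rows(per_fold))
}

#' Pare a feature catalogue down by permutation importance
#'
#' Replays the iterative feature-paring workflow: starting from the full
#' catalogue, repeatedly fits a random forest with permutation importance
#' and drops the least important feature until `n_keep` remain.
#'
#' @inheritParams fit_song_classifier
#' @param data Labeled feature tibble (label column plus feature columns).
#' @param n_keep Number of features to retain (default 5).
#' @return Character vector of the retained feature names, in their
#'   original column order.
#' @export
pare_features <- function(data, n_keep = 5, n_trees = 500, seed = 1L,
                          label_col = "label") {
  check_labels(data, label_col)
  keep <- setdiff(names(data), label_col)
  if (n_keep >= length(keep)) return(keep)
  y <- factor(data[[label_col]], levels = c(0, 1))
  step <- 0L
  while (length(keep) > n_keep) {
    step <- step + 1L
    fit <- ranger::ranger(x = as.data.frame(data[keep]), y = y,
                          num.trees = n_trees, importance = "permutation",
                          seed = seed + step, num.threads = 1)
    drop <- names(which.min(fit$variable.importance))
    keep <- setdiff(keep, drop)
  }
  keep
}
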
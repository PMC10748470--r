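#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Lomb-Scargle periodogram
#'
#' @param x An `ls_periodogram`.
#' @param ... Unused.
#' @return Tibble with `period_h`, `power`, `threshold`, `significant`.
#' @method tidy ls_periodogram
#' @export
tidy.ls_periodogram <- function(x, ...) {
  mutate(x$spectrum, threshold = x$threshold,
         significant = .data$power > x$threshold)
}

#' @rdname tidy.ls_periodogram
#' @return `glance()`: one row with `best_period`, `peak_power`,
#'   `threshold`, `alpha`, `is_rhythmic`, `n`.
#' @method glance ls_periodogram
#' @export
glance.ls_periodogram <- function(x, ...) {
  tibble(best_period = x$best_period, peak_power = x$peak_power,
         threshold = x$threshold, alpha = x$alpha,
         is_rhythmic = x$is_rhythmic, n = x$n)
}

#' Tidy a classifier evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return `tidy()`: the confusion matrix in long form (`truth`,
#'   `predicted`, `n`), with per-fold accuracies appended as an attribute
#'   when the report came from cross-validation.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  cm <- x$confusion
  out <- tibble(truth = rep(rownames(cm) %||% c("0", "1"), 2),
                predicted = rep(colnames(cm) %||% c("0", "1"), each = 2),
                n = as.vector(cm))
  attr(out, "per_fold") <- x$per_fold
  out
}

#' @rdname tidy.eval_report
#' @return `glance()`: one row with `accuracy`, `kappa`, `ci_lo`, `ci_hi`,
#'   `n`, and mean/SD of per-fold accuracy when available.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, kappa = x$kappa,
         ci_lo = unname(x$accuracy_ci["lo"]),
         ci_hi = unname(x$accuracy_ci["hi"]),
         n = sum(x$confusion),
         fold_accuracy_mean = if (!is.null(x$per_fold)) {
           mean(x$per_fold$accuracy)
         } else NA_real_,
         fold_accuracy_sd = if (!is.null(x$per_fold)) {
           sd(x$per_fold$accuracy)
         } else NA_real_)
}

#' @importFrom rlang %||%
NULL

#' Glance at a fitted song classifier
#'
#' @param x A `song_classifier`.
#' @param ... Unused.
#' @return One-row tibble with `learner`, `n_features`, `n_trees`, `seed`.
#' @method glance song_classifier
#' @export
glance.song_classifier <- function(x, ...) {
  tibble(learner = x$learner, n_features = length(x$feature_names),
         n_trees = x$config$n_trees, seed = x$config$seed)
}
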
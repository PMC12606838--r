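#' Reproducible k-fold partition
#'
#' Splits `1:n` into `k` disjoint folds whose sizes differ by at most one.
#' The partition is a simple random split, reproducible from `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param n number of rows.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` integer vectors covering `1:n`.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (n < k) stop("need at least k = ", k, " rows, got ", n)
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

# pooled out-of-sample metrics on the proportion scale
.prediction_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  err <- pred - obs
  corr <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_ else
    stats::cor(pred, obs)
  list(r_squared = corr^2, bias = mean(err), mae = mean(abs(err)),
       correlation = corr, n = length(obs))
}

#' k-fold cross-validation of a DFPS model specification
#'
#' For each fold the model is refitted on the remaining folds and the
#' held-out rows are predicted and back-transformed to the proportion
#' scale. All held-out (predicted, observed) pairs are pooled and
#' summarized by bias (mean of predicted minus observed), mean absolute
#' error, Pearson correlation, and R^2 (the squared pooled correlation) --
#' all on the proportion scale.
#'
#' @inheritParams fit_fp
#' @param k number of folds (default 5); `k = n` gives leave-one-out.
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_result`: `r_squared`, `bias`, `mae`,
#'   `correlation`, `k`, `seed`, `n`.
#' @export
cross_validate <- function(data, outcome = c("any", "modern"),
                           powers = c(0, 2), extras = "cpdiff",
                           k = 5, seed = 1, cluster = "country_id") {
  outcome <- match.arg(outcome)
  cols <- .outcome_cols(outcome)
  n <- nrow(data)
  folds <- kfold_split(n, k, seed)
  pred <- obs <- numeric(0)
  for (i in seq_along(folds)) {
    test_idx <- folds[[i]]
    train <- data[-test_idx, , drop = FALSE]
    fit <- tryCatch(
      fit_fp(train, outcome, powers = powers, extras = extras,
             cluster = cluster),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    pred <- c(pred, predict(fit, data[test_idx, , drop = FALSE],
                            type = "response"))
    obs <- c(obs, data[[cols$dfps]][test_idx])
  }
  m <- .prediction_metrics(pred, obs)
  structure(c(m, list(k = k, seed = seed)), class = "cv_result")
}

#' Evaluate a frozen model on another dataset
#'
#' Predicts every row of `data` with an already-fitted model (no
#' refitting, no folds), back-transforms, and computes the same metrics as
#' [cross_validate()] -- the design used to check how a model fitted on one
#' inequality dimension performs on the others.
#'
#' @param fit an `fp_fit` (fitted or loaded via [read_model()]).
#' @param data estimation rows holding the model's predictors and the
#'   observed outcome.
#' @return object of class `cv_result` with `k = NA` and `seed = NA`.
#' @export
out_of_sample_eval <- function(fit, data) {
  cols <- .outcome_cols(fit$outcome)
  if (!cols$dfps %in% names(data)) {
    stop("column '", cols$dfps, "' not found in evaluation data")
  }
  pred <- predict(fit, data, type = "response")
  m <- .prediction_metrics(pred, data[[cols$dfps]])
  structure(c(m, list(k = NA_integer_, seed = NA_integer_)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  lab <- if (is.na(x$k)) "Out-of-sample evaluation" else
    sprintf("%d-fold cross-validation (seed %d)", x$k, x$seed)
  cat(lab, "\n", sep = "")
  cat(sprintf("  n = %d held-out predictions\n", x$n))
  cat(sprintf("  R^2 = %.4f  bias = %+.4f  MAE = %.4f  r = %.4f\n",
              x$r_squared, x$bias, x$mae, x$correlation))
  invisible(x)
}
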
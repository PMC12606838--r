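#' Logit and inverse-logit transforms
#'
#' The DFPS models are linear on the logit scale; back-transforming with
#' `inv_logit()` guarantees predictions stay inside (0, 1).
#'
#' @param p proportion strictly inside (0, 1).
#' @param x real number.
#' @return `logit()` returns `log(p / (1 - p))`; `inv_logit()` returns
#'   `1 / (1 + exp(-x))`.
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.937))
#' @export
logit <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit is defined only for proportions strictly inside (0, 1)")
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  stats::plogis(x)
}

#' Published DFPS predictor coefficients
#'
#' The fitted fractional-polynomial equations mapping contraceptive
#' prevalence to demand for family planning satisfied, on the logit scale:
#'
#' \deqn{logit(DFPSany) = 1.05 + 0.93 \log(CPRany) + 2.49\, CPRany^2 +
#'   0.70\, cpdiff}
#' \deqn{logit(DFPSm) = 1.12 + 0.97 \log(CPRm) + 2.13\, CPRm^2 -
#'   1.43\, cpdiff}
#'
#' where all quantities -- CPR, cpdiff = CPRany − CPRm, and DFPS -- are on
#' the proportion (0--1) scale and `log` is the natural logarithm.
#'
#' @param outcome `"any"` (DFPSany) or `"modern"` (DFPSm).
#' @param intercept,beta_log,beta_sq,beta_cpdiff optional overrides of the
#'   default coefficients, e.g. from a refit via [fit_fp()].
#' @return object of class `dfps_coefficients`.
#' @export
dfps_coefficients <- function(outcome = c("any", "modern"),
                              intercept = NULL, beta_log = NULL,
                              beta_sq = NULL, beta_cpdiff = NULL) {
  outcome <- match.arg(outcome)
  defaults <- if (outcome == "any") {
    c(intercept = 1.05, beta_log = 0.93, beta_sq = 2.49, beta_cpdiff = 0.70)
  } else {
    c(intercept = 1.12, beta_log = 0.97, beta_sq = 2.13, beta_cpdiff = -1.43)
  }
  out <- list(
    outcome = outcome,
    intercept = if (is.null(intercept)) defaults[["intercept"]] else intercept,
    beta_log = if (is.null(beta_log)) defaults[["beta_log"]] else beta_log,
    beta_sq = if (is.null(beta_sq)) defaults[["beta_sq"]] else beta_sq,
    beta_cpdiff = if (is.null(beta_cpdiff)) defaults[["beta_cpdiff"]] else
      beta_cpdiff
  )
  structure(out, class = "dfps_coefficients")
}

#' @export
print.dfps_coefficients <- function(x, ...) {
  lab <- if (x$outcome == "any") c("DFPSany", "CPRany") else
    c("DFPSm", "CPRm")
  cat(sprintf("logit(%s) = %.4g + %.4g*log(%s) + %.4g*%s^2 + %.4g*cpdiff\n",
              lab[1], x$intercept, x$beta_log, lab[2], x$beta_sq, lab[2],
              x$beta_cpdiff))
  invisible(x)
}

# linear predictor on the logit scale; cpr is the outcome-relevant CPR
.dfps_link <- function(cpr, cpdiff, coeffs) {
  coeffs$intercept + coeffs$beta_log * log(cpr) +
    coeffs$beta_sq * cpr^2 + coeffs$beta_cpdiff * cpdiff
}

#' Predict demand for family planning satisfied from CPR
#'
#' Evaluates the published equations (see [dfps_coefficients()]). The
#' outcome-relevant prevalence is CPRany for DFPSany and CPRm for DFPSm;
#' cpdiff = CPRany − CPRm enters both equations.
#'
#' Prevalences below 1% are outside the fitted range and raise an error
#' here (use [predict_batch()] to flag-and-continue over a table). Values
#' above 0.99 are clamped to 0.99 with a warning to keep the logit finite.
#' When `cpr_m` is unknown for the modern outcome's companion, `cpdiff`
#' falls back to 0 with a warning; that is an approximation, not a silent
#' default.
#'
#' @param cpr_any contraceptive prevalence, any method, proportion scale.
#' @param cpr_m contraceptive prevalence, modern methods, proportion scale;
#'   may be `NULL` (cpdiff taken as 0, with a warning).
#' @param outcome `"any"` or `"modern"`.
#' @param coeffs optional [dfps_coefficients()] override.
#' @return numeric vector of predicted DFPS on the proportion scale.
#' @examples
#' predict_dfps(cpr_any = 0.437, cpr_m = 0.403, outcome = "any")
#' @export
predict_dfps <- function(cpr_any, cpr_m = NULL,
                         outcome = c("any", "modern"), coeffs = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(coeffs)) coeffs <- dfps_coefficients(outcome)
  stopifnot(inherits(coeffs, "dfps_coefficients"))
  if (is.null(cpr_m)) {
    warning("cpr_m not supplied; using cpdiff = 0 (approximation)")
    cpdiff <- rep(0, length(cpr_any))
    cpr_m <- cpr_any
  } else {
    if (length(cpr_m) != length(cpr_any)) {
      stop("cpr_any and cpr_m must have the same length")
    }
    if (any(!is.na(cpr_m) & !is.na(cpr_any) & cpr_m > cpr_any + 1e-12)) {
      stop("cpr_m exceeds cpr_any: modern users are a subset of all users")
    }
    cpdiff <- cpr_any - cpr_m
  }
  cpr <- if (outcome == "any") cpr_any else cpr_m
  if (any(is.na(cpr))) stop("missing prevalence values; use predict_batch()")
  if (any(cpr < 0.01)) {
    stop("prevalence below 1% is outside the fitted range; ",
         "rows should be excluded (see apply_exclusion)")
  }
  if (any(cpr > 0.99)) {
    warning("prevalence above 0.99 clamped to 0.99")
    cpr <- pmin(cpr, 0.99)
  }
  inv_logit(.dfps_link(cpr, cpdiff, coeffs))
}

#' Predict DFPS over a table of prevalence rows
#'
#' Row-wise application of [predict_dfps()] that never aborts the batch:
#' rows outside the fitted range (relevant CPR < 1%), with missing values,
#' or violating CPRm <= CPRany are flagged and left unpredicted.
#'
#' @param rows data frame with columns `cpr_any` and `cpr_m` (proportion
#'   scale).
#' @inheritParams predict_dfps
#' @return `rows` with three added columns: `dfps_pred` (NA where
#'   excluded), `excluded` (logical), `note` (reason, `""` if none). Row
#'   order is preserved.
#' @export
predict_batch <- function(rows, outcome = c("any", "modern"), coeffs = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(coeffs)) coeffs <- dfps_coefficients(outcome)
  need_cols <- c("cpr_any", "cpr_m")
  miss <- setdiff(need_cols, names(rows))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(rows)
  pred <- rep(NA_real_, n)
  note <- character(n)
  if (n == 0) {
    rows$dfps_pred <- numeric(0)
    rows$excluded <- logical(0)
    rows$note <- character(0)
    return(rows)
  }
  cpr_any <- rows$cpr_any
  cpr_m <- rows$cpr_m
  cpr <- if (outcome == "any") cpr_any else cpr_m
  bad_na <- is.na(cpr_any) | is.na(cpr_m)
  bad_order <- !bad_na & cpr_m > cpr_any + 1e-12
  bad_range <- !bad_na & !bad_order &
    (cpr_any < 0 | cpr_any > 1 | cpr_m < 0 | cpr_m > 1)
  low <- !bad_na & !bad_order & !bad_range & cpr < 0.01
  high <- !bad_na & !bad_order & !bad_range & !low & cpr > 0.99
  note[bad_na] <- "missing prevalence"
  note[bad_order] <- "cpr_m > cpr_any"
  note[bad_range] <- "prevalence outside [0, 1]"
  note[low] <- "prevalence below 1% (excluded)"
  note[high] <- "prevalence clamped at 0.99"
  ok <- !bad_na & !bad_order & !bad_range & !low
  if (any(ok)) {
    cpr_ok <- pmin(cpr[ok], 0.99)
    pred[ok] <- inv_logit(
      .dfps_link(cpr_ok, cpr_any[ok] - cpr_m[ok], coeffs))
  }
  rows$dfps_pred <- pred
  rows$excluded <- !ok
  rows$note <- note
  rows
}

#' Prediction surface over a CPR grid at fixed cpdiff levels
#'
#' Long-format table of predicted DFPS across a prevalence grid, one curve
#' per cpdiff level -- the data behind plots of predicted DFPS against CPR
#' at, say, the 10th percentile, mean, and 90th percentile of the observed
#' cpdiff distribution (see [export_surface_data()]).
#'
#' @param outcome `"any"` or `"modern"`.
#' @param cpdiff_levels numeric vector of cpdiff values (proportion scale).
#' @param cpr_grid numeric grid inside \[0.01, 0.99\].
#' @inheritParams predict_dfps
#' @return data frame with columns `cpr`, `cpdiff`, `dfps_pred`, `outcome`.
#' @export
prediction_surface <- function(outcome = c("any", "modern"),
                               cpdiff_levels,
                               cpr_grid = seq(0.01, 0.99, by = 0.01),
                               coeffs = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(coeffs)) coeffs <- dfps_coefficients(outcome)
  if (any(cpr_grid < 0.01 | cpr_grid > 0.99)) {
    stop("cpr_grid must lie within [0.01, 0.99]")
  }
  grid <- expand.grid(cpr = cpr_grid, cpdiff = cpdiff_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$dfps_pred <- inv_logit(.dfps_link(grid$cpr, grid$cpdiff, coeffs))
  grid$outcome <- outcome
  grid
}

#' The published DFPS models as frozen fitted-model objects
#'
#' Wraps the published equations (see [dfps_coefficients()]) in an
#' `fp_fit` so they can be used wherever a fitted model is expected --
#' notably [out_of_sample_eval()] for frozen evaluation on new data, and
#' [predict.fp_fit()].
#'
#' @inheritParams dfps_coefficients
#' @return an `fp_fit` with powers (0, 2), the cpdiff covariate, and the
#'   published coefficients; fit summaries are `NA` (the source data are
#'   not distributed).
#' @examples
#' m <- published_model("any")
#' predict(m, data.frame(cpr_any = 0.437, cpr_m = 0.403))
#' @export
published_model <- function(outcome = c("any", "modern")) {
  outcome <- match.arg(outcome)
  co <- dfps_coefficients(outcome)
  var <- if (outcome == "any") "cpr_any" else "cpr_m"
  coefs <- c(co$intercept, co$beta_log, co$beta_sq, co$beta_cpdiff)
  names(coefs) <- c("(Intercept)", paste0("log(", var, ")"),
                    paste0(var, "^2"), "cpdiff")
  structure(list(
    coefficients = coefs, robust_se = rep(NA_real_, 4), vcov = NULL,
    rss = NA_real_, r_squared = NA_real_, n_obs = NA_integer_,
    n_clusters = NA_integer_, df_residual = NA_integer_,
    outcome = outcome, powers = c(0, 2), extras = "cpdiff"
  ), class = "fp_fit")
}
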
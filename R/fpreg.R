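#' Standard fractional-polynomial power set
#'
#' The Royston--Altman candidate powers for fractional polynomials:
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where power 0 denotes the natural
#' logarithm and a repeated power adds a log-multiplied term.
#'
#' @return numeric vector of candidate powers.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

.fp_term_label <- function(var, p) {
  if (p == 0) paste0("log(", var, ")")
  else if (p == 1) var
  else paste0(var, "^", format(p))
}

#' Fractional-polynomial basis transform
#'
#' Builds the design columns for a fractional polynomial of a positive
#' predictor: power `p != 0` gives `x^p`, power 0 gives `log(x)`, and a
#' repeated power `(p, p)` gives `x^p` and `x^p * log(x)` (for `(0, 0)`:
#' `log(x)` and `log(x)^2`), the standard convention.
#'
#' @param x positive numeric vector.
#' @param powers numeric vector of length 1 or 2 drawn from [fp_powers()]
#'   (any real powers are accepted; the standard set is what [fp_search()]
#'   explores).
#' @param var_name name used to label the columns.
#' @return numeric matrix with one column per term.
#' @examples
#' fp_transform(0.5, c(0, 2))
#' @export
fp_transform <- function(x, powers, var_name = "x") {
  if (length(powers) < 1 || length(powers) > 2) {
    stop("powers must have length 1 or 2")
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop("fractional polynomial requires strictly positive values; ",
         "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  one <- function(p) if (p == 0) log(x) else x^p
  powers <- sort(powers)
  if (length(powers) == 2 && powers[1] == powers[2]) {
    p <- powers[1]
    cols <- cbind(one(p), one(p) * log(x))
    colnames(cols) <- c(.fp_term_label(var_name, p),
                        paste0(.fp_term_label(var_name, p), "*log(",
                               var_name, ")"))
  } else {
    cols <- vapply(powers, one, numeric(length(x)))
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = length(x))
    colnames(cols) <- vapply(powers, .fp_term_label, "", var = var_name)
  }
  cols
}

#' Least-squares fit with country-clustered standard errors
#'
#' Ordinary least squares of a (logit-scale) outcome on a design matrix,
#' with cluster-robust sandwich standard errors so that subnational regions
#' of one country are treated as a dependence cluster. The variance uses
#' the HC1-type small-sample factor G/(G-1) * (N-1)/(N-k).
#'
#' @param design numeric matrix of predictors (no intercept column; one is
#'   added).
#' @param y numeric outcome vector.
#' @param cluster vector of cluster identifiers, one per row.
#' @return object of class `fp_fit`: coefficients (intercept first),
#'   `robust_se`, `vcov`, `rss`, `r_squared`, `n_obs`, `n_clusters`,
#'   `df_residual`.
#' @export
fit_ols <- function(design, y, cluster) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  n <- length(y)
  k <- ncol(design) + 1L
  if (nrow(design) != n || length(cluster) != n) {
    stop("design, y and cluster must have matching rows")
  }
  if (n < k + 1L) stop("need at least ", k + 1L, " rows to fit ", k,
                       " coefficients")
  cluster <- factor(cluster)
  if (nlevels(cluster) < 2L) stop("need at least 2 clusters")
  df <- data.frame(.y = y, design, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  # a noise-free outcome is a valid input here; silence summary.lm's
  # "essentially perfect fit" nag raised through the sandwich bread
  vc <- withCallingHandlers(
    sandwich::vcovCL(fit, cluster = cluster, type = "HC1", cadjust = TRUE),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", colnames(design))
  dimnames(vc) <- list(names(coefs), names(coefs))
  structure(list(
    coefficients = coefs,
    robust_se = sqrt(diag(vc)),
    vcov = vc,
    rss = rss,
    r_squared = 1 - rss / tss,
    n_obs = n,
    n_clusters = nlevels(cluster),
    df_residual = n - k,
    outcome = NULL, powers = NULL, extras = NULL
  ), class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Fractional-polynomial OLS fit")
  if (!is.null(x$outcome)) {
    cat(" (outcome: DFPS", x$outcome, ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$powers)) {
    cat("  powers: (", paste(x$powers, collapse = ", "), ")",
        if (length(x$extras)) paste0("  extras: ",
                                     paste(x$extras, collapse = ", ")),
        "\n", sep = "")
  }
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$robust_se)
  print(round(tab, 4))
  cat(sprintf("  n = %d regions, %d clusters; RSS = %.4g; R^2 = %.4f\n",
              x$n_obs, x$n_clusters, x$rss, x$r_squared))
  invisible(x)
}

# outcome-relevant columns for estimation rows
.outcome_cols <- function(outcome) {
  if (outcome == "any") list(cpr = "cpr_any", dfps = "dfps_any")
  else list(cpr = "cpr_m", dfps = "dfps_m")
}

.extra_column <- function(data, extra) {
  switch(extra,
    cpdiff = if ("cpdiff" %in% names(data)) data$cpdiff else
      data$cpr_any - data$cpr_m,
    cpr_ratio = data$cpr_any / data$cpr_m,
    tfr = {
      if (!"tfr" %in% names(data)) stop("column 'tfr' not found")
      data$tfr
    },
    stop("unknown extra covariate: ", extra)
  )
}

.fp_design <- function(data, outcome, powers, extras) {
  cols <- .outcome_cols(outcome)
  x <- data[[cols$cpr]]
  X <- fp_transform(x, powers, var_name = cols$cpr)
  for (e in extras) {
    X <- cbind(X, .extra_column(data, e))
    colnames(X)[ncol(X)] <- e
  }
  X
}

#' Fit a DFPS fractional-polynomial model to estimation rows
#'
#' Fits logit(DFPS) on a fractional polynomial of the outcome-relevant
#' prevalence (CPRany for DFPSany, CPRm for DFPSm) plus optional extra
#' covariates, with standard errors clustered on country. The published
#' models use powers (0, 2) -- log and square -- with cpdiff.
#'
#' @param data estimation rows: data frame with `cpr_any`, `cpr_m`,
#'   `dfps_any` and/or `dfps_m` (proportion scale) and a cluster column.
#' @param outcome `"any"` or `"modern"`.
#' @param powers fractional-polynomial powers, length 1 or 2.
#' @param extras extra covariates from `c("cpdiff", "cpr_ratio", "tfr")`.
#' @param cluster name of the cluster (country) column.
#' @return an `fp_fit` (see [fit_ols()]) carrying the model specification.
#' @export
fit_fp <- function(data, outcome = c("any", "modern"), powers = c(0, 2),
                   extras = "cpdiff", cluster = "country_id") {
  outcome <- match.arg(outcome)
  cols <- .outcome_cols(outcome)
  if (!cols$dfps %in% names(data)) {
    stop("column '", cols$dfps, "' not found in estimation rows")
  }
  if (!cluster %in% names(data)) {
    stop("cluster column not found: ", cluster)
  }
  X <- .fp_design(data, outcome, powers, extras)
  y <- logit(data[[cols$dfps]])
  fit <- fit_ols(X, y, data[[cluster]])
  fit$outcome <- outcome
  fit$powers <- sort(powers)
  fit$extras <- extras
  fit
}

#' Predict from a fitted DFPS model
#'
#' @param object an `fp_fit` from [fit_fp()] or [read_model()].
#' @param newdata estimation rows with the model's predictor columns.
#' @param type `"response"` (back-transformed proportion, default) or
#'   `"link"` (logit scale).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fp_fit <- function(object, newdata,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(object$powers)) {
    stop("this fit carries no model specification; use fit_fp()")
  }
  X <- .fp_design(newdata, object$outcome, object$powers, object$extras)
  eta <- drop(cbind(1, X) %*% object$coefficients)
  if (type == "link") eta else inv_logit(eta)
}

#' Exclude rows with prevalence below a threshold
#'
#' Prevalence estimates below 1% are excluded before model fitting to avoid
#' instability of the log term near zero; a 15% threshold reproduces the
#' sensitivity restriction under which the CPR--DFPS relationship is
#' effectively linear.
#'
#' @param data estimation rows.
#' @param outcome `"any"`, `"modern"`, or `"both"` -- which prevalence
#'   column(s) the threshold applies to.
#' @param threshold exclusion threshold on the proportion scale
#'   (default 0.01).
#' @return the filtered rows; the removals are recorded in
#'   `attr(, "exclusion_log")` (row index, prevalence, reason).
#' @export
apply_exclusion <- function(data, outcome = c("any", "modern", "both"),
                            threshold = 0.01) {
  outcome <- match.arg(outcome)
  cols <- switch(outcome, any = "cpr_any", modern = "cpr_m",
                 both = c("cpr_any", "cpr_m"))
  drop <- rep(FALSE, nrow(data))
  log_rows <- list()
  for (cc in cols) {
    hit <- !is.na(data[[cc]]) & data[[cc]] < threshold
    if (any(hit)) {
      log_rows[[cc]] <- data.frame(
        row = which(hit), column = cc, value = data[[cc]][hit],
        reason = sprintf("%s below threshold %g", cc, threshold))
    }
    drop <- drop | hit
  }
  out <- data[!drop, , drop = FALSE]
  log_df <- if (length(log_rows)) do.call(rbind, c(log_rows,
                                                   make.row.names = FALSE))
  else data.frame(row = integer(), column = character(),
                  value = numeric(), reason = character())
  attr(out, "exclusion_log") <- log_df
  out
}

# all multisets of size 1 and 2 from the standard power set
.fp_power_sets <- function() {
  pw <- fp_powers()
  sets <- lapply(pw, function(p) p)
  for (i in seq_along(pw)) {
    for (j in i:length(pw)) {
      sets[[length(sets) + 1L]] <- c(pw[i], pw[j])
    }
  }
  sets
}

.subsets <- function(x) {
  if (!length(x)) return(list(character()))
  out <- list(character())
  for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
  out
}

#' Search fractional-polynomial specifications
#'
#' Fits every fractional-polynomial multiset of size 1 and 2 from the
#' standard power set, crossed with every subset of the candidate extra
#' covariates, and ranks the fits by residual sum of squares (ties broken
#' toward fewer parameters, then lexicographically lower powers).
#'
#' @inheritParams fit_fp
#' @param extras_candidates extra covariates to try including
#'   (default `"cpdiff"`); every subset of this vector is crossed with
#'   every power set.
#' @return object of class `fp_search`: `$results` is a data frame (one
#'   row per candidate, ranked best first), `$fits` the corresponding
#'   `fp_fit` objects, `$best` the top fit.
#' @export
fp_search <- function(data, outcome = c("any", "modern"),
                      extras_candidates = "cpdiff",
                      cluster = "country_id") {
  outcome <- match.arg(outcome)
  data <- apply_exclusion(data, outcome = outcome, threshold = 0.01)
  power_sets <- .fp_power_sets()
  extra_sets <- .subsets(extras_candidates)
  fits <- list()
  rows <- list()
  for (ps in power_sets) {
    for (es in extra_sets) {
      fit <- tryCatch(
        fit_fp(data, outcome, powers = ps, extras = es, cluster = cluster),
        error = function(e) NULL)
      if (is.null(fit)) next
      fits[[length(fits) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        powers = paste(sort(ps), collapse = ","),
        extras = paste(es, collapse = ","),
        n_params = length(fit$coefficients),
        rss = fit$rss, r_squared = fit$r_squared,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(fits)) {
    stop("no candidate specification could be fitted (singular designs)")
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$rss, tab$n_params, tab$powers)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  fits <- fits[ord]
  structure(list(results = tab, fits = fits, best = fits[[1]],
                 outcome = outcome),
            class = "fp_search")
}

#' @export
print.fp_search <- function(x, ...) {
  cat("Fractional-polynomial model search (outcome: DFPS", x$outcome,
      "), ", nrow(x$results), " candidates\n", sep = "")
  print(utils::head(x$results, 5))
  cat("Best fit:\n")
  print(x$best)
  invisible(x)
}

#' Compare the straight-line model with the best fractional polynomial
#'
#' Under a restriction to prevalences of 15% or more the CPR--DFPS
#' relationship is close to linear on the logit scale; this comparison
#' fits the straight line and the best degree-2 fractional polynomial of
#' the prevalence (no extra covariates) and tests the fractional
#' polynomial's added flexibility with the conventional 3-df F test
#' (two extra parameters plus the power-pair selection).
#'
#' @inheritParams fit_fp
#' @return list of class `linear_fp_comparison`: the two fits, their rss
#'   and R^2, and the F statistic, degrees of freedom and p-value.
#' @export
compare_linear_fp <- function(data, outcome = c("any", "modern"),
                              cluster = "country_id") {
  outcome <- match.arg(outcome)
  linear <- fit_fp(data, outcome, powers = 1, extras = character(),
                   cluster = cluster)
  search <- fp_search(data, outcome, extras_candidates = character(),
                      cluster = cluster)
  # best among degree-2 candidates (the straight line is nested in them)
  deg2 <- which(vapply(search$fits,
                       function(f) length(f$powers) == 2L, logical(1)))
  best <- search$fits[[deg2[1]]]
  df1 <- 3
  df2 <- best$df_residual
  f_stat <- max(0, (linear$rss - best$rss) / df1 / (best$rss / df2))
  structure(list(
    linear = linear, fp = best,
    rss_linear = linear$rss, rss_fp = best$rss,
    r2_linear = linear$r_squared, r2_fp = best$r_squared,
    f_statistic = f_stat, df1 = df1, df2 = df2,
    p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  ), class = "linear_fp_comparison")
}

#' @export
print.linear_fp_comparison <- function(x, ...) {
  cat("Linear vs fractional-polynomial comparison\n")
  cat(sprintf("  linear: rss = %.4g, R^2 = %.4f\n", x$rss_linear,
              x$r2_linear))
  cat(sprintf("  best FP (powers %s): rss = %.4g, R^2 = %.4f\n",
              paste(x$fp$powers, collapse = ", "), x$rss_fp, x$r2_fp))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4f\n", x$df1, x$df2,
              x$f_statistic, x$p_value))
  invisible(x)
}
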
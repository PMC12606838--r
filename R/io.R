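.model_schema_version <- "1.0"

#' Read a region/stratum-level estimation table
#'
#' Reads a comma-separated table of prevalence (and optionally observed
#' DFPS) estimates. Column names can be remapped via `mapping`. Because
#' published tables mix percent and proportion scales, each numeric column
#' is auto-detected: if any value exceeds 1 the whole column is divided by
#' 100 and a notice is emitted.
#'
#' @param path path to a CSV file with a header row.
#' @param mapping optional named character vector mapping package column
#'   names to the file's column names, e.g.
#'   `c(cpr_any = "CPR_total", cpr_m = "CPR_modern")`.
#' @return data frame of estimation rows on the proportion scale, with
#'   `cpdiff` computed if absent. A header-only file yields zero rows with
#'   a warning.
#' @export
read_estimation_rows <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (target in names(mapping)) {
      src <- mapping[[target]]
      if (!src %in% names(df)) {
        stop("mapped column not found in file: ", src)
      }
      names(df)[names(df) == src] <- target
    }
  }
  if (!"cpr_any" %in% names(df) && !"cpr_m" %in% names(df)) {
    stop("missing mandatory column: cpr_any or cpr_m ",
         "(use `mapping` to point at your column names)")
  }
  if (nrow(df) == 0) {
    warning("header-only file: no estimation rows in ", path)
    return(df)
  }
  prop_cols <- intersect(
    c("cpr_any", "cpr_m", "cpdiff", "dfps_any", "dfps_m"), names(df))
  for (cc in prop_cols) {
    x <- df[[cc]]
    if (!is.numeric(x)) {
      xs <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xs) & !is.na(x) & x != "")
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "', row ", bad[1],
             ": '", x[bad[1]], "'")
      }
      x <- xs
    }
    if (any(x > 1, na.rm = TRUE)) {
      message("column '", cc,
              "' looks like percentages; dividing by 100")
      x <- x / 100
    }
    df[[cc]] <- x
  }
  if (!"cpdiff" %in% names(df) &&
      all(c("cpr_any", "cpr_m") %in% names(df))) {
    df$cpdiff <- df$cpr_any - df$cpr_m
  }
  df
}

#' Write a table of estimates or predictions as CSV
#'
#' Plain comma-separated output with a header row; readers in this package
#' accept their own output.
#'
#' @param x data frame (e.g. from [estimate_indicator()] or
#'   [predict_batch()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON and back
#'
#' A round-trip through `write_model()` / `read_model()` preserves the
#' model specification, coefficients, robust standard errors and fit
#' summaries; the reloaded object predicts identically to the original.
#' Unknown fields in the file are ignored with a warning; a missing or
#' different schema version is an error.
#'
#' @param fit an `fp_fit` from [fit_fp()].
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns an `fp_fit`.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "fp_fit"))
  payload <- list(
    schema_version = .model_schema_version,
    outcome = fit$outcome,
    powers = fit$powers,
    extras = fit$extras,
    coefficients = as.list(fit$coefficients),
    robust_se = as.list(stats::setNames(fit$robust_se,
                                        names(fit$coefficients))),
    rss = fit$rss, r_squared = fit$r_squared,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    df_residual = fit$df_residual
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema_version", "outcome", "powers", "extras",
             "coefficients", "robust_se", "rss", "r_squared", "n_obs",
             "n_clusters", "df_residual")
  extra <- setdiff(names(payload), known)
  if (length(extra)) {
    warning("ignoring unknown field(s) in model file: ",
            paste(extra, collapse = ", "))
  }
  if (is.null(payload$schema_version) ||
      !identical(payload$schema_version, .model_schema_version)) {
    stop("model file schema version mismatch: expected ",
         .model_schema_version, ", got ",
         if (is.null(payload$schema_version)) "none" else
           payload$schema_version)
  }
  structure(list(
    coefficients = unlist(payload$coefficients),
    robust_se = unname(unlist(payload$robust_se)),
    vcov = NULL,
    rss = payload$rss, r_squared = payload$r_squared,
    n_obs = payload$n_obs, n_clusters = payload$n_clusters,
    df_residual = payload$df_residual,
    outcome = payload$outcome,
    powers = as.numeric(payload$powers),
    extras = as.character(unlist(payload$extras))
  ), class = "fp_fit")
}

#' Export figure-style prediction-surface data
#'
#' Computes the 10th percentile, mean and 90th percentile of cpdiff in an
#' observed estimation table and exports the predicted DFPS surface at
#' those three levels across a prevalence grid -- the data behind the
#' predicted-DFPS-versus-CPR figures.
#'
#' @param rows estimation rows (data frame or CSV path; a path goes
#'   through [read_estimation_rows()]).
#' @inheritParams prediction_surface
#' @return long-format data frame: `cpr`, `cpdiff`, `cpdiff_level`
#'   (`"p10"`, `"mean"`, `"p90"`), `dfps_pred`, `outcome`.
#' @export
export_surface_data <- function(rows, outcome = c("any", "modern"),
                                cpr_grid = seq(0.01, 0.99, by = 0.01),
                                coeffs = NULL) {
  outcome <- match.arg(outcome)
  if (is.character(rows)) rows <- read_estimation_rows(rows)
  if (!"cpdiff" %in% names(rows)) {
    if (!all(c("cpr_any", "cpr_m") %in% names(rows))) {
      stop("estimation rows must carry cpdiff (or cpr_any and cpr_m)")
    }
    rows$cpdiff <- rows$cpr_any - rows$cpr_m
  }
  if (nrow(rows) < 10) {
    warning("fewer than 10 rows: cpdiff percentiles will be unstable")
  }
  cd <- rows$cpdiff
  levels_ <- c(p10 = unname(stats::quantile(cd, 0.10)),
               mean = mean(cd),
               p90 = unname(stats::quantile(cd, 0.90)))
  surf <- prediction_surface(outcome, cpdiff_levels = unname(levels_),
                             cpr_grid = cpr_grid, coeffs = coeffs)
  surf$cpdiff_level <- rep(names(levels_), each = length(cpr_grid))
  surf[, c("cpr", "cpdiff", "cpdiff_level", "dfps_pred", "outcome")]
}
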
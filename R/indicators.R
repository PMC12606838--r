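#' @keywords internal
"_PACKAGE"

# Column helper: return the column if present, else a default-filled vector.
# Missing answers never drop a record; they count as condition-not-met.
.col <- function(women, name, default, n = nrow(women)) {
  if (name %in% names(women)) {
    x <- women[[name]]
    x
  } else {
    rep(default, n)
  }
}

.false_if_na <- function(x) {
  x[is.na(x)] <- FALSE
  as.logical(x)
}

#' Classify women as infecund
#'
#' A woman is classified infecund if any of five conditions holds:
#' (i) she has never menstruated; (ii) she is menopausal; (iii) she has no
#' child under five and her last menstrual period was more than six months
#' ago; (iv) she has been married five or more years without a birth while
#' not using contraception; (v) she declares herself unable to conceive.
#' Missing answers count as condition-not-met, so no record is ever dropped
#' for item nonresponse.
#'
#' @param women data frame of woman-level records (see
#'   [woman_record_columns()]).
#' @return logical vector, `TRUE` for infecund women.
#' @export
classify_infecund <- function(women) {
  n <- nrow(women)
  never_m <- .false_if_na(.col(women, "never_menstruated", FALSE, n))
  meno <- .false_if_na(.col(women, "menopausal", FALSE, n))
  under5 <- .col(women, "has_under5_child", NA, n)
  mslp <- .col(women, "months_since_last_period", NA_real_, n)
  # (iii) requires an affirmative "no under-five child" and a reported gap
  no_recent <- .false_if_na(!is.na(under5) & !under5 & !is.na(mslp) & mslp > 6)
  married5 <- .false_if_na(
    .col(women, "years_married_no_birth_no_contraception_5y", FALSE, n))
  selfdecl <- .false_if_na(.col(women, "self_declared_infecund", FALSE, n))
  never_m | meno | no_recent | married5 | selfdecl
}

#' Classify women as in need of contraception
#'
#' Need for contraception (or for family planning) combines three routes:
#' \describe{
#'   \item{users}{every current contraceptive user is in need -- demand
#'     satisfied is the share of women in need who use a method, so the
#'     numerator must be a subset of the denominator;}
#'   \item{fecund non-users}{women who are neither pregnant nor postpartum
#'     amenorrheic (within the configured window), are fecund, and want no
#'     child in the next two years or want to delay two or more years;}
#'   \item{pregnant/amenorrheic non-users}{women currently pregnant or
#'     postpartum amenorrheic whose pregnancy was mistimed (`"later"`) or
#'     unwanted (`"not_at_all"`).}
#' }
#' Missing intention answers count as not-in-need rather than dropping the
#' record.
#'
#' @inheritParams classify_infecund
#' @param taxonomy a [method_taxonomy()] used to identify users.
#' @param amenorrhea_window_months postpartum amenorrhea is honoured only
#'   within this many months since the last birth (default 24, the revised
#'   shortened window); beyond it a non-menstruating woman is assessed under
#'   the fecund non-user rule.
#' @param undecided_in_need should non-users whose two-year intention is
#'   `"undecided"` count as in need? Default `FALSE`.
#' @return logical vector, `TRUE` for women in need of contraception.
#' @export
classify_need <- function(women, taxonomy = default_method_taxonomy(),
                          amenorrhea_window_months = 24,
                          undecided_in_need = FALSE) {
  n <- nrow(women)
  use <- classify_method(.col(women, "method_code", "none", n), taxonomy)
  user <- use != "none"

  pregnant <- .false_if_na(.col(women, "pregnant", FALSE, n))
  ppa <- .false_if_na(.col(women, "postpartum_amenorrheic", FALSE, n))
  mslb <- .col(women, "months_since_last_birth", NA_real_, n)
  # amenorrhea is honoured only within the window; an unreported birth date
  # leaves the answer as given
  ppa_active <- ppa & (is.na(mslb) | mslb <= amenorrhea_window_months)

  infecund <- classify_infecund(women)
  wants <- as.character(.col(women, "wants_child_within_2y", NA_character_, n))
  avoid_levels <- c("no", "delay_2y_plus")
  if (undecided_in_need) avoid_levels <- c(avoid_levels, "undecided")
  wants_avoid <- !is.na(wants) & wants %in% avoid_levels

  lastw <- as.character(.col(women, "last_pregnancy_wanted", NA_character_, n))
  preg_unintended <- !is.na(lastw) & lastw %in% c("later", "not_at_all")

  fecund_need <- !pregnant & !ppa_active & !infecund & wants_avoid
  preg_need <- (pregnant | ppa_active) & preg_unintended

  user | fecund_need | preg_need
}

#' Woman-level record columns
#'
#' Documents the column dictionary expected by the indicator functions. All
#' classification fields are missing-tolerant: an absent column or an `NA`
#' counts as condition-not-met.
#'
#' @return named character vector mapping column names to short
#'   descriptions.
#' @export
woman_record_columns <- function() {
  c(age = "age in years, 15-49",
    partnered = "married or in union (logical)",
    method_code = "current contraceptive method code, or 'none'",
    pregnant = "currently pregnant (logical)",
    postpartum_amenorrheic = "menses not returned since last birth (logical)",
    months_since_last_birth = "months since last birth (integer or NA)",
    last_pregnancy_wanted = "'then', 'later' or 'not_at_all' (or NA)",
    wants_child_within_2y = "'yes', 'no', 'delay_2y_plus' or 'undecided'",
    never_menstruated = "never menstruated (logical)",
    menopausal = "menopausal (logical)",
    months_since_last_period = "months since last period (integer or NA)",
    has_under5_child = "has a living child under five (logical)",
    years_married_no_birth_no_contraception_5y =
      "married 5+ years, no birth, no contraception (logical)",
    self_declared_infecund = "declares herself unable to conceive (logical)",
    weight = "positive sampling weight",
    cluster_id = "primary sampling unit identifier",
    country_id = "country identifier",
    region_id = "subnational region identifier",
    residence = "'urban' or 'rural'",
    wealth_quintile = "household wealth quintile 1-5",
    education = "woman's education category")
}

.indicator_names <- c("CPRany", "CPRm", "DFPSany", "DFPSm")

#' Survey-weighted family planning indicator estimates
#'
#' Computes weighted point estimates of contraceptive prevalence (CPRany,
#' CPRm) and demand for family planning satisfied (DFPSany, DFPSm) for
#' arbitrary population strata. All four indicators share a numerator --
#' the weighted count of partnered women 15--49 using (any or modern)
#' contraception. CPR divides by all partnered women 15--49; DFPS restricts
#' the denominator to women in need of contraception.
#'
#' The analysis population is partnered women aged 15--49; other rows are
#' dropped before estimation. A stratum whose denominator weight is zero is
#' returned with `value = NA` rather than 0/0.
#'
#' @inheritParams classify_need
#' @param indicator character vector from `c("CPRany", "CPRm", "DFPSany",
#'   "DFPSm")`; estimates are returned for each.
#' @param stratify_by name of a column in `women` defining strata, or `NULL`
#'   for a single national estimate.
#' @param ... passed on to [classify_need()] (amenorrhea window, undecided
#'   switch).
#' @return data frame with one row per indicator x stratum: `indicator`,
#'   `dimension`, `stratum`, `value`, `numerator_weight`,
#'   `denominator_weight`, `n_unweighted`.
#' @examples
#' w <- data.frame(
#'   age = c(30, 25, 40, 35), partnered = TRUE,
#'   method_code = c("pill", "iud", "withdrawal", "none"),
#'   wants_child_within_2y = c(NA, NA, NA, "no"),
#'   weight = 1
#' )
#' estimate_indicator(w, c("CPRany", "CPRm", "DFPSany", "DFPSm"))
#' @export
estimate_indicator <- function(women, indicator = .indicator_names,
                               stratify_by = NULL,
                               taxonomy = default_method_taxonomy(), ...) {
  indicator <- match.arg(indicator, .indicator_names, several.ok = TRUE)
  n <- nrow(women)
  if (!"weight" %in% names(women)) {
    stop("women table must have a 'weight' column")
  }
  if (any(is.na(women$weight)) || any(women$weight <= 0)) {
    stop("sampling weights must be positive and non-missing")
  }
  age <- .col(women, "age", NA_real_, n)
  partnered <- .false_if_na(.col(women, "partnered", TRUE, n))
  keep <- partnered & !is.na(age) & age >= 15 & age <= 49
  women <- women[keep, , drop = FALSE]
  if (nrow(women) == 0) {
    stop("no partnered women aged 15-49 in the input")
  }

  use <- classify_method(.col(women, "method_code", "none", nrow(women)),
                         taxonomy)
  in_need <- classify_need(women, taxonomy, ...)
  wt <- women$weight

  if (is.null(stratify_by)) {
    strat <- rep("national", nrow(women))
    dimension <- "national"
  } else {
    if (!stratify_by %in% names(women)) {
      stop("stratification column not found: ", stratify_by)
    }
    strat <- as.character(women[[stratify_by]])
    dimension <- stratify_by
  }

  out <- list()
  for (ind in indicator) {
    num_flag <- if (ind %in% c("CPRm", "DFPSm")) use == "modern" else
      use != "none"
    den_flag <- if (ind %in% c("DFPSany", "DFPSm")) in_need else
      rep(TRUE, nrow(women))
    num_w <- tapply(wt * num_flag, strat, sum)
    den_w <- tapply(wt * den_flag, strat, sum)
    n_unw <- tapply(den_flag, strat, sum)
    levels_ <- names(num_w)
    value <- ifelse(den_w > 0, num_w / den_w, NA_real_)
    if (any(den_w == 0)) {
      warning("zero denominator weight in stratum ",
              paste(levels_[den_w == 0], collapse = ", "),
              " for ", ind, "; estimate set to NA")
    }
    out[[ind]] <- data.frame(
      indicator = ind, dimension = dimension, stratum = levels_,
      value = as.numeric(value),
      numerator_weight = as.numeric(num_w),
      denominator_weight = as.numeric(den_w),
      n_unweighted = as.integer(n_unw),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
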
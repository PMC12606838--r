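#' Configuration for the synthetic region-table generator
#'
#' The generator emulates the structure the regression models assume: a
#' pool of subnational regions nested in countries, each carrying the four
#' family planning indicators, with DFPS generated from the published
#' equations plus country-level and region-level Gaussian perturbations on
#' the logit scale.
#'
#' Defaults reproduce the observed marginals of the real pool: 103
#' countries, 1,099 regions in total, CPRany drawn from a scaled Beta on
#' \[0.015, 0.848\] matched to the observed mean (41.8%) and 10th/50th/90th
#' percentiles, and cpdiff from a scaled Beta on \[0, 0.639\] matched to
#' the observed mean (6.7 p.p.) and percentiles. cpdiff is truncated at
#' CPRany − 0.012 so that generated CPRm never falls below the observed
#' minimum of 1.2%.
#'
#' @param n_countries number of countries.
#' @param n_regions total number of regions, allocated as evenly as
#'   possible across countries (the remainder goes one-per-country).
#' @param cpr_any_range,cpr_any_shape support and Beta shape of the CPRany
#'   distribution.
#' @param cpdiff_max,cpdiff_shape upper bound and Beta shape of the cpdiff
#'   distribution.
#' @param logit_noise_sd region-level Gaussian noise sd, logit scale.
#' @param country_effect_sd sd of the shared country-level intercept
#'   perturbation, logit scale.
#' @param truth_any,truth_modern [dfps_coefficients()] used as the
#'   generating equations.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_countries = 103, n_regions = 1099,
                             cpr_any_range = c(0.015, 0.848),
                             cpr_any_shape = c(1.45, 1.54),
                             cpdiff_max = 0.639,
                             cpdiff_shape = c(0.68, 6.04),
                             logit_noise_sd = 0.05,
                             country_effect_sd = 0.05,
                             truth_any = dfps_coefficients("any"),
                             truth_modern = dfps_coefficients("modern")) {
  stopifnot(n_countries >= 1, n_regions >= n_countries,
            length(cpr_any_range) == 2,
            cpr_any_range[1] > 0, cpr_any_range[2] <= 1,
            cpr_any_range[1] < cpr_any_range[2],
            cpdiff_max >= 0, cpdiff_max < 1,
            all(cpr_any_shape > 0), all(cpdiff_shape > 0),
            logit_noise_sd >= 0, country_effect_sd >= 0)
  structure(list(
    n_countries = n_countries, n_regions = n_regions,
    cpr_any_range = cpr_any_range, cpr_any_shape = cpr_any_shape,
    cpdiff_max = cpdiff_max, cpdiff_shape = cpdiff_shape,
    logit_noise_sd = logit_noise_sd, country_effect_sd = country_effect_sd,
    truth_any = truth_any, truth_modern = truth_modern
  ), class = "generator_config")
}

#' Generate a synthetic region-level estimation table
#'
#' Draws CPRany and cpdiff per region, computes the noise-free DFPSany and
#' DFPSm from the generating equations, and adds a country-shared intercept
#' perturbation plus independent region-level noise on the logit scale.
#' With both noise sds at zero the observed DFPS equals the predictor
#' output exactly.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return list with `rows` (observed estimation rows: `country_id`,
#'   `region_id`, `cpr_any`, `cpr_m`, `cpdiff`, `dfps_any`, `dfps_m`) and
#'   `truth` (the same rows with noise-free DFPS).
#' @export
gen_region_rows <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(seed, {
    nc <- config$n_countries
    nr <- config$n_regions
    per <- rep(nr %/% nc, nc)
    extra <- nr %% nc
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    country <- rep(sprintf("C%03d", seq_len(nc)), times = per)
    region <- unlist(lapply(per, function(m) sprintf("R%02d", seq_len(m))))
    region <- paste(country, region, sep = "_")

    rng <- config$cpr_any_range
    cpr_any <- rng[1] + diff(rng) *
      stats::rbeta(nr, config$cpr_any_shape[1], config$cpr_any_shape[2])
    cpdiff <- config$cpdiff_max *
      stats::rbeta(nr, config$cpdiff_shape[1], config$cpdiff_shape[2])
    # keep generated CPRm at or above the observed minimum of 1.2%
    cpdiff <- pmin(cpdiff, pmax(cpr_any - 0.012, 0))
    cpr_m <- cpr_any - cpdiff

    mu_any <- .dfps_link(cpr_any, cpdiff, config$truth_any)
    mu_m <- .dfps_link(cpr_m, cpdiff, config$truth_modern)

    u_any <- rep(stats::rnorm(nc, 0, config$country_effect_sd), times = per)
    u_m <- rep(stats::rnorm(nc, 0, config$country_effect_sd), times = per)
    e_any <- stats::rnorm(nr, 0, config$logit_noise_sd)
    e_m <- stats::rnorm(nr, 0, config$logit_noise_sd)

    base <- data.frame(country_id = country, region_id = region,
                       cpr_any = cpr_any, cpr_m = cpr_m, cpdiff = cpdiff,
                       stringsAsFactors = FALSE)
    rows <- base
    rows$dfps_any <- inv_logit(mu_any + u_any + e_any)
    rows$dfps_m <- inv_logit(mu_m + u_m + e_m)
    truth <- base
    truth$dfps_any <- inv_logit(mu_any)
    truth$dfps_m <- inv_logit(mu_m)
    list(rows = rows, truth = truth)
  })
}

# check the four targets are mutually consistent; DFPS shares the CPR
# numerator, so dfps_m is implied: dfps_m = cpr_m * dfps_any / cpr_any
.check_targets <- function(t) {
  need <- c("cpr_any", "cpr_m", "dfps_any", "dfps_m")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("targets missing: ", paste(miss, collapse = ", "))
  with(t, {
    if (any(unlist(t[need]) < 0) || any(unlist(t[need]) > 1)) {
      stop("targets must be proportions in [0, 1]")
    }
    if (cpr_m > cpr_any + 1e-9) stop("infeasible targets: CPRm > CPRany")
    if (dfps_m > dfps_any + 1e-9) {
      stop("infeasible targets: DFPSm > DFPSany")
    }
    if (cpr_any > dfps_any + 1e-9) {
      stop("infeasible targets: CPRany > DFPSany ",
           "(users are a subset of women in need)")
    }
    if (dfps_any <= 0 || cpr_any <= 0) {
      stop("targets require cpr_any > 0 and dfps_any > 0")
    }
    implied <- cpr_m * dfps_any / cpr_any
    if (abs(implied - dfps_m) > 1e-6) {
      stop(sprintf(
        paste0("inconsistent targets: the shared numerator implies ",
               "DFPSm = CPRm*DFPSany/CPRany = %.4f, got %.4f"),
        implied, dfps_m))
    }
  })
  invisible(TRUE)
}

#' Generate woman-level microdata matching target indicators
#'
#' Samples `n_women` partnered women aged 15--49 into use/need categories
#' with probabilities solved from the four target indicators, then fills
#' in the questionnaire fields (method, pregnancy, intentions, fecundity)
#' so that running [estimate_indicator()] on the output recovers each
#' target within binomial sampling error. Because all four indicators
#' share one numerator, the targets are over-determined; inconsistent
#' quadruples raise an error naming the violated relation.
#'
#' Category shares among all women: modern user = CPRm; traditional user =
#' CPRany − CPRm; non-user in need = CPRany/DFPSany − CPRany (a mix of
#' fecund women wanting to avoid/delay and mistimed pregnancies); the
#' remainder is not in need (wanted pregnancies, infecund women, women
#' wanting a child soon). Sampling weights default to a constant 1 so that
#' the recovery error of the weighted estimator is plain binomial;
#' heterogeneous weights (independent of category) can be requested via
#' `weight_range`.
#'
#' @param targets named list or one-row data frame with `cpr_any`,
#'   `cpr_m`, `dfps_any`, `dfps_m` (proportion scale); optionally
#'   `country_id`, `region_id`, `stratum`.
#' @param n_women number of records to generate.
#' @param seed integer seed.
#' @param taxonomy a [method_taxonomy()] supplying method codes.
#' @param weight_range range of the uniform sampling-weight distribution;
#'   the default `c(1, 1)` gives equal weights.
#' @return data frame of woman-level records (see
#'   [woman_record_columns()]).
#' @export
gen_microdata <- function(targets, n_women = 10000, seed = 1,
                          taxonomy = default_method_taxonomy(),
                          weight_range = c(1, 1)) {
  targets <- as.list(targets)
  .check_targets(targets)
  need_share <- targets$cpr_any / targets$dfps_any
  p <- c(modern = targets$cpr_m,
         traditional = targets$cpr_any - targets$cpr_m,
         need_nonuser = need_share - targets$cpr_any,
         not_in_need = 1 - need_share)
  p <- pmax(p, 0)  # guard tiny negative rounding
  withr::with_seed(seed, {
    cat_ <- sample(names(p), n_women, replace = TRUE, prob = p)
    n <- n_women
    w <- data.frame(
      age = sample(15:49, n, replace = TRUE),
      partnered = TRUE,
      method_code = "none",
      pregnant = FALSE,
      postpartum_amenorrheic = FALSE,
      months_since_last_birth = NA_integer_,
      last_pregnancy_wanted = NA_character_,
      wants_child_within_2y = NA_character_,
      never_menstruated = FALSE,
      menopausal = FALSE,
      months_since_last_period = sample(0:3, n, replace = TRUE),
      has_under5_child = sample(c(TRUE, FALSE), n, replace = TRUE),
      years_married_no_birth_no_contraception_5y = FALSE,
      self_declared_infecund = FALSE,
      weight = stats::runif(n, weight_range[1], weight_range[2]),
      cluster_id = sample(sprintf("PSU%03d", seq_len(max(1, n %/% 20))),
                          n, replace = TRUE),
      country_id = if (is.null(targets$country_id)) "C001" else
        targets$country_id,
      region_id = if (is.null(targets$region_id)) "C001_R01" else
        targets$region_id,
      residence = sample(c("urban", "rural"), n, replace = TRUE),
      wealth_quintile = sample(1:5, n, replace = TRUE),
      education = sample(c("none", "primary", "secondary", "higher"),
                         n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    is_mod <- cat_ == "modern"
    is_trad <- cat_ == "traditional"
    if (any(is_mod)) {
      w$method_code[is_mod] <- sample(taxonomy$modern, sum(is_mod),
                                      replace = TRUE)
    }
    if (any(is_trad)) {
      w$method_code[is_trad] <- sample(taxonomy$traditional, sum(is_trad),
                                       replace = TRUE)
    }
    # non-users in need: mostly fecund avoiders, some mistimed pregnancies
    nn <- which(cat_ == "need_nonuser")
    if (length(nn)) {
      preg <- stats::runif(length(nn)) < 0.25
      w$pregnant[nn[preg]] <- TRUE
      w$last_pregnancy_wanted[nn[preg]] <-
        sample(c("later", "not_at_all"), sum(preg), replace = TRUE)
      w$wants_child_within_2y[nn[!preg]] <-
        sample(c("no", "delay_2y_plus"), sum(!preg), replace = TRUE)
    }
    # not in need: wanted pregnancy / infecund / wants a child soon
    out <- which(cat_ == "not_in_need")
    if (length(out)) {
      kind <- sample(c("preg_wanted", "infecund", "wants_soon"),
                     length(out), replace = TRUE)
      pw <- out[kind == "preg_wanted"]
      w$pregnant[pw] <- TRUE
      w$last_pregnancy_wanted[pw] <- "then"
      inf <- out[kind == "infecund"]
      w$menopausal[inf] <- TRUE
      w$wants_child_within_2y[inf] <- "no"
      ws <- out[kind == "wants_soon"]
      w$wants_child_within_2y[ws] <- "yes"
    }
    w
  })
}
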
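test_that("method classification follows the taxonomy", {
  tax <- default_method_taxonomy()
  expect_equal(classify_method("iud", tax), "modern")
  expect_equal(classify_method("none", tax), "none")
  expect_equal(classify_method("withdrawal", tax), "traditional")
  # LAM is absent from the modern-method list, so it defaults traditional
  expect_equal(classify_method("lam", tax), "traditional")
  expect_equal(classify_method(c("pill", NA, "rhythm"), tax),
               c("modern", "none", "traditional"))
  expect_error(classify_method("magic_bean", tax), "magic_bean")
})

test_that("taxonomy construction rejects overlapping or reserved codes", {
  expect_error(method_taxonomy(c("pill", "x"), c("x")), "both")
  expect_error(method_taxonomy("none", "withdrawal"), "none")
  custom <- method_taxonomy("pill", "lam")
  expect_equal(classify_method("lam", custom), "traditional")
})

test_that("infecundity rules: any of the five conditions suffices", {
  base <- data.frame(
    never_menstruated = FALSE, menopausal = FALSE,
    has_under5_child = TRUE, months_since_last_period = 2,
    years_married_no_birth_no_contraception_5y = FALSE,
    self_declared_infecund = FALSE
  )
  expect_false(classify_infecund(base))
  cases <- list(
    list(menopausal = TRUE),
    list(never_menstruated = TRUE),
    list(has_under5_child = FALSE, months_since_last_period = 7),
    list(years_married_no_birth_no_contraception_5y = TRUE),
    list(self_declared_infecund = TRUE)
  )
  for (ch in cases) {
    w <- base
    for (nm in names(ch)) w[[nm]] <- ch[[nm]]
    expect_true(classify_infecund(w))
  }
  # six months ago exactly is not "more than six months"
  w <- base; w$has_under5_child <- FALSE; w$months_since_last_period <- 6
  expect_false(classify_infecund(w))
})

test_that("missing fecundity answers count as condition-not-met", {
  w <- data.frame(age = 30, partnered = TRUE, method_code = "none",
                  weight = 1)
  expect_false(classify_infecund(w))
  w2 <- data.frame(menopausal = NA, months_since_last_period = NA,
                   has_under5_child = NA)
  expect_false(classify_infecund(w2))
})

test_that("need classification: users, fecund avoiders, unintended pregnancies", {
  # fecund non-user who wants no child within two years
  w <- data.frame(method_code = "none", pregnant = FALSE,
                  wants_child_within_2y = "no")
  expect_true(classify_need(w))
  # wanted pregnancy is not unmet need
  w <- data.frame(method_code = "none", pregnant = TRUE,
                  last_pregnancy_wanted = "then")
  expect_false(classify_need(w))
  # users are in need by construction, whatever their fecundity
  w <- data.frame(method_code = "condom", menopausal = TRUE)
  expect_true(classify_need(w))
  # mistimed pregnancy is in need
  w <- data.frame(method_code = "none", pregnant = TRUE,
                  last_pregnancy_wanted = "later")
  expect_true(classify_need(w))
  # infecund women are not in need even if they want to avoid
  w <- data.frame(method_code = "none", menopausal = TRUE,
                  wants_child_within_2y = "no")
  expect_false(classify_need(w))
  # missing intention answers leave a non-user out of need
  w <- data.frame(method_code = "none")
  expect_false(classify_need(w))
})

test_that("undecided intention and the amenorrhea window are configurable", {
  w <- data.frame(method_code = "none", pregnant = FALSE,
                  wants_child_within_2y = "undecided")
  expect_false(classify_need(w))
  expect_true(classify_need(w, undecided_in_need = TRUE))

  # amenorrheic with a mistimed birth: in need within the window only via
  # the pregnancy route; past the window she is assessed as fecund
  w <- data.frame(method_code = "none", postpartum_amenorrheic = TRUE,
                  months_since_last_birth = 10,
                  last_pregnancy_wanted = "later")
  expect_true(classify_need(w))
  w$months_since_last_birth <- 30
  expect_false(classify_need(w))            # outside window, no intention
  w$wants_child_within_2y <- "no"
  expect_true(classify_need(w))             # outside window, fecund route
  # wanted birth: inside a widened window neither route applies
  w$last_pregnancy_wanted <- "then"
  expect_true(classify_need(w))
  expect_false(classify_need(w, amenorrhea_window_months = 36))
})

test_that("weighted indicator estimates match hand counts", {
  est <- estimate_indicator(four_women())
  val <- function(ind) est$value[est$indicator == ind]
  expect_equal(val("CPRm"), 0.50)
  expect_equal(val("CPRany"), 0.75)
  expect_equal(val("DFPSany"), 0.75)
  expect_equal(val("DFPSm"), 0.50)
  expect_equal(unique(est$n_unweighted[est$indicator %in%
                                         c("CPRany", "CPRm")]), 4L)

  # weights (2,1,1,1), users are the first two (modern, traditional):
  # weighted CPRany = (2 + 1) / 5 = 0.60
  w2 <- four_women(weights = c(2, 1, 1, 1))
  w2$method_code <- c("pill", "withdrawal", "none", "none")
  w2$wants_child_within_2y <- c(NA, NA, "no", "no")
  est_w <- estimate_indicator(w2, indicator = "CPRany")
  expect_equal(est_w$value, 0.60)
})

test_that("estimates are invariant to rescaling all weights", {
  w <- gen_microdata(random_targets(11), n_women = 500, seed = 3,
                     weight_range = c(0.5, 1.5))
  e1 <- estimate_indicator(w)
  w$weight <- w$weight * 2
  e2 <- estimate_indicator(w)
  expect_equal(e1$value, e2$value)
})

test_that("stratum estimates aggregate exactly to the national estimate", {
  w <- gen_microdata(random_targets(5), n_women = 2000, seed = 8)
  nat <- estimate_indicator(w, indicator = "DFPSm")
  strat <- estimate_indicator(w, indicator = "DFPSm",
                              stratify_by = "residence")
  expect_equal(sum(strat$numerator_weight), nat$numerator_weight)
  expect_equal(sum(strat$denominator_weight), nat$denominator_weight)
  expect_equal(sum(strat$numerator_weight) / sum(strat$denominator_weight),
               nat$value)
})

test_that("indicator ordering holds in every generated stratum", {
  for (s in 1:5) {
    w <- gen_microdata(random_targets(100 + s), n_women = 1500, seed = s)
    est <- estimate_indicator(w, stratify_by = "wealth_quintile")
    wide <- reshape(est[, c("indicator", "stratum", "value")],
                    idvar = "stratum", timevar = "indicator",
                    direction = "wide")
    expect_true(all(wide$value.DFPSany >= wide$value.DFPSm))
    expect_true(all(wide$value.CPRany >= wide$value.CPRm))
    expect_true(all(wide$value.DFPSany >= wide$value.CPRany))
    expect_true(all(wide$value.DFPSm >= wide$value.CPRm))
  }
})

test_that("every user is classified in need (numerator within denominator)", {
  w <- gen_microdata(random_targets(42), n_women = 1000, seed = 9)
  users <- classify_method(w$method_code) != "none"
  expect_true(all(classify_need(w)[users]))
})

test_that("analysis population and degenerate strata are handled", {
  w <- four_women()
  w$partnered <- c(TRUE, TRUE, FALSE, TRUE)       # drop the traditional user
  est <- estimate_indicator(w, indicator = "CPRany")
  expect_equal(est$value, 2 / 3)
  w2 <- four_women()
  w2$age <- c(30, 25, 40, 52)                      # over-age woman dropped
  est2 <- estimate_indicator(w2, indicator = "CPRany")
  expect_equal(est2$value, 1)
  # a stratum where nobody is in need yields NA, not 0/0
  w3 <- data.frame(age = 30, partnered = TRUE, method_code = "none",
                   weight = 1, grp = "a")
  expect_warning(est3 <- estimate_indicator(w3, indicator = "DFPSany",
                                            stratify_by = "grp"), "zero")
  expect_true(is.na(est3$value))
  expect_error(estimate_indicator(data.frame(age = 10, partnered = TRUE,
                                             method_code = "none",
                                             weight = 1)),
               "no partnered women")
  bad <- four_women(); bad$weight[1] <- -1
  expect_error(estimate_indicator(bad), "positive")
})
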
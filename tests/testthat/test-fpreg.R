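test_that("fractional-polynomial basis follows the standard conventions", {
  expect_equal(unname(fp_transform(0.5, c(0, 2))[1, ]),
               c(log(0.5), 0.25))
  expect_equal(unname(fp_transform(c(0.2, 0.7), 1)[, 1]), c(0.2, 0.7))
  expect_equal(unname(fp_transform(0.3, -0.5)[1, 1]), 0.3^-0.5)
  # repeated power: x^p and x^p * log(x)
  expect_equal(unname(fp_transform(exp(1), c(2, 2))[1, ]),
               c(exp(2), exp(2)))
  expect_equal(unname(fp_transform(2, c(0, 0))[1, ]),
               c(log(2), log(2)^2))
  expect_error(fp_transform(c(0.5, 0), 1), "positive.*2")
  expect_error(fp_transform(0.5, c(1, 2, 3)), "length")
})

test_that("fit_ols matches an independent normal-equations oracle", {
  withr::with_seed(101, {
    X <- matrix(rnorm(90), 30, 3)
    y <- 1 + X %*% c(0.5, -2, 0.3) + rnorm(30, sd = 0.3)
    cl <- rep(1:6, each = 5)
  })
  fit <- fit_ols(X, drop(y), cl)
  expect_equal(unname(fit$coefficients), unname(ols_oracle(X, drop(y))),
               tolerance = 1e-8)
  expect_equal(unname(fit$robust_se),
               unname(cluster_se_oracle(X, drop(y), cl)),
               tolerance = 1e-8)
  expect_equal(fit$n_clusters, 6L)
})

test_that("a noise-free linear outcome is fitted exactly", {
  x <- seq(1, 10)
  y <- 2 + 3 * x
  fit <- fit_ols(matrix(x, ncol = 1), y, cluster = rep(1:2, 5))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  expect_equal(fit$r_squared, 1)
})

test_that("singleton clusters reduce the sandwich to heteroskedasticity-robust", {
  withr::with_seed(7, {
    X <- matrix(rnorm(40), 20, 2)
    y <- drop(X %*% c(1, -1)) + rnorm(20)
  })
  fit <- fit_ols(X, y, cluster = seq_len(20))
  expect_equal(unname(fit$robust_se),
               unname(cluster_se_oracle(X, y, seq_len(20))),
               tolerance = 1e-10)
})

test_that("robust SEs are invariant to cluster relabeling", {
  sim <- small_sim(seed = 4)$rows
  f1 <- fit_fp(sim, "any")
  relab <- sim
  key <- setNames(sample(unique(sim$country_id)),
                  unique(sim$country_id))
  relab$country_id <- unname(key[sim$country_id])
  f2 <- fit_fp(relab, "any")
  expect_equal(f1$robust_se, f2$robust_se)
  expect_equal(f1$coefficients, f2$coefficients)
})

test_that("degenerate designs raise informative errors", {
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(X, rnorm(10), rep(1:2, 5)), "collinear")
  expect_error(fit_ols(matrix(1:10, ncol = 1), rnorm(10), rep(1, 10)),
               "2 clusters")
  expect_error(fit_ols(matrix(1:2, ncol = 1), 1:2, 1:2), "rows")
})

test_that("exclusion filter removes low-prevalence rows and logs them", {
  d <- data.frame(cpr_any = c(0.005, 0.2, 0.5), cpr_m = c(0.004, 0.1, 0.4))
  out <- apply_exclusion(d, "any")
  expect_equal(nrow(out), 2)
  log_ <- attr(out, "exclusion_log")
  expect_equal(log_$row, 1L)
  expect_match(log_$reason, "below threshold")
  # 15% threshold on both prevalences reproduces the sensitivity restriction
  out15 <- apply_exclusion(d, "both", threshold = 0.15)
  expect_equal(out15$cpr_any, 0.5)
  # nothing below threshold: output identical, empty log
  clean <- apply_exclusion(d[2:3, ], "any")
  expect_equal(clean$cpr_any, d$cpr_any[2:3])
  expect_equal(nrow(attr(clean, "exclusion_log")), 0)
})

test_that("fp_search recovers the generating specification", {
  sim <- gen_region_rows(generator_config(), seed = 12)
  sr <- fp_search(sim$rows, "any")
  expect_equal(sr$best$powers, c(0, 2))
  expect_true("cpdiff" %in% sr$best$extras)
  # ranking is invariant to row order
  perm <- withr::with_seed(3, sample(nrow(sim$rows)))
  sr2 <- fp_search(sim$rows[perm, ], "any")
  expect_equal(sr2$results$powers, sr$results$powers)
  expect_equal(sr2$results$rss, sr$results$rss)
})

test_that("rss is monotone under nesting of fp specifications", {
  sim <- small_sim(seed = 21)$rows
  sr <- fp_search(sim, "modern", extras_candidates = character())
  res <- sr$results
  two_term <- grepl(",", res$powers)
  best2 <- min(res$rss[two_term])
  best1 <- min(res$rss[!two_term])
  expect_lte(best2, best1)
  expect_lte(best1, max(res$rss))
})

test_that("linear-vs-fp comparison is deterministic and detects curvature", {
  sim <- gen_region_rows(generator_config(n_countries = 40,
                                          n_regions = 400), seed = 6)
  rows <- apply_exclusion(sim$rows, "any")
  c1 <- compare_linear_fp(rows, "any")
  c2 <- compare_linear_fp(rows, "any")
  expect_identical(c1$p_value, c2$p_value)
  # data generated over the full prevalence range are genuinely curved
  expect_lt(c1$rss_fp, c1$rss_linear)
  expect_lt(c1$p_value, 0.05)
})

test_that("no spurious fp signal on truly linear logit data", {
  # logit(dfps) linear in prevalence; count rejections across replicates
  rejections <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    d <- withr::with_seed(400 + s, {
      cpr <- runif(150, 0.15, 0.85)
      data.frame(
        country_id = rep(sprintf("C%02d", 1:30), each = 5),
        cpr_any = cpr, cpr_m = cpr, cpdiff = 0,
        dfps_any = plogis(-0.5 + 2.5 * cpr + rnorm(150, sd = 0.1)))
    })
    cmp <- compare_linear_fp(d, "any")
    if (cmp$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.10)
})
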
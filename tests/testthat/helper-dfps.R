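# Shared fixtures and independent oracles, built in code at test time.

# Four partnered women: two modern users, one traditional user, one
# non-user in need. Hand counts: CPRany 3/4, CPRm 2/4, everyone in need.
four_women <- function(weights = c(1, 1, 1, 1)) {
  data.frame(
    age = c(30, 25, 40, 35),
    partnered = TRUE,
    method_code = c("pill", "iud", "withdrawal", "none"),
    pregnant = FALSE,
    wants_child_within_2y = c(NA, NA, NA, "no"),
    weight = weights,
    cluster_id = "PSU1", country_id = "C1", region_id = "R1",
    stringsAsFactors = FALSE
  )
}

# Independent OLS oracle: normal equations, nothing shared with fit_ols.
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# Independent cluster-sandwich oracle with the HC1-type small-sample
# factor G/(G-1) * (N-1)/(N-k).
cluster_se_oracle <- function(X, y, cluster) {
  Xi <- cbind(1, X)
  n <- nrow(Xi); k <- ncol(Xi)
  beta <- ols_oracle(X, y)
  res <- y - Xi %*% beta
  bread <- solve(t(Xi) %*% Xi)
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(Xi[idx, , drop = FALSE]) %*% res[idx]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster))
  adj <- G / (G - 1) * (n - 1) / (n - k)
  sqrt(diag(adj * bread %*% meat %*% bread))
}

# Random internally consistent indicator targets: the four quantities
# share one numerator, so DFPSm is implied by the other three.
random_targets <- function(seed) {
  withr::with_seed(seed, {
    cpr_any <- runif(1, 0.10, 0.80)
    cpr_m <- cpr_any * runif(1, 0.4, 1)
    need <- runif(1, cpr_any, 1)
    list(cpr_any = cpr_any, cpr_m = cpr_m,
         dfps_any = cpr_any / need, dfps_m = cpr_m / need)
  })
}

# Small synthetic region table for fast tests.
small_sim <- function(seed = 1, noise = 0.05, country_sd = 0.05,
                      n_countries = 25, n_regions = 150) {
  cfg <- generator_config(n_countries = n_countries, n_regions = n_regions,
                          logit_noise_sd = noise,
                          country_effect_sd = country_sd)
  gen_region_rows(cfg, seed = seed)
}
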
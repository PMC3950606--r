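beh_controls <- c("fruit_index", "rainfall_mm")

fit_q <- function(tab, ...) {
  suppressWarnings(fit_model(tab, "y", "mg_pct", beh_controls, ...))
}

test_that("standardize centres and scales by the sample SD", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(rep(4, 10), "flat"), "flat")
  set.seed(3)
  z <- standardize(rnorm(50, 7, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("the AC covariate is the kernel-weighted mean of other same-male residuals", {
  expect_equal(build_ac_term(as.Date("2011-01-01"), "m1", 0.7, 2), 0)
  # two same-male rows: the single neighbour's residual, any sigma
  d <- as.Date("2011-01-01") + c(0, 1)
  for (s in c(0.5, 2, 16)) {
    expect_equal(build_ac_term(d, c("m1", "m1"), c(0.3, -0.8), s),
                 c(-0.8, 0.3))
  }
  # hand-computed three-row case
  d3 <- as.Date("2011-01-01") + c(0, 1, 3)
  r3 <- c(1, 2, 4)
  w12 <- exp(-1 / 8); w13 <- exp(-9 / 8)
  expect_equal(build_ac_term(d3, rep("m1", 3), r3, 2)[1],
               (w12 * 2 + w13 * 4) / (w12 + w13))
  # other males contribute nothing
  expect_equal(build_ac_term(d3, c("m1", "m2", "m2"), r3, 2)[1], 0)
})

test_that("including the AC term raises the likelihood under AR(1) residuals", {
  set.seed(17)
  wins <- 0L
  for (i in 1:100) {
    tab <- simulate_model_table(n_males = 3, days_per_male = 100,
                                beta_mg = 0, rho = 0.6,
                                seed = sample.int(2^31 - 1, 1))
    with_ac <- fit_q(tab, ac = 2)
    without <- fit_q(tab, ac = "none")
    if (with_ac$logLik > without$logLik) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("the LRT matches the hand-computed statistic and handles edge cases", {
  tab <- simulate_model_table(beta_mg = -1, seed = 2)
  f <- fit_q(tab, ac = "none")
  chisq_hand <- 2 * (as.numeric(logLik(f$fit_full)) -
                       as.numeric(logLik(f$fit_null)))
  expect_equal(f$lrt$chisq, chisq_hand)
  expect_equal(f$lrt$df, 1)           # one dropped slope
  expect_equal(f$lrt$p,
               pchisq(chisq_hand, 1, lower.tail = FALSE))
  same <- lrt(f$fit_full, f$fit_full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(f$fit_null, f$fit_full), "not nested|more parameters")
})

test_that("the full-vs-null LRT is invariant to affine predictor rescaling", {
  tab <- simulate_model_table(beta_mg = -1, seed = 5)
  f1 <- fit_q(tab, ac = 2)
  tab2 <- tab
  tab2$mg_pct <- tab2$mg_pct / 100 + 0.2
  tab2$rainfall_mm <- tab2$rainfall_mm * 10 - 3
  f2 <- fit_q(tab2, ac = 2)
  expect_equal(f1$lrt$chisq, f2$lrt$chisq, tolerance = 1e-4)
})

test_that("VIFs follow the 1/(1-R^2) closed form and agree with car", {
  set.seed(23)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)   # population r = 0.8
  x3 <- rnorm(n)
  tab <- data.frame(y = rnorm(n), a = x1, b = x2, c = x3)
  v <- vif_table(tab, c("a", "b", "c"))
  r2_a <- summary(lm(a ~ b + c, tab))$r.squared
  expect_equal(v$vif[v$predictor == "a"], 1 / (1 - r2_a))
  expect_equal(v$vif[v$predictor == "a"], 1 / (1 - 0.64), tolerance = 0.25)
  skip_if_not_installed("car")
  cv <- car::vif(lm(y ~ a + b + c, tab))
  expect_equal(v$vif, unname(cv[v$predictor]), tolerance = 1e-8)
  # orthogonal predictors give VIF 1; a duplicate is flagged infinite
  ortho <- data.frame(y = rnorm(4), a = c(1, 1, -1, -1),
                      b = c(1, -1, 1, -1))
  expect_equal(vif_table(ortho, c("a", "b"))$vif, c(1, 1))
  dup <- data.frame(y = rnorm(10), a = 1:10, b = 1:10)
  vd <- vif_table(dup, c("a", "b"))
  expect_true(all(!is.finite(vd$vif)) && all(vd$flagged))
})

test_that("a null mate-guarding effect is covered by the 95 % interval at the nominal rate", {
  set.seed(29)
  cover <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    tab <- simulate_model_table(beta_mg = 0, seed = sample.int(2^31 - 1, 1))
    f <- fit_q(tab, ac = 2)
    co <- f$coefficients[f$coefficients$term == "mg_pct", ]
    if (abs(co$estimate) < 1.96 * co$se) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.85)
  expect_lte(cover / n_rep, 1.0)
})

test_that("a planted standardized effect is recovered", {
  set.seed(31)
  est <- vapply(sample.int(2^31 - 1, 20), function(s) {
    tab <- simulate_model_table(beta_mg = -2, seed = s)
    f <- fit_q(tab, ac = 2)
    f$coefficients$estimate[f$coefficients$term == "mg_pct"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-2)), 0.2)
})

test_that("model specs match the study's fixed/control/random structures", {
  sp <- mg_model_specs()
  expect_named(sp, c("pct_feeding", "pct_fruit_in_diet",
                     "hourly_vertical_m", "hourly_distance_m",
                     "restlessness", "ucp_mg", "ucp_rank"))
  for (nm in c("pct_feeding", "pct_fruit_in_diet", "hourly_vertical_m",
               "hourly_distance_m", "restlessness")) {
    expect_equal(sp[[nm]]$test, "mg_pct")
    expect_equal(sp[[nm]]$controls, c("fruit_index", "rainfall_mm"))
    expect_equal(sp[[nm]]$ac, "grid")
    expect_equal(sp[[nm]]$table, "behaviour")
  }
  expect_equal(sp$ucp_mg$controls,
               c("hourly_vertical_m", "pct_feeding", "fruit_index",
                 "collection_time", "storage_months"))
  expect_equal(sp$ucp_rank$test, "rank_class")
  expect_equal(sp$ucp_rank$controls,
               c("fruit_index", "collection_time", "storage_months"))
})

test_that("few random-effect levels trigger the small-cluster warning", {
  tab <- simulate_model_table(beta_mg = 0, seed = 13)
  expect_warning(
    fit_model(tab, "y", "mg_pct", beh_controls, ac = "none"),
    class = "mg_small_cluster_warning")
})
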
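test_that("the comparison decision tree selects the expected test", {
  withr::with_seed(1, {
    a <- rnorm(50); b <- rnorm(50, 0.3)
  })
  res <- select_and_compare(a, b)
  expect_equal(res$test_name, "independent_t")
  expect_true(length(res$decision_trace) >= 3)

  withr::with_seed(2, skewed <- rexp(50))
  res2 <- select_and_compare(skewed, a + 1)
  expect_equal(res2$test_name, "mann_whitney_u")

  withr::with_seed(501, {
    c1 <- rnorm(50); wide <- rnorm(50, 0, 6)
  })
  res3 <- select_and_compare(c1, wide)
  expect_equal(res3$test_name, "welch_t")

  withr::with_seed(3, {
    d <- rnorm(30)
    res4 <- select_and_compare(d + rnorm(30, 0.2, 0.1), d, paired = TRUE)
  })
  expect_true(res4$test_name %in% c("paired_t", "wilcoxon_signed_rank"))
  expect_error(select_and_compare(rnorm(5), rnorm(4), paired = TRUE),
               "equal-length")
  expect_error(select_and_compare(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               "all zero")
  expect_error(select_and_compare(1:2, 1:5), "at least 3")
})

test_that("identical inputs always select the identical test", {
  withr::with_seed(55, {
    a <- rnorm(20); b <- rexp(20)
  })
  r1 <- select_and_compare(a, b)
  r2 <- select_and_compare(a, b)
  expect_identical(r1$test_name, r2$test_name)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$decision_trace, r2$decision_trace)
})

test_that("with no clustering the mixed model matches ordinary least squares", {
  out <- simulate_moderation_cohort(seed = 77, n_per_group = 50,
                                    interaction = 5, noise = 1)
  # overwrite with a model that has no subject effect at all
  withr::with_seed(78, {
    metric <- rnorm(nrow(out), 0.5, 0.1)
    is_trt <- as.numeric(out$group == "treatment")
    y <- 1 + 2 * metric + 0.5 * is_trt + 5 * metric * is_trt +
      0.1 * out$timepoint + rnorm(nrow(out))
  })
  fit <- fit_moderation_model(y, metric, out$group, out$timepoint,
                              out$subject)
  ols <- lm(y ~ metric * group + factor(timepoint),
            data = data.frame(metric = metric, group = out$group,
                              timepoint = out$timepoint))
  b_lmm <- coef(fit)
  b_ols <- coef(ols)
  expect_equal(unname(b_lmm["metric:grouptreatment"]),
               unname(b_ols["metric:grouptreatment"]), tolerance = 1e-3)
  expect_equal(unname(b_lmm["metric"]), unname(b_ols["metric"]),
               tolerance = 1e-3)
})

test_that("a planted interaction at realistic scale is recovered", {
  out <- simulate_moderation_cohort(seed = 42, n_per_group = 20,
                                    interaction = 9.087, noise = 0.5)
  fit <- fit_moderation_model(out$path_length, out$metric, out$group,
                              out$timepoint, out$subject)
  ix <- grep(":", fit$coefficients$term)
  expect_lt(abs(fit$coefficients$estimate[ix] - 9.087), 0.5)
  expect_equal(fit$df_method, "Satterthwaite")
  expect_true(all(c("r2_marginal", "r2_conditional", "f2_interaction") %in%
                    names(unlist(fit[c("r2_marginal", "r2_conditional",
                                       "f2_interaction")]))))
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
  expect_gte(fit$f2_interaction, 0)
})

test_that("in the low-noise limit planted coefficients are recovered", {
  out <- simulate_moderation_cohort(seed = 5, n_per_group = 10,
                                    interaction = 9.087, noise = 1e-4,
                                    subject_sd = 1e-4)
  fit <- fit_moderation_model(out$path_length, out$metric, out$group,
                              out$timepoint, out$subject)
  ix <- grep(":", fit$coefficients$term)
  expect_equal(fit$coefficients$estimate[ix], 9.087, tolerance = 5e-4)
})

test_that("degenerate designs are rejected", {
  out <- simulate_moderation_cohort(seed = 6, n_per_group = 3)
  one_group <- out[out$group == "sci", ]
  expect_error(fit_moderation_model(one_group$path_length, one_group$metric,
                                    one_group$group, one_group$timepoint,
                                    one_group$subject), "2 groups")
  base_only <- out[out$timepoint == 0, ]
  expect_error(fit_moderation_model(base_only$path_length, base_only$metric,
                                    base_only$group, base_only$timepoint,
                                    base_only$subject), "2 timepoints")
})

test_that("simple slopes obey the reference-coding identity", {
  out <- simulate_moderation_cohort(seed = 8, n_per_group = 8)
  fit <- fit_moderation_model(out$path_length, out$metric, out$group,
                              out$timepoint, out$subject)
  ss <- fit$simple_slopes
  ix <- grep(":", fit$coefficients$term)
  beta_metric <- fit$coefficients$estimate[fit$coefficients$term == "metric"]
  beta_int <- fit$coefficients$estimate[ix]
  expect_equal(ss$estimate[ss$contrast == "sci"], beta_metric,
               tolerance = 1e-12)
  expect_equal(ss$estimate[ss$contrast == "treatment"],
               beta_metric + beta_int, tolerance = 1e-10)
  expect_equal(ss$estimate[ss$contrast == "difference"], beta_int,
               tolerance = 1e-12)
  # CIs contain their point estimates
  expect_true(all(ss$lower <= ss$estimate & ss$estimate <= ss$upper))
})

test_that("simple slopes agree with the emmeans trend decomposition", {
  skip_if_not_installed("emmeans")
  out <- simulate_moderation_cohort(seed = 9, n_per_group = 8)
  fit <- fit_moderation_model(out$path_length, out$metric, out$group,
                              out$timepoint, out$subject)
  emt <- as.data.frame(emmeans::emtrends(fit$model, "group", var = "metric",
                                         lmer.df = "satterthwaite"))
  ss <- fit$simple_slopes
  expect_equal(ss$estimate[1:2], emt$metric.trend, tolerance = 1e-8)
  expect_equal(ss$se[1:2], emt$SE, tolerance = 1e-6)
})

test_that("effect sizes follow the marginal-R2 definition of f2", {
  out <- simulate_moderation_cohort(seed = 10, n_per_group = 10)
  fit <- fit_moderation_model(out$path_length, out$metric, out$group,
                              out$timepoint, out$subject)
  es <- model_effect_sizes(fit)
  # independent reconstruction of the marginal/conditional R2
  X <- lme4::getME(fit$model, "X")
  vf <- var(as.vector(X %*% lme4::fixef(fit$model)))
  vc <- lme4::VarCorr(fit$model)
  vr <- as.numeric(vc$subject[1, 1])
  ve <- attr(vc, "sc")^2
  expect_equal(unname(es["r2_marginal"]), vf / (vf + vr + ve),
               tolerance = 1e-10)
  expect_equal(unname(es["r2_conditional"]), (vf + vr) / (vf + vr + ve),
               tolerance = 1e-10)
  # the f2 arithmetic on known R2 values: (0.5 - 0.4) / (1 - 0.5)
  expect_equal((0.5 - 0.4) / (1 - 0.5), 0.2)
})

test_that("trajectory fit finds a linear trend with edf near 1", {
  withr::with_seed(1, {
    months <- rep(c(0, 1, 2, 3, 6, 12), 8)
    subject <- rep(sprintf("S%02d", 1:8), each = 6)
    u <- rnorm(8, 0, 0.5)[rep(1:8, each = 6)]
    y <- 2 + 0.4 * months + u + rnorm(48, 0, 0.3)
  })
  tf <- fit_trajectory(y, months, subject)
  expect_lte(tf$edf, 1.3)
  expect_lt(abs(tf$slope - 0.4), 2 * tf$slope_se)
  # determinism
  tf2 <- fit_trajectory(y, months, subject)
  expect_identical(tf$k_selected, tf2$k_selected)
  expect_identical(tf$fitted_curve, tf2$fitted_curve)
})

test_that("trajectory preconditions are enforced", {
  expect_error(fit_trajectory(rnorm(9), rep(c(0, 1, 2), 3),
                              rep(c("a", "b", "c"), each = 3)),
               "4 distinct")
  months <- rep(c(0, 1, 2, 3, 6, 12), 4)
  expect_error(fit_trajectory(rnorm(24), months,
                              rep(sprintf("S%d", 1:4), each = 6),
                              k_candidates = c(2, 3)), "k_candidates")
  expect_error(fit_trajectory(rnorm(24), months,
                              rep(sprintf("S%d", 1:4), each = 6),
                              k_candidates = 7), "k_candidates")
})
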
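#' Decision-tree two-sample comparison
#'
#' Picks the comparison test the way longitudinal imaging studies commonly
#' do. Unpaired: Shapiro-Wilk on each group (alpha = 0.05); if either group
#' deviates from normality the Mann-Whitney U test is used; otherwise
#' Levene's test for homogeneity of variance decides between Student's
#' (equal-variance) t-test and Welch's t-test. Paired: Shapiro-Wilk on the
#' paired differences decides between the paired t-test and the Wilcoxon
#' signed-rank test. Every check that fired is recorded in
#' `decision_trace`, so the selection is auditable and reproducible.
#'
#' Effect sizes: Cohen's d (pooled SD) for the t-tests, d_z for the paired
#' t-test, rank-biserial correlation for the rank tests.
#'
#' @param group_a,group_b numeric observations (for paired comparisons the
#'   vectors must align and have equal length).
#' @param paired logical.
#' @param alpha screening level of the normality and variance checks.
#' @return Object of class `comparison_result`: `test_name`, `statistic`,
#'   `p_value`, `ci` (95% interval where defined), `effect_size`,
#'   `decision_trace`.
#' @export
select_and_compare <- function(group_a, group_b, paired = FALSE,
                               alpha = 0.05) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  trace <- character(0)
  if (paired) {
    if (length(group_a) != length(group_b)) {
      stop("paired comparison requires equal-length samples", call. = FALSE)
    }
    d <- group_a - group_b
    d <- d[!is.na(d)]
    if (all(d == 0)) {
      stop("paired differences are all zero: test degenerate", call. = FALSE)
    }
    sw <- shapiro.test(d)
    trace <- c(trace, sprintf("shapiro(differences) p=%.4f -> %s",
                              sw$p.value,
                              if (sw$p.value < alpha) "non-normal" else "normal"))
    if (sw$p.value < alpha) {
      ht <- suppressWarnings(wilcox.test(group_a, group_b, paired = TRUE,
                                         conf.int = TRUE, exact = FALSE))
      nz <- sum(d != 0)
      rb <- as.numeric(ht$statistic) / (nz * (nz + 1) / 4) - 1
      res <- list(test_name = "wilcoxon_signed_rank", ht = ht,
                  effect_size = c(rank_biserial = rb))
    } else {
      ht <- t.test(group_a, group_b, paired = TRUE)
      res <- list(test_name = "paired_t", ht = ht,
                  effect_size = c(cohens_dz = mean(d) / sd(d)))
    }
  } else {
    sw_a <- shapiro.test(a)
    sw_b <- shapiro.test(b)
    trace <- c(trace,
               sprintf("shapiro(group_a) p=%.4f", sw_a$p.value),
               sprintf("shapiro(group_b) p=%.4f", sw_b$p.value))
    if (min(sw_a$p.value, sw_b$p.value) < alpha) {
      trace <- c(trace, "normality rejected -> Mann-Whitney U")
      ht <- suppressWarnings(wilcox.test(a, b, conf.int = TRUE, exact = FALSE))
      rb <- 1 - 2 * as.numeric(ht$statistic) / (length(a) * length(b))
      res <- list(test_name = "mann_whitney_u", ht = ht,
                  effect_size = c(rank_biserial = rb))
    } else {
      lev <- car::leveneTest(c(a, b),
                             factor(rep(c("a", "b"), c(length(a), length(b)))),
                             center = mean)
      p_lev <- lev[["Pr(>F)"]][1L]
      trace <- c(trace, sprintf("levene p=%.4f -> %s variances", p_lev,
                                if (p_lev < alpha) "unequal" else "equal"))
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
      d_eff <- c(cohens_d = (mean(a) - mean(b)) / sp)
      if (p_lev < alpha) {
        ht <- t.test(a, b, var.equal = FALSE)
        res <- list(test_name = "welch_t", ht = ht, effect_size = d_eff)
      } else {
        ht <- t.test(a, b, var.equal = TRUE)
        res <- list(test_name = "independent_t", ht = ht, effect_size = d_eff)
      }
    }
  }
  ci <- if (!is.null(res$ht$conf.int)) as.numeric(res$ht$conf.int) else
    c(NA_real_, NA_real_)
  structure(
    list(test_name = res$test_name,
         statistic = as.numeric(res$ht$statistic),
         p_value = res$ht$p.value,
         ci = ci,
         effect_size = res$effect_size,
         decision_trace = trace),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!anyNA(x$ci)) cat(sprintf("  95%% CI [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  cat(sprintf("  %s = %.4f\n", names(x$effect_size), x$effect_size))
  cat("  decision trace:\n")
  for (s in x$decision_trace) cat("   -", s, "\n")
  invisible(x)
}

ci_from <- function(est, se, df) {
  q <- qt(0.975, df)
  cbind(lower = est - q * se, upper = est + q * se)
}

#' Mixed-effects moderation model of a network metric on an outcome
#'
#' Fits, by REML, the linear mixed model
#' `outcome ~ metric + group + metric:group + timepoint + (1 | subject)`
#' with timepoint entered categorically and the injury-only group as the
#' reference level. The metric-by-group interaction tests whether the
#' brain-behavior association differs between groups (moderation). Fixed
#' effects are reported with Satterthwaite small-sample denominator degrees
#' of freedom; per-group simple slopes and their contrast, Nakagawa marginal
#' and conditional R-squared, and Cohen's f-squared of the interaction
#' (against the interaction-free refit) are computed alongside.
#'
#' @param outcome,metric numeric vectors.
#' @param group two-level grouping; reference level is `"sci"` when present,
#'   otherwise the first factor level.
#' @param timepoint visit labels (treated as categorical).
#' @param subject subject identifiers (random intercept).
#' @return Object of class `moderation_fit`.
#' @export
fit_moderation_model <- function(outcome, metric, group, timepoint, subject) {
  d <- data.frame(outcome = outcome, metric = metric,
                  group = factor(group), timepoint = factor(timepoint),
                  subject = factor(subject))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if ("sci" %in% levels(d$group)) d$group <- stats::relevel(d$group, "sci")
  if (nlevels(d$group) != 2L) {
    stop("moderation model needs exactly 2 groups (singular design)",
         call. = FALSE)
  }
  per_group <- table(unique(d[, c("subject", "group")])$group)
  if (any(per_group < 2L)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (nlevels(d$timepoint) < 2L) {
    stop("need at least 2 timepoints", call. = FALSE)
  }
  fit <- tryCatch(
    lmerTest::lmer(outcome ~ metric * group + timepoint + (1 | subject),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) stop("moderation model failed to fit: ",
                             conditionMessage(e), call. = FALSE)
  )
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages) &&
      any(grepl("failed to converge", conv$messages))) {
    stop("moderation model did not converge: ",
         paste(conv$messages, collapse = "; "), call. = FALSE)
  }
  smry <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(smry),
    estimate = smry[, "Estimate"],
    se = smry[, "Std. Error"],
    df = smry[, "df"],
    t = smry[, "t value"],
    p = smry[, "Pr(>|t|)"],
    row.names = NULL
  )
  cis <- ci_from(coefs$estimate, coefs$se, coefs$df)
  coefs$lower <- cis[, "lower"]
  coefs$upper <- cis[, "upper"]

  reduced <- stats::update(fit, . ~ . - metric:group)
  out <- structure(
    list(model = fit, reduced_model = reduced, coefficients = coefs,
         data = d, df_method = "Satterthwaite",
         groups = levels(d$group),
         interaction_term = grep(":", coefs$term, value = TRUE)),
    class = "moderation_fit"
  )
  out$simple_slopes <- simple_slopes(out)
  es <- model_effect_sizes(out)
  out$r2_marginal <- es[["r2_marginal"]]
  out$r2_conditional <- es[["r2_conditional"]]
  out$f2_interaction <- es[["f2_interaction"]]
  out
}

interaction_row <- function(fit) {
  ix <- grep("^metric:", fit$coefficients$term)
  if (!length(ix)) stop("model has no metric-by-group interaction term",
                        call. = FALSE)
  ix
}

#' Per-group simple slopes of the network metric
#'
#' Under reference coding the injury-only slope is the `metric` coefficient
#' and the treatment slope is `metric` + `metric:group`; standard errors come
#' from the linear-combination variance, with Satterthwaite degrees of
#' freedom for each contrast. The between-group slope difference is exactly
#' the interaction coefficient with its test.
#'
#' @param fit a [fit_moderation_model()] result.
#' @return Data frame of class `simple_slopes`: one row per group plus a
#'   `difference` row, with estimate, SE, df, t, p and 95% CI.
#' @export
simple_slopes <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  ix <- interaction_row(fit)
  fe <- lme4::fixef(fit$model)
  terms <- names(fe)
  L_ref <- as.numeric(terms == "metric")
  L_trt <- L_ref + as.numeric(seq_along(terms) == which(terms ==
                                fit$coefficients$term[ix]))
  L_diff <- L_trt - L_ref
  rows <- lapply(list(L_ref, L_trt, L_diff), function(L) {
    ct <- lmerTest::contest1D(fit$model, L, confint = TRUE)
    data.frame(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
               t = ct$`t value`, p = ct$`Pr(>|t|)`,
               lower = ct$lower, upper = ct$upper)
  })
  out <- do.call(rbind, rows)
  out <- cbind(contrast = c(fit$groups, "difference"), out)
  rownames(out) <- NULL
  class(out) <- c("simple_slopes", "data.frame")
  out
}

nakagawa_r2 <- function(model) {
  X <- lme4::getME(model, "X")
  beta <- lme4::fixef(model)
  var_fixed <- var(as.vector(X %*% beta))
  vc <- lme4::VarCorr(model)
  var_random <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_resid <- attr(vc, "sc")^2
  tot <- var_fixed + var_random + var_resid
  c(r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_random) / tot)
}

#' Variance explained and interaction effect size
#'
#' Nakagawa R-squared: marginal = variance of the fixed-effect predictions
#' over (fixed + random + residual) variance; conditional adds the random
#' variance to the numerator. Cohen's f-squared of the interaction compares
#' the full model with its interaction-free refit on the marginal scale:
#' f2 = (R2_full - R2_reduced) / (1 - R2_full).
#'
#' @param fit a [fit_moderation_model()] result.
#' @return Named vector: `r2_marginal`, `r2_conditional`, `f2_interaction`.
#' @export
model_effect_sizes <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  r2 <- nakagawa_r2(fit$model)
  r2_red <- nakagawa_r2(fit$reduced_model)
  if (r2[["r2_marginal"]] >= 1 - 1e-12) {
    stop("full-model R-squared is 1: f-squared undefined", call. = FALSE)
  }
  f2 <- (r2[["r2_marginal"]] - r2_red[["r2_marginal"]]) /
    (1 - r2[["r2_marginal"]])
  c(r2, f2_interaction = max(f2, 0))
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Mixed-effects moderation model (REML,", x$df_method, "df)\n")
  cat("  outcome ~ metric * group + timepoint + (1 | subject)\n\n")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat("\nSimple slopes of metric by group:\n")
  print(format(as.data.frame(x$simple_slopes), digits = 4),
        row.names = FALSE)
  cat(sprintf("\nR2 marginal %.3f, conditional %.3f; interaction f2 %.3f\n",
              x$r2_marginal, x$r2_conditional, x$f2_interaction))
  invisible(x)
}

#' @export
coef.moderation_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.moderation_fit <- function(object, ...) {
  list(coefficients = object$coefficients,
       simple_slopes = object$simple_slopes,
       r2_marginal = object$r2_marginal,
       r2_conditional = object$r2_conditional,
       f2_interaction = object$f2_interaction,
       df_method = object$df_method)
}

#' Longitudinal trajectory of a global metric
#'
#' Penalized cubic regression spline of the metric on months since injury
#' with a subject random intercept (a generalized additive mixed model in
#' its one-dimensional form), estimated by REML so the wiggliness is
#' penalized rather than overfitted. The basis dimension k is chosen by
#' minimum BIC over `k_candidates`. Reports the effective degrees of freedom
#' of the smooth (about 1 for a linear trend), its significance, and the
#' fitted population curve with pointwise standard errors. A linear
#' approximation of the trend (slope of the fitted curve) is provided for
#' interpretation.
#'
#' @param metric,months,subject aligned vectors: metric value, months since
#'   injury, subject id.
#' @param k_candidates candidate basis dimensions, each in
#'   [3, number of distinct months]; default 3 up to that count (capped at 8).
#' @return Object of class `trajectory_fit`: `model`, `k_selected`, `bic`
#'   (per candidate), `edf`, `p_smooth`, `fitted_curve` (grid data frame with
#'   `months`, `fit`, `se`), `slope` and `slope_se` of the linear
#'   approximation, `subject_intercepts`.
#' @export
fit_trajectory <- function(metric, months, subject, k_candidates = NULL) {
  d <- data.frame(metric = metric, months = as.numeric(months),
                  subject = factor(subject))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_distinct <- length(unique(d$months))
  if (n_distinct < 4L) stop("need at least 4 distinct time values",
                            call. = FALSE)
  if (is.null(k_candidates)) k_candidates <- 3:min(n_distinct, 8L)
  if (any(k_candidates < 3L | k_candidates > n_distinct)) {
    stop("k_candidates must lie in [3, number of distinct time values]",
         call. = FALSE)
  }
  fits <- lapply(k_candidates, function(k) {
    mgcv::gam(metric ~ s(months, bs = "cr", k = k) + s(subject, bs = "re"),
              data = d, method = "REML")
  })
  bics <- vapply(fits, BIC, numeric(1))
  best <- which.min(bics)
  model <- fits[[best]]
  st <- summary(model)$s.table
  grid <- seq(min(d$months), max(d$months), length.out = 100L)
  nd <- data.frame(months = grid, subject = d$subject[1L])
  Xp <- predict(model, newdata = nd, type = "lpmatrix")
  Xp[, grepl("subject", colnames(Xp))] <- 0  # population-level curve
  cf <- coef(model)
  curve <- as.vector(Xp %*% cf)
  se <- sqrt(rowSums((Xp %*% model$Vp) * Xp))
  gm <- grid - mean(grid)
  wls <- gm / sum(gm^2)
  slope <- sum(wls * curve)
  slope_se <- sqrt(drop(t(wls) %*% Xp %*% model$Vp %*% t(Xp) %*% wls))
  re <- cf[grepl("subject", names(cf))]
  structure(
    list(model = model, k_selected = k_candidates[best],
         bic = setNames(bics, paste0("k", k_candidates)),
         edf = unname(st[grep("months", rownames(st)), "edf"]),
         p_smooth = unname(st[grep("months", rownames(st)), "p-value"]),
         fitted_curve = data.frame(months = grid, fit = curve, se = se),
         slope = slope, slope_se = slope_se,
         subject_intercepts = re,
         data = d),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Penalized-spline trajectory (REML, subject random intercepts)\n")
  cat(sprintf("  k selected by BIC: %d (BIC %s)\n", x$k_selected,
              paste(sprintf("%s=%.1f", names(x$bic), x$bic),
                    collapse = ", ")))
  cat(sprintf("  smooth edf %.2f, p = %.4g\n", x$edf, x$p_smooth))
  cat(sprintf("  linear approximation: slope %.4f (SE %.4f) per month\n",
              x$slope, x$slope_se))
  invisible(x)
}

#' @export
plot.trajectory_fit <- function(x, ...) {
  fc <- x$fitted_curve
  plot(x$data$months, x$data$metric, pch = 16, col = "grey50",
       xlab = "months since injury", ylab = "metric", ...)
  graphics::lines(fc$months, fc$fit, lwd = 2)
  graphics::lines(fc$months, fc$fit + 2 * fc$se, lty = 2)
  graphics::lines(fc$months, fc$fit - 2 * fc$se, lty = 2)
  invisible(x)
}
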
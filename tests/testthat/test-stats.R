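make_roi_table <- function(n_subjects, entropy_fun = function(n) runif(n, 0.5, 1.5)) {
  tab <- expand.grid(subject = sprintf("S%03d", seq_len(n_subjects)),
                     condition = c("joint", "parallel"),
                     roi = c("LF", "RF", "LC", "RC", "other"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$entropy <- entropy_fun(nrow(tab))
  tab$valid <- TRUE
  tab
}

test_that("the analysis table joins, transforms, and standardizes as specified", {
  set.seed(51)
  ent <- make_roi_table(61)
  gaze <- data.frame(subject = sprintf("S%03d", 1:61),
                     gaze_duration = runif(61, 5, 60))
  tab <- build_analysis_table(ent, gaze)
  expect_equal(nrow(tab), 610)
  expect_equal(mean(tab$gaze_z[!duplicated(tab$subject)]), 0,
               tolerance = 1e-10)
  expect_equal(sd(tab$gaze_z[!duplicated(tab$subject)]), 1,
               tolerance = 1e-10)
  expect_equal(levels(tab$condition)[1], "parallel")
  expect_equal(levels(tab$roi)[1], "other")

  # sqrt transform on a known cell
  ent2 <- ent
  ent2$entropy[1] <- 0.25
  tab2 <- build_analysis_table(ent2, gaze)
  key <- ent2[1, ]
  expect_equal(tab2$sqrt_entropy[tab2$subject == key$subject &
                                   tab2$condition == key$condition &
                                   tab2$roi == key$roi], 0.5)

  # subject missing gaze: dropped with a warning naming it
  expect_warning(tab3 <- build_analysis_table(ent, gaze[-61, ]), "S061")
  expect_equal(nrow(tab3), 600)
})

test_that("an exact linear response is recovered with zero residuals", {
  set.seed(52)
  tab <- simulate_stats_table(n_subjects = 20, resid_sd = 1e-12,
                              beta_gaze = 0.02, beta_condition = -0.01,
                              roi_effects = c(LF = .1, RF = .2, LC = 0, RC = -.1))
  fit <- fit_entropy_glm(tab)
  expect_lt(max(abs(residuals(fit$lm))), 1e-9)
  expect_equal(summary(fit$lm)$r.squared, 1, tolerance = 1e-9)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "gaze_z"], 0.02, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "conditionjoint"], -0.01,
               tolerance = 1e-8)

  one_level <- tab[tab$condition == "joint", ]
  expect_error(fit_entropy_glm(one_level), "at least 2")
})

test_that("the true gaze coefficient is covered by its 95% CI at nominal rate", {
  set.seed(53)
  hits <- 0
  for (i in 1:100) {
    tab <- simulate_stats_table(n_subjects = 61)
    fit <- fit_entropy_glm(tab)
    ci <- confint(fit$lm)["gaze_z", ]
    if (ci[1] <= 0.013 && 0.013 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("outlier screening removes only constructed outliers and reports influence", {
  set.seed(54)
  tab <- simulate_stats_table(n_subjects = 40)
  fit <- fit_entropy_glm(tab)
  clean <- screen_outliers(fit)
  expect_length(clean$removed, 0)
  # no removals: the refit reproduces the original fit exactly
  expect_equal(coef(clean$lm), coef(fit$lm))
  expect_true(all(clean$cooks >= 0))
  expect_length(clean$influential, 0)

  # inflate one response by 10 residual SDs
  tab2 <- tab
  tab2$sqrt_entropy[123] <- tab2$sqrt_entropy[123] + 10 * 0.16
  fit2 <- fit_entropy_glm(tab2)
  scr2 <- screen_outliers(fit2)
  expect_equal(scr2$removed, 123)
  expect_equal(scr2$n_removed, 1L)

  # duplicating a typical row is low-leverage: all D stay small
  tab3 <- rbind(tab, tab[17, ])
  scr3 <- screen_outliers(fit_entropy_glm(tab3))
  expect_true(all(scr3$cooks < 1))
})

test_that("ROI estimated marginal means match the model algebra and Tukey adjusts upward", {
  set.seed(55)
  tab <- simulate_stats_table(n_subjects = 30,
                              roi_effects = c(LF = 0.1, RF = 0, LC = 0, RC = 0))
  fit <- fit_entropy_glm(tab)
  out <- emm_roi_contrasts(fit)
  expect_equal(nrow(out$emm), 5)
  expect_equal(nrow(out$contrasts), choose(5, 2))

  # EMM of an ROI = intercept + roi effect + mean condition effect at gaze 0
  cf <- coef(fit$lm)
  expect_equal(out$emm$emmean[out$emm$roi == "LF"],
               unname(cf["(Intercept)"] + cf["roiLF"] +
                        0.5 * cf["conditionjoint"]),
               tolerance = 1e-10)
  expect_equal(out$emm$emmean[out$emm$roi == "other"],
               unname(cf["(Intercept)"] + 0.5 * cf["conditionjoint"]),
               tolerance = 1e-10)

  # Tukey-adjusted p >= unadjusted p for every contrast
  raw <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit$lm, ~roi, at = list(gaze_z = 0)),
    method = "pairwise", adjust = "none"))
  expect_true(all(out$contrasts$p.value >= raw$p.value - 1e-12))
})

test_that("with no ROI effect, contrasts center on zero and rarely reject", {
  set.seed(56)
  est <- c(); padj <- c()
  for (i in 1:40) {
    tab <- simulate_stats_table(n_subjects = 30)
    out <- emm_roi_contrasts(fit_entropy_glm(tab))
    est <- c(est, out$contrasts$estimate)
    padj <- c(padj, out$contrasts$p.value)
  }
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
  expect_lt(mean(padj < 0.05), 0.06)
})

test_that("cluster-robust standard errors agree with the sandwich estimator", {
  skip_if_not_installed("sandwich")
  set.seed(57)
  tab <- simulate_stats_table(n_subjects = 25)
  # induce within-subject correlation so the two SEs genuinely differ
  bump <- rnorm(25, sd = 0.1)
  tab$sqrt_entropy <- tab$sqrt_entropy + bump[as.integer(factor(tab$subject))]
  fit <- fit_entropy_glm(tab, cluster_robust = TRUE)
  V <- sandwich::vcovCL(fit$lm, cluster = tab$subject, type = "HC0",
                        cadjust = FALSE)
  expect_equal(unname(fit$cluster_se), unname(sqrt(diag(V))),
               tolerance = 1e-8)
})
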
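test_that("deviation and Helmert codings are zero-sum and orthogonal", {
  m <- rep(c("production", "comprehension"), each = 3)
  r <- rep(c("BA44", "BA45", "LpMTG"), 2)
  cc <- code_factors(m, r)
  expect_equal(sort(unique(cc$modality_dev)), c(-0.5, 0.5))
  expect_equal(sum(cc$modality_dev), 0)
  expect_equal(sum(cc$roi_lifg_vs_pmtg), 0)
  expect_equal(sum(cc$roi_ba44_vs_ba45), 0)
  expect_equal(sum(cc$roi_lifg_vs_pmtg * cc$roi_ba44_vs_ba45), 0)
  expect_error(code_factors(modality = "listening"), "unknown modality")
  expect_error(code_factors(roi = "V1"), "unknown ROI")
})

test_that("mixed fits are invariant to row order and report the AIC identity", {
  long <- small_long()
  fit <- fit_mixed_model(long, "value", baseline_terms,
                         random_slopes = c("top_down", "bottom_up"),
                         focal = "top_down")
  expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logLik, tolerance = 1e-10)
  set.seed(1)
  perm <- sample(nrow(long))
  fit2 <- fit_mixed_model(long[perm, ], "value", baseline_terms,
                          random_slopes = c("top_down", "bottom_up"),
                          focal = "top_down")
  expect_equal(fit2$fixed$estimate, fit$fixed$estimate, tolerance = 1e-8)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("with zero random-slope variance the mixed fit matches OLS", {
  cfg <- fast_config(slope_sd = c(top_down = 0, bottom_up = 0))
  study <- simulate_study(4, 80, cfg, seed = 77)
  long <- stack_bold_design(study$bold, study$designs)
  mixed <- fit_mixed_model(long, "value", baseline_terms,
                           random_slopes = "top_down", focal = "top_down")
  ols <- fit_mixed_model(long, "value", baseline_terms)  # no random terms
  # the estimated slope variance is near but not exactly zero, so agreement
  # is close rather than exact
  expect_equal(mixed$fixed$estimate, ols$fixed$estimate, tolerance = 0.02)
})

test_that("rank-deficient designs are refused naming the aliased column", {
  long <- small_long()
  long$dup <- long$top_down
  expect_error(fit_mixed_model(long, "value", c(baseline_terms, "dup"),
                               random_slopes = "top_down"),
               "rank deficient")
})

test_that("Wald term tests match t^2 for single terms and car's Anova", {
  long <- small_long()
  fit <- fit_mixed_model(long, "value", baseline_terms,
                         random_slopes = c("top_down", "bottom_up"),
                         focal = "top_down")
  wt <- wald_tests(fit)
  expect_equal(wt$term, baseline_terms)
  td <- fit$fixed[fit$fixed$term == "top_down", ]
  expect_equal(wt$chisq[wt$term == "top_down"], td$t^2, tolerance = 1e-6)
  ca <- car::Anova(fit$model, type = 3)
  ca <- ca[rownames(ca) != "(Intercept)", ]
  expect_equal(wt$chisq, as.numeric(ca$Chisq), tolerance = 1e-6)
})

test_that("interaction bundles carry the right degrees of freedom", {
  long <- small_long()
  # a three-level ROI factor interacting with a slope is a 2-df bundle
  fit <- fit_mixed_model(long, "value",
                         c(baseline_terms, "roi", "top_down:roi"),
                         random_slopes = "top_down", focal = "top_down")
  wt <- wald_tests(fit)
  expect_equal(wt$df[wt$term == "top_down:roi"], 2)
  expect_equal(wt$df[wt$term == "roi"], 2)
  expect_equal(wt$df[wt$term == "top_down"], 1)
})

test_that("per-cell slopes agree with emmeans trends", {
  long <- small_long()
  terms_ia <- c(baseline_terms, "top_down:roi_lifg_vs_pmtg",
                "top_down:roi_ba44_vs_ba45")
  fit <- fit_mixed_model(long, "value", terms_ia, random_slopes = "top_down",
                         focal = "top_down")
  by <- list(roi_lifg_vs_pmtg = c(BA44 = 0.5, BA45 = 0.5, LpMTG = -1),
             roi_ba44_vs_ba45 = c(BA44 = 1, BA45 = -1, LpMTG = 0))
  # the 3x3 grid contains the three observed ROI cells; check those
  pc <- pairwise_contrasts(fit, "top_down", by)
  et <- emmeans::emtrends(fit$model, ~ roi_lifg_vs_pmtg + roi_ba44_vs_ba45,
                          var = "top_down", lmer.df = "asymptotic",
                          at = list(roi_lifg_vs_pmtg = c(0.5, -1),
                                    roi_ba44_vs_ba45 = c(1, -1, 0)))
  et <- as.data.frame(et)
  for (roi in c("BA44", "BA45", "LpMTG")) {
    mine <- pc$cells[pc$cells$roi_lifg_vs_pmtg == roi &
                       pc$cells$roi_ba44_vs_ba45 == roi, ]
    code1 <- c(BA44 = 0.5, BA45 = 0.5, LpMTG = -1)[[roi]]
    code2 <- c(BA44 = 1, BA45 = -1, LpMTG = 0)[[roi]]
    ref <- et[abs(et$roi_lifg_vs_pmtg - code1) < 1e-9 &
                abs(et$roi_ba44_vs_ba45 - code2) < 1e-9, ]
    expect_equal(mine$slope, ref$top_down.trend, tolerance = 1e-6)
    expect_equal(mine$se, ref$SE, tolerance = 1e-6)
  }
})

test_that("deviation coding makes the interaction the modality difference", {
  long <- small_long()
  # assign half the participants to comprehension (balanced, between-subject)
  parts <- levels(long$participant)
  mod <- ifelse(seq_along(parts) %% 2 == 0, "production", "comprehension")
  names(mod) <- parts
  long$modality_dev <- code_factors(
    modality = mod[as.character(long$participant)])$modality_dev
  fit <- fit_mixed_model(long, "value",
                         c(baseline_terms, "modality_dev",
                           "top_down:modality_dev"),
                         random_slopes = "top_down", focal = "top_down")
  pc <- pairwise_contrasts(fit, "top_down",
                           list(modality_dev = c(production = 0.5,
                                                 comprehension = -0.5)))
  ia <- fit$fixed$estimate[fit$fixed$term == "top_down:modality_dev"]
  expect_equal(pc$contrasts$estimate[1], ia, tolerance = 1e-10)
  # cell slopes average to the main-effect slope under +-1/2 coding
  main <- fit$fixed$estimate[fit$fixed$term == "top_down"]
  expect_equal(mean(pc$cells$slope), main, tolerance = 1e-10)
})

test_that("model comparison ranks by AIC with valid likelihood-ratio tests", {
  long <- small_long()
  f_small <- fit_mixed_model(long, "value", baseline_terms[1:4],
                             random_slopes = "surprisal", focal = "surprisal")
  f_big <- fit_mixed_model(long, "value", baseline_terms,
                           random_slopes = "surprisal", focal = "surprisal")
  cmp <- compare_models(list(small = f_small, big = f_big))
  expect_equal(cmp$model[1], "big")  # true signal in top_down/bottom_up
  expect_equal(cmp$dAIC[1], 0)
  lrt <- cmp[cmp$model == "big", ]
  expect_equal(lrt$lrt_df, 2)
  expect_equal(lrt$lrt_chisq, 2 * (f_big$logLik - f_small$logLik),
               tolerance = 1e-10)
  # adding a fixed effect can only increase the ML log-likelihood
  expect_gte(f_big$logLik + 1e-6, f_small$logLik)
  # duplicated fit: zero AIC difference, no (0-df) LRT reported
  cmp2 <- compare_models(list(a = f_small, b = f_small))
  expect_equal(cmp2$dAIC, c(0, 0))
  expect_true(is.na(cmp2$lrt_chisq[2]))
  # differing observation sets are refused
  f_sub <- fit_mixed_model(long[1:1000, ], "value", baseline_terms[1:4],
                           random_slopes = "surprisal", focal = "surprisal")
  expect_error(compare_models(list(f_small, f_sub)), "observation")
})

test_that("REML fits with different fixed effects cannot be compared", {
  long <- small_long()
  f1 <- fit_mixed_model(long, "value", baseline_terms[1:4],
                        random_slopes = "surprisal", estimation = "REML")
  f2 <- fit_mixed_model(long, "value", baseline_terms,
                        random_slopes = "surprisal", estimation = "REML")
  expect_error(compare_models(list(f1, f2)), "REML")
})

test_that("the convergence fallback drops weak non-focal slopes only", {
  cfg <- fast_config(slope_sd = c(top_down = 0.4, bottom_up = 0))
  study <- simulate_study(5, 80, cfg, seed = 31)
  long <- stack_bold_design(study$bold, study$designs)
  fit <- fit_mixed_model(long, "value", baseline_terms,
                         random_slopes = c("top_down", "bottom_up"),
                         focal = "top_down")
  if (length(fit$dropped_slopes)) {
    expect_false("top_down" %in% fit$dropped_slopes)
    expect_true(all(fit$dropped_slopes %in% "bottom_up"))
  }
  expect_true("top_down" %in% names(fit$varcomp))
})
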
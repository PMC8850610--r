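test_that("resting FC handles degenerate and brute-force cases", {
  b <- simulate_roi_pair(590, signal_spec(target_r = -0.3), seed = 14)
  # identical series stay perfectly correlated through the offline pipeline
  expect_equal(resting_fc(b$roi1, b$roi1, b$motion, b$tissue_means), 1,
               tolerance = 1e-9)

  # equality with the independent brute-force pipeline
  for (seed in 1:3) {
    bb <- simulate_roi_pair(590,
                            signal_spec(target_r = -0.2,
                                        nuisance_amplitudes = c(global = 0.4,
                                                                csf = 0.2,
                                                                gm = 0.3),
                                        spike_volumes = c(120L, 380L)),
                            seed = seed)
    cfg <- fcnef_config()
    expect_equal(resting_fc(bb$roi1, bb$roi2, bb$motion, bb$tissue_means, cfg),
                 bf_resting_fc(bb$roi1, bb$roi2, bb$motion, bb$tissue_means,
                               cfg),
                 tolerance = 1e-6)
  }
})

test_that("scrubbing removes spike-borne artificial correlation", {
  # shared bursts with unequal amplitudes: not in the span of the motion
  # regressors or their derivatives, so only censoring can remove them
  errs <- sapply(1:10, function(seed) {
    b <- simulate_roi_pair(590, signal_spec(target_r = 0,
                                            spike_volumes = c(100L, 250L, 400L)),
                           seed = seed)
    art <- rep(0, 590); art[c(100, 250, 400)] <- c(10, 25, 40)
    roi1 <- b$roi1 + art; roi2 <- b$roi2 + art
    scrubbed <- resting_fc(roi1, roi2, b$motion, b$tissue_means)
    # same pipeline with the censoring disabled (threshold far above any FD)
    unscrubbed <- resting_fc(roi1, roi2, b$motion, b$tissue_means,
                             fcnef_config(fd_threshold_mm = 100))
    c(abs(scrubbed - 0), abs(unscrubbed - 0))
  })
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("change scores subtract Day 0 and drop incomplete participants", {
  sim <- simulate_cohort(cohort_spec(n_participants = 6L, seed = 31))
  tab <- as.data.frame(sim$cohort)
  tab$BDI[tab$participant_id == "P01" & tab$day == "Day0"] <- 20
  tab$BDI[tab$participant_id == "P01" & tab$day == "FCNefDay4"] <- 15
  cs <- change_scores(as_cohort_table(tab))
  expect_equal(cs$delta_BDI[cs$participant_id == "P01"], -5)

  # swapping the two days negates every change score
  swapped <- tab
  swapped$day[tab$day == "Day0"] <- "FCNefDay4"
  swapped$day[tab$day == "FCNefDay4"] <- "Day0"
  cs_sw <- change_scores(as_cohort_table(swapped))
  expect_equal(cs_sw$delta_BDI, -cs$delta_BDI)
  expect_equal(cs_sw$delta_rs_fc, -cs$delta_rs_fc)

  # a participant without the horizon row is dropped with a warning
  part <- tab[!(tab$participant_id == "P02" & tab$day == "FCNefDay4"), ]
  expect_warning(cs_p <- change_scores(as_cohort_table(part)), "P02")
  expect_false("P02" %in% cs_p$participant_id)
  expect_equal(nrow(cs_p), 5)
})

test_that("the 2-SD outlier rule is a single pass over all values", {
  # hand calculation: mean 20, sd ~44.7, |100 - 20| = 80 < 2 * 44.7 -> keep all
  v <- c(0, 0, 0, 0, 100)
  expect_equal(exclude_outliers(v, 2), rep(TRUE, 5))
  expect_equal(abs(v - mean(v)) <= 2 * sd(v), exclude_outliers(v, 2))

  # a genuinely extreme point is excluded
  v2 <- c(rnorm(20, sd = 0.1), 50)
  expect_false(exclude_outliers(v2, 2)[21])
  expect_true(all(exclude_outliers(v2, 2)[1:20]))

  expect_equal(exclude_outliers(rep(3, 5)), rep(TRUE, 5))
  expect_equal(exclude_outliers(c(-1, 1, -1), 2), rep(TRUE, 3))
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("the change model recovers noiseless slopes and reports ML likelihoods", {
  cs <- make_noiseless_changes(n = 12, beta = 20, intercept = -2)
  fit <- suppressWarnings(fit_change_model(cs, "BDI"))  # exact fit: lm warns
  expect_equal(unname(coef(fit)["delta_rs_fc"]), 20, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["(Intercept)"]), -2, tolerance = 1e-9)
  expect_equal(fit$n_used, 12)
  # F for the rs-FC term is enormous in the noiseless case
  expect_gt(fit$anova["delta_rs_fc", "F value"], 1e10)

  # AIC consistency: AIC = 2k - 2 logLik
  expect_equal(fit$AIC, 2 * attr(logLik(fit$fit), "df") - 2 * fit$logLik)

  # slope invariant under participant reordering
  fit_rev <- suppressWarnings(fit_change_model(cs[rev(seq_len(nrow(cs))), ], "BDI"))
  expect_equal(coef(fit_rev), coef(fit))

  expect_error(fit_change_model(cs, "weight"), "unknown outcome")
})

test_that("the experiment interaction model estimates separate slopes", {
  cs <- make_noiseless_changes(n = 16, beta = 10, intercept = 0)
  cs$delta_BDI <- cs$delta_BDI + 5 * (cs$experiment_id == 2L)
  fit <- suppressWarnings(
    fit_change_model(cs, "BDI", include_experiment_interaction = TRUE))
  co <- coef(fit)
  expect_equal(unname(co["delta_rs_fc"]), 10, tolerance = 1e-8)
  expect_equal(unname(co["experiment2"]), 5, tolerance = 1e-8)
  expect_equal(unname(co["delta_rs_fc:experiment2"]), 0, tolerance = 1e-6)
})

test_that("the likelihood-ratio test has the right df and degenerate behavior", {
  sim <- simulate_cohort(cohort_spec(beta = 20, residual_sd = 3, seed = 6))
  cs <- change_scores(sim$cohort)
  full <- fit_change_model(cs, "BDI", include_experiment_interaction = TRUE)
  red <- fit_change_model(cs, "BDI")
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 2)  # experiment main effect + interaction
  expect_gte(lrt$chi2, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  # the AIC difference identity: chi2 = AIC_red - AIC_full + 2 df
  expect_equal(lrt$chi2, lrt$aic_reduced - lrt$aic_full + 2 * lrt$df,
               tolerance = 1e-9)

  same <- likelihood_ratio_test(red, red)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
})

test_that("leave-one-out prediction is exact on noiseless cohorts", {
  cs <- make_noiseless_changes(n = 10, beta = 20, intercept = -2)
  loo <- loo_predict(cs, "BDI")
  expect_equal(loo$predicted, loo$actual, tolerance = 1e-8)
  expect_equal(loo$r, 1, tolerance = 1e-9)
  expect_error(loo_predict(make_noiseless_changes(n = 4), "BDI"), "at least 5")
})

test_that("change correlations match a hand-computed five-pair table", {
  cs <- make_noiseless_changes(n = 5)
  cs$delta_rs_fc <- c(-0.2, -0.1, 0.0, 0.1, 0.3)
  cs$delta_BDI <- c(-6, -5, -1, 2, 3)
  out <- correlate_changes(cs, "BDI", exclude_outliers = FALSE)
  expect_equal(out$r, bf_pearson(cs$delta_rs_fc, cs$delta_BDI),
               tolerance = 1e-12)
  expect_equal(out$n, 5)

  lin <- make_noiseless_changes(n = 8, beta = 5)
  expect_equal(correlate_changes(lin, "BDI")$r, 1, tolerance = 1e-9)

  flat <- make_noiseless_changes(n = 6, beta = 0)
  expect_error(correlate_changes(flat, "BDI"), "zero variance")
})

test_that("the repeated-measures task model recovers planted day effects", {
  participants <- sprintf("P%02d", 1:19)
  days <- 1:4
  grid <- expand.grid(participant_id = participants, day = days,
                      stringsAsFactors = FALSE)
  # planted: intercept 50, +3 points per day, near-noiseless
  set.seed(60)
  grid$score <- 50 + 3 * grid$day + rnorm(nrow(grid), sd = 0.01)
  fit <- suppressMessages(repeated_measures_task_model(grid))
  expect_equal(unname(coef(fit)["day"]), 3, tolerance = 1e-2)

  # with participant-specific intercepts, the day slope survives
  set.seed(61)
  shift <- setNames(rnorm(19, sd = 5), participants)
  grid$score <- 50 + shift[grid$participant_id] + 3 * grid$day +
    rnorm(nrow(grid), sd = 1)
  fit2 <- repeated_measures_task_model(grid)
  expect_equal(unname(coef(fit2)["day"]), 3, tolerance = 0.5)
  expect_gt(fit2$varcomp[["participant_id"]], 1)
  expect_lt(fit2$anova["day", "Pr(>F)"], 0.001)

  one_day <- grid[grid$day == 1, ]
  expect_error(repeated_measures_task_model(one_day), "two days")
})
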
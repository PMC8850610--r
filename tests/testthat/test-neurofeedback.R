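test_that("Fisher transform matches its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(inverse_fisher(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("trial FC is exact in degenerate limits and shift-invariant", {
  sched <- trial_schedule(n_trials = 1)
  sess <- simulate_session(sched, -0.3, signal_spec(target_r = 0), seed = 9)
  seg <- sess$segments
  tw <- c(seg$trials$induction_used_start[1], seg$trials$induction_used_end[1])

  # identical ROI signals correlate perfectly through the whole pipeline
  expect_equal(trial_fc(sess$roi1, sess$roi1, tw, seg$rest_used), 1,
               tolerance = 1e-9)

  # constant offsets never change the correlation
  r0 <- trial_fc(sess$roi1, sess$roi2, tw, seg$rest_used, sess$nuisance)
  r_off <- trial_fc(sess$roi1 + 100, sess$roi2 - 42, tw, seg$rest_used,
                    sess$nuisance)
  expect_equal(r_off, r0, tolerance = 1e-9)
  expect_true(abs(r0) <= 1)

  expect_error(trial_fc(sess$roi1, sess$roi2, c(10, 11), seg$rest_used),
               "at least 3")
})

test_that("trial FC equals an independent brute-force pipeline", {
  cfg <- fcnef_config()
  sched <- trial_schedule(n_trials = 2)
  for (seed in 1:4) {
    sess <- simulate_session(sched, c(-0.5, 0.2),
                             signal_spec(target_r = 0,
                                         nuisance_amplitudes = c(global = 0.4,
                                                                 csf = 0.2,
                                                                 gm = 0.3)),
                             seed = seed)
    seg <- sess$segments
    for (i in 1:2) {
      tw <- c(seg$trials$induction_used_start[i],
              seg$trials$induction_used_end[i])
      r_pkg <- trial_fc(sess$roi1, sess$roi2, tw, seg$rest_used,
                        sess$nuisance, cfg)
      r_bf <- bf_trial_fc(sess$roi1, sess$roi2, tw, seg$rest_used,
                          sess$nuisance, cfg)
      expect_equal(r_pkg, r_bf, tolerance = 1e-6)
    }
  }
})

test_that("trial FC recovers a planted induction correlation on average", {
  sched <- trial_schedule()
  set.seed(99)
  means <- replicate(34, {
    sess <- simulate_session(sched, rep(-0.6, 6), signal_spec(target_r = 0),
                             seed = sample.int(2^30, 1))
    seg <- sess$segments
    mean(sapply(1:6, function(i) {
      trial_fc(sess$roi1, sess$roi2,
               c(seg$trials$induction_used_start[i],
                 seg$trials$induction_used_end[i]),
               seg$rest_used, sess$nuisance)
    }))
  })
  expect_equal(mean(means), -0.6, tolerance = 0.05)  # ~200 trials
})

test_that("baseline statistics are Fisher-z means with symmetric anchors", {
  b <- compute_baseline(c(0.3, -0.3))
  expect_equal(b$mean_z, 0)
  expect_equal(b$mean_r, 0)
  expect_equal(b$lower_anchor_r, -b$upper_anchor_r)
  expect_equal(b$n_trials_used, 2L)

  # direct computation on the z values
  rs <- c(0.3, -0.1, 0.2, 0.05, -0.25)
  b2 <- compute_baseline(rs)
  expect_equal(b2$mean_z, mean(atanh(rs)))
  expect_equal(b2$sd_z, sd(atanh(rs)))
  expect_equal(b2$mean_r, tanh(mean(atanh(rs))))
  expect_equal(b2$lower_anchor_r, tanh(mean(atanh(rs)) - sd(atanh(rs))))

  expect_error(compute_baseline(rep(0.4, 6)), "zero variance")
  expect_error(compute_baseline(0.4), "at least two")
})

test_that("baseline z-mean is recovered from sampled trials", {
  set.seed(17)
  errs <- replicate(100, {
    z <- rnorm(30, mean = 0.1, sd = 0.2)
    compute_baseline(tanh(z))$mean_z - 0.1
  })
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("the score map hits the three printed anchors and is monotone", {
  b <- compute_baseline(c(0.3, -0.3, 0.1, -0.1))
  expect_equal(score_trial(b$mean_r, b), 50)
  expect_equal(score_trial(b$lower_anchor_r, b), 100)
  expect_equal(score_trial(b$upper_anchor_r, b), 0)
  # clamped beyond the anchors
  expect_equal(score_trial(b$lower_anchor_r - 0.2, b), 100)
  expect_equal(score_trial(-0.99, b), 100)
  expect_equal(score_trial(b$upper_anchor_r + 0.2, b), 0)
  expect_equal(score_trial(0.99, b), 0)
  # midway in z between mean and the lower anchor -> 75
  expect_equal(score_trial(tanh(b$mean_z - b$sd_z / 2), b), 75)

  # nonincreasing in r, bounded in [0, 100]
  grid <- seq(-0.999, 0.999, length.out = 400)
  sc <- score_trial(grid, b)
  expect_true(all(diff(sc) <= 1e-12))
  expect_true(all(sc >= 0 & sc <= 100))

  # r-space anchor alternative behaves the same at the anchors
  br <- compute_baseline(c(0.3, -0.3, 0.1, -0.1), anchor_space = "r")
  expect_equal(score_trial(br$mean_r, br), 50)
  expect_equal(score_trial(br$lower_anchor_r, br), 100)
  expect_equal(score_trial(br$upper_anchor_r, br), 0)
})

test_that("SHAM draws follow the published Normal(50, 30.3) and are seed-stable", {
  cfg <- fcnef_config()
  set.seed(123)
  d <- sham_score(1e5, cfg)
  expect_equal(mean(d$raw), 50, tolerance = 0.5)
  expect_equal(sd(d$raw), 30.3, tolerance = 0.5)
  expect_true(all(d$display >= 0 & d$display <= 100))
  expect_true(any(d$raw < 0) || any(d$raw > 100))  # raw kept unclamped

  set.seed(77); a <- sham_score(10, cfg)
  set.seed(77); b <- sham_score(10, cfg)
  expect_identical(a, b)
})

test_that("session scoring composes trial FC with the score map", {
  sched <- trial_schedule()
  base <- compute_baseline(c(0.25, -0.05, 0.1, -0.2, 0.05, -0.1))
  sess <- simulate_session(sched, rep(-0.5, 6), signal_spec(target_r = 0),
                           seed = 41)
  scores <- run_fcnef_session(sess, base)
  expect_equal(nrow(scores), 6)
  expect_equal(scores$score, score_trial(scores$r, base))
  expect_equal(attr(scores, "mean_score"), mean(scores$score))

  # SHAM mode reproduces the seeded draw sequence
  set.seed(55)
  sham <- run_fcnef_session(sess, baseline = NULL, sham = TRUE)
  set.seed(55)
  expected <- sham_score(6, fcnef_config())$display
  expect_equal(sham$score, expected)

  # more anticorrelated induction periods earn higher scores on average
  easy <- simulate_session(sched, rep(-0.8, 6), signal_spec(target_r = 0),
                           seed = 42)
  hard <- simulate_session(sched, rep(0.2, 6), signal_spec(target_r = 0),
                           seed = 42)
  expect_gt(attr(run_fcnef_session(easy, base), "mean_score"),
            attr(run_fcnef_session(hard, base), "mean_score"))
})
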
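test_that("membership ramps hit their anchor values", {
  th <- stagingThresholds()
  # SWS delta membership: 0 at <= 0.5, 1 at >= 1, midpoint 0.5 at 0.75
  s <- stageMembership(feat_row(0.75, 0.5, 0.5), th)
  expect_equal((s$SWS * 3) - 1 - 1, 0.5)   # delta part after removing
                                           # saturated theta & EMG parts
  low <- stageMembership(feat_row(0.3, 0.5, 0.5), th)
  expect_equal(low$SWS, 2 / 3)             # delta part 0
  hi <- stageMembership(feat_row(1.2, 0.5, 0.5), th)
  expect_equal(hi$SWS, 1)                  # fully saturated SWS
  # paradoxical saturation: low delta, high theta:delta, low EMG
  par <- stageMembership(feat_row(0.3, 3.5, 0.5), th)
  expect_equal(par$PARADOXICAL, 1)
  expect_lt(par$WAKE, 1)
  expect_lt(par$SWS, 1)
  # wake saturation on delta/theta plus EMG at the wake anchor
  wk <- stageMembership(feat_row(0.3, 0.5, 2.4), th)
  expect_equal(wk$WAKE, 1)
})

test_that("memberships are monotone in their driving feature", {
  th <- stagingThresholds()
  d <- seq(0, 2, by = 0.05)
  sws <- stageMembership(feat_row(d, 0.5, 0.5), th)$SWS
  expect_true(all(diff(sws) >= 0))
  t <- seq(0, 5, by = 0.1)
  par <- stageMembership(feat_row(0.3, t, 0.5), th)$PARADOXICAL
  expect_true(all(diff(par) >= 0))
  m <- seq(0, 3.5, by = 0.1)
  wak <- stageMembership(feat_row(0.3, 0.5, m), th)$WAKE
  expect_true(all(diff(wak) >= 0))
  expect_error(stagingThresholds(deltaLow = 1.5), "ordered")
})

test_that("activity and EMG overrides force active wake", {
  th <- stagingThresholds()
  f <- feat_row(1.2, 0.5, 0.5, a = 0.2)   # would be SWS by scores
  expect_equal(classifyEpoch(stageMembership(f, th), f, th), "ACTIVE_WAKE")
  f2 <- feat_row(0.3, 0.5, 4.0)           # 4.0 >= 1.5 * 2.4 = 3.6
  expect_equal(classifyEpoch(stageMembership(f2, th), f2, th), "ACTIVE_WAKE")
  f3 <- feat_row(0.3, 0.5, 3.0)           # below the override, wake by score
  expect_equal(classifyEpoch(stageMembership(f3, th), f3, th), "WAKE")
  # plain arg-max with ties broken WAKE > SWS > PARADOXICAL
  sc <- data.frame(WAKE = 0.2, SWS = 0.9, PARADOXICAL = 0.3)
  expect_equal(classifyEpoch(sc, feat_row(1, 0.1, 0.5), th), "SWS")
  tie <- data.frame(WAKE = 0.5, SWS = 0.5, PARADOXICAL = 0.5)
  expect_equal(classifyEpoch(tie, feat_row(0.7, 1, 1), th), "WAKE")
})

test_that("the classifier returns the forced stage on saturated feature grids", {
  th <- stagingThresholds()
  grid <- expand.grid(d = c(0.3, 1.2), t = c(0.5, 3.5), m = c(0.5, 4.0),
                      a = c(0, 0.2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    f <- feat_row(g$d, g$t, g$m, g$a)
    sc <- stageMembership(f, th)
    got <- classifyEpoch(sc, f, th)
    # expected label derived independently from the rule definitions
    if (g$a > 0.1 || g$m >= 3.6) {
      expect_identical(got, "ACTIVE_WAKE")
    } else {
      sat <- c(WAKE = g$d <= 0.5 && g$t <= 1.3 && g$m >= 2.4,
               SWS = g$d >= 1 && g$t <= 1.3 && g$m <= 1,
               PARADOXICAL = g$d <= 0.5 && g$t >= 3 && g$m <= 1)
      if (sum(sat) == 1) expect_identical(got, names(sat)[sat])
    }
  }
})

test_that("epoch features are exact on constructed recordings", {
  # identical epochs: all ratios are exactly 1
  one <- sine_recording(freq = 2, amp = 80, duration = 100)
  one@emg <- sin(2 * pi * 50 * seq_len(50000) / 500) * 40
  f <- computeEpochFeatures(one, 10)
  expect_equal(f$delta_ratio, rep(1, 10))
  expect_equal(f$emg_ratio, rep(1, 10))
  expect_equal(f$mean_activity, rep(0, 10))
  # doubling delta amplitude in one epoch quadruples its delta ratio
  rec <- sine_recording(freq = 2, amp = 80, duration = 100)
  rec@eeg[10001:15000] <- 2 * rec@eeg[10001:15000]   # epoch 3
  rec@emg <- one@emg
  f2 <- computeEpochFeatures(rec, 10)
  expect_equal(f2$delta_ratio[3] / f2$delta_ratio[1], 4, tolerance = 0.01)
  # flat recording is rejected
  flat <- Recording(eeg = numeric(50000), emg = numeric(50000),
                    eegRate = 500)
  expect_error(computeEpochFeatures(flat, 10), "flat")
})

test_that("hypnogram percentages are permutation-invariant and sum to 100", {
  set.seed(31)
  labs <- sample(c("WAKE", "SWS", "PARADOXICAL", "ACTIVE_WAKE", "ARTIFACT"),
                 200, replace = TRUE)
  h1 <- ephysuite:::Hypnogram(10, labs)
  h2 <- ephysuite:::Hypnogram(10, sample(labs))
  expect_equal(sum(stagePercentages(h1)), 100)
  expect_equal(stagePercentages(h1), stagePercentages(h2))
})

test_that("a session generated in one stage regime scores as that stage", {
  cfg <- eegSynthConfig(duration = 300,
                        transitionMatrix = diag(4)[c(3, 3, 3, 3), ],
                        spikeTrainsPerHour = 0, seed = 17)
  sim <- simulateEEGSession(cfg)
  expect_true(all(sim$truth$stages == "SWS"))
  hyp <- scoreHypnogram(sim$recording)
  expect_equal(unname(stagePercentages(hyp)["SWS"]), 100)
})

test_that("staging accuracy is high at feature-regime centres with noise", {
  set.seed(32)
  th <- stagingThresholds()
  centres <- list(WAKE = c(d = 0.25, t = 0.9, m = 2.8),
                  SWS = c(d = 1.4, t = 0.6, m = 0.6),
                  PARADOXICAL = c(d = 0.25, t = 3.4, m = 0.6))
  n_per <- 300
  correct <- 0
  for (stage in names(centres)) {
    c0 <- centres[[stage]]
    # noise SD = 10% of each feature's ramp width
    f <- data.frame(epoch_index = seq_len(n_per),
                    delta_ratio = pmax(0, c0["d"] + rnorm(n_per, 0, 0.05)),
                    theta_delta_ratio = pmax(0, c0["t"] + rnorm(n_per, 0, 0.17)),
                    emg_ratio = pmax(0, c0["m"] + rnorm(n_per, 0, 0.14)),
                    mean_activity = 0, artifact = FALSE)
    got <- classifyEpoch(stageMembership(f, th), f, th)
    correct <- correct + sum(got == stage)
  }
  expect_gte(correct / (3 * n_per), 0.95)
})
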
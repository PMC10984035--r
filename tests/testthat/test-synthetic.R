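test_that("simulators are bit-identical under the same seed", {
  cfg <- eegSynthConfig(duration = 120, seed = 51)
  a <- simulateEEGSession(cfg)
  b <- simulateEEGSession(cfg)
  expect_identical(eeg(a$recording), eeg(b$recording))
  expect_identical(emg(a$recording), emg(b$recording))
  expect_identical(activity(a$recording), activity(b$recording))
  expect_identical(a$truth$stages, b$truth$stages)
  c <- simulateEEGSession(eegSynthConfig(duration = 120, seed = 52))
  expect_false(identical(eeg(a$recording), eeg(c$recording)))

  m1 <- simulateMEARaster(meaSynthConfig(nElectrodes = 32, duration = 30,
                                         seed = 53))
  m2 <- simulateMEARaster(meaSynthConfig(nElectrodes = 32, duration = 30,
                                         seed = 53))
  expect_identical(spikeTimes(m1$raster), spikeTimes(m2$raster))
  expect_identical(m1$truth$burstPeaks, m2$truth$burstPeaks)
})

test_that("band-limited noise hits its target power in band", {
  set.seed(54)
  x <- bandNoise(50000, 500, lo = 0.5, hi = 4, rms = 20)
  expect_equal(sd(x), 20, tolerance = 0.1)
  sp <- computePSD(x, 500, window = "rectangular")
  expect_gt(bandPower(sp, 0.5, 4) / (sum(psd(sp)) * (500 / 50000)), 0.97)
})

test_that("a degenerate transition matrix pins the chain to one stage", {
  cfg <- eegSynthConfig(duration = 200,
                        transitionMatrix = diag(4)[c(2, 2, 2, 2), ],
                        seed = 55)
  sim <- simulateEEGSession(cfg)
  expect_true(all(sim$truth$stages == "WAKE"))
})

test_that("Markov occupancy converges to the stationary distribution", {
  # stay = 0.3 shortens bouts so 720 epochs give ~400 effective samples
  cfg <- eegSynthConfig(duration = 7200, stay = 0.3, seed = 56,
                        spikeTrainsPerHour = 0)
  sim <- simulateEEGSession(cfg)
  occ <- table(factor(sim$truth$stages,
                      levels = c("ACTIVE_WAKE", "WAKE", "SWS",
                                 "PARADOXICAL"))) / 720
  expect_lt(max(abs(as.numeric(occ) - cfg$occupancy)), 0.08)
})

test_that("stage regimes reach the staging anchors within a mixed session", {
  # ratios are referenced to the whole-session median, so fidelity is a
  # conditional statement: given the true stage, the feature should land
  # on that stage's side of its anchors in nearly all epochs
  cfg <- eegSynthConfig(duration = 7200, spikeTrainsPerHour = 0, seed = 57)
  sim <- simulateEEGSession(cfg)
  f <- computeEpochFeatures(sim$recording, 10)
  s <- sim$truth$stages
  expect_gte(mean(f$delta_ratio[s == "SWS"] >= 1), 0.85)
  expect_gte(mean(f$delta_ratio[s == "WAKE"] <= 0.5), 0.95)
  expect_gte(mean(f$theta_delta_ratio[s == "PARADOXICAL"] >= 3), 0.95)
  expect_gte(mean(f$theta_delta_ratio[s == "WAKE"] <= 3), 0.95)
  expect_gte(mean(f$emg_ratio[s == "PARADOXICAL"] <= 1), 0.95)
})

test_that("planted spike trains are recovered by the detector", {
  cfg <- eegSynthConfig(duration = 1800, spikeTrainsPerHour = 40, seed = 59)
  sim <- simulateEEGSession(cfg)
  sp <- detectSpikes(eeg(sim$recording), 500)
  m <- matchEventTimes(sim$truth$spikeOnsets, sp$onset_s, tolerance = 0.02)
  expect_gte(m$recall, 0.95)
})

test_that("doubling delta amplitude doubles mean delta power downstream", {
  base <- eegSynthConfig(duration = 300,
                         transitionMatrix = diag(4)[c(2, 2, 2, 2), ],
                         spikeTrainsPerHour = 0, seed = 60)
  het <- injectGenotypeEffect(base, "HET",
                              effects = list(sws_occupancy_mult = 1))
  expect_equal(het$bandAmps[, "delta"], base$bandAmps[, "delta"] * sqrt(2))
  p_wt <- bandPowerTimecourse(simulateEEGSession(base)$recording)$means
  p_het <- bandPowerTimecourse(simulateEEGSession(het)$recording)$means
  expect_equal(p_het[["delta"]] / p_wt[["delta"]], 2, tolerance = 0.15)
  expect_equal(p_het[["gamma"]] / p_wt[["gamma"]], 1, tolerance = 0.15)
  # WT mapping is the identity
  expect_identical(injectGenotypeEffect(base, "WT"), base)
})

test_that("Poisson background totals and silent-background bursts behave", {
  sim <- simulateMEARaster(meaSynthConfig(nElectrodes = 200, duration = 60,
                                          backgroundRate = 0.5,
                                          burstRate = 0, seed = 61))
  expected <- 200 * 0.5 * 60
  expect_lt(abs(nSpikes(sim$raster) - expected), 3 * sqrt(expected))
  # zero background: every spike lies within 4 sigma of a planted peak
  sb <- simulateMEARaster(meaSynthConfig(nElectrodes = 50, duration = 120,
                                         backgroundRate = 0, burstRate = 3,
                                         seed = 62))
  ts <- unlist(spikeTimes(sb$raster))
  expect_gt(length(ts), 0)
  near <- vapply(ts, function(s)
    min(abs(s - sb$truth$burstPeaks)) <= 4 * 0.1 + 1e-9, logical(1))
  expect_true(all(near))
  # doubling the burst rate roughly doubles the planted count
  hi <- simulateMEARaster(meaSynthConfig(nElectrodes = 50, duration = 120,
                                         backgroundRate = 0, burstRate = 6,
                                         seed = 62))
  expect_gt(length(hi$truth$burstPeaks), length(sb$truth$burstPeaks))
})

test_that("configs validate their invariants", {
  expect_error(eegSynthConfig(duration = -1), "positive")
  bad <- matrix(0.3, 4, 4)
  expect_error(eegSynthConfig(transitionMatrix = bad), "stochastic")
  expect_error(meaSynthConfig(participationFraction = 1.5), "\\[0, 1\\]")
  expect_error(injectGenotypeEffect(eegSynthConfig(duration = 10), "HET",
                                    effects = list(delta_amp_mult = -1)),
               "positive")
})
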
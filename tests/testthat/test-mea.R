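test_that("raster CSV round trip preserves spikes, metadata and sorting", {
  set.seed(41)
  st <- list(sort(runif(10, 0, 300)), sort(runif(10, 0, 300)),
             sort(runif(10, 0, 300)))
  ras <- SpikeRaster(c(5L, 9L, 11L), st, 300,
                     list(nElectrodesTotal = 26400L, div = 21L,
                          genotype = "HET"))
  expect_equal(nSpikes(ras), 30)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRaster(ras, path)
  back <- readRaster(path)
  expect_equal(electrodeIDs(back), electrodeIDs(ras))
  expect_equal(spikeTimes(back), spikeTimes(ras), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(recDuration(back), 300)
  expect_equal(chipMetadata(back)$genotype, "HET")
  expect_equal(chipMetadata(back)$div, 21L)
  # unsorted rows come back sorted; out-of-range times are rejected
  writeLines(c("# duration_s=10", "electrode_id,spike_time_s",
               "1,5.0", "1,2.0", "2,8.0"), path)
  expect_equal(spikeTimes(readRaster(path))[[1]], c(2, 5))
  writeLines(c("# duration_s=10", "electrode_id,spike_time_s", "1,12.0"),
             path)
  expect_error(readRaster(path), "outside")
})

test_that("activity-scan rates are count over duration", {
  ras <- SpikeRaster(1:3, list(seq(0.5, 29.5, by = 1), numeric(0), 1:15),
                     30)
  s <- activityScanSummary(ras)
  expect_equal(s$rates$rate_hz, c(1, 0, 0.5))
  expect_equal(s$max_rate_hz, 1)
  expect_equal(s$mean_rate_hz, 0.5)
})

test_that("Poisson firing rates are unbiased across many electrodes", {
  set.seed(42)
  sim <- simulateMEARaster(meaSynthConfig(nElectrodes = 1000, duration = 30,
                                          backgroundRate = 2, burstRate = 0,
                                          seed = 42))
  s <- activityScanSummary(sim$raster)
  se <- sqrt(2 / 30 / 1000)          # SE of the mean rate
  expect_lt(abs(s$mean_rate_hz - 2), 3 * se)
})

test_that("top-electrode selection ranks by rate with id tie-breaks", {
  rates <- data.frame(electrode_id = 1:5, rate_hz = c(1, 3, 2, 0, 3))
  expect_equal(selectTopElectrodes(rates, 2), c(2L, 5L))
  ties <- data.frame(electrode_id = 5:1, rate_hz = rep(1, 5))
  expect_equal(selectTopElectrodes(ties, 2), c(1L, 2L))   # lower ids win
  expect_warning(sel <- selectTopElectrodes(rates, 10), "available")
  expect_length(sel, 5)
})

test_that("network activity equals direct discrete convolution", {
  set.seed(43)
  ras <- SpikeRaster(1:5, lapply(1:5, function(i) sort(runif(40, 0, 20))),
                     20)
  got <- networkActivity(ras, bin = 0.01, sigma = 0.1)
  want <- oracle_network_activity(ras, bin = 0.01, sigma = 0.1)
  expect_equal(got$time_s, want$time_s)
  expect_lt(max(abs(got$rate_hz - want$rate_hz)), 1e-9)
  # single spike: a Gaussian bump peaking at the spike's bin
  one <- SpikeRaster(1L, list(10.005), 20)
  tr1 <- networkActivity(one, 0.01, 0.1)
  expect_equal(tr1$time_s[which.max(tr1$rate_hz)], 10.005)
  expect_equal(max(tr1$rate_hz), dnorm(0, sd = 0.1), tolerance = 1e-9)
  # linearity: two simultaneous spikes double the trace
  two <- SpikeRaster(1:2, list(10.005, 10.005), 20)
  expect_equal(networkActivity(two, 0.01, 0.1)$rate_hz, 2 * tr1$rate_hz)
  # empty raster: identically zero
  expect_true(all(networkActivity(SpikeRaster(1L, list(numeric(0)), 20),
                                  0.01, 0.1)$rate_hz == 0))
})

test_that("the trace integrates to the total spike count", {
  set.seed(44)
  ras <- SpikeRaster(1:20, lapply(1:20, function(i)
    sort(runif(50, 1, 59))), 60)
  tr <- networkActivity(ras, 0.01, 0.1)
  expect_equal(sum(tr$rate_hz) * 0.01, nSpikes(ras), tolerance = 1e-4)
})

test_that("burst detection finds planted bursts and skips weak bumps", {
  set.seed(45)
  cfg <- meaSynthConfig(nElectrodes = 64, duration = 60, backgroundRate = 1,
                        burstRate = 0, seed = 45)
  sim <- simulateMEARaster(cfg)
  st <- spikeTimes(sim$raster)
  for (p in c(10, 20)) {   # plant two strong synchronous bursts by hand
    for (e in seq_len(40))
      st[[e]] <- sort(c(st[[e]], rnorm(8, p, 0.05)))
  }
  ras <- SpikeRaster(electrodeIDs(sim$raster), st, 60)
  tr <- networkActivity(ras)
  b <- detectBursts(tr, ras)
  expect_equal(nrow(b), 2)
  expect_lt(max(abs(b$peak_time_s - c(10, 20))), 0.02)   # within 2 bins
  expect_true(all(b$spike_count > 100))
  expect_true(all(b$n_active_electrodes >= 40))
  # a flat trace yields no bursts
  flat <- SpikeRaster(1L, list(seq(0.5, 59.5, by = 0.5)), 60)
  expect_equal(nrow(detectBursts(networkActivity(flat), flat)), 0)
})

test_that("burst metrics follow the worked IBI example", {
  b <- data.frame(peak_time_s = c(10, 20, 35), start_s = c(9.9, 19.9, 34.9),
                  end_s = c(10.2, 20.2, 35.2),
                  duration_s = rep(0.3, 3), peak_rate_hz = 1,
                  spike_count = c(100, 120, 80), n_active_electrodes = 50)
  m <- burstMetrics(b)
  expect_equal(m$n_bursts, 3)
  expect_equal(m$mean_ibi_s, 12.5)          # gaps 10 and 15
  expect_equal(m$mean_duration_s, 0.3)
  expect_equal(m$mean_spikes_per_burst, 100)
  expect_true(is.na(burstMetrics(b[1, ])$mean_ibi_s))
  empty <- burstMetrics(b[0, ])
  expect_equal(empty$n_bursts, 0)
  expect_true(is.na(empty$mean_ibi_s))
})

test_that("more planted bursts are never detected as fewer", {
  counts <- vapply(c(2, 4, 8), function(br) {
    sim <- simulateMEARaster(meaSynthConfig(nElectrodes = 64, duration = 120,
                                            backgroundRate = 0, burstRate = br,
                                            seed = 46))
    tr <- networkActivity(sim$raster)
    nrow(detectBursts(tr, sim$raster))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
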
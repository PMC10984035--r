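#' @include signal-io.R spectral.R eeg-events.R sleep-staging.R mea.R
NULL

#' Run the full analysis pipeline over a cohort
#'
#' For every recording: artifact mask, per-band mean powers (10 s
#' epochs), spike/spike-train summaries and hypnogram stage percentages.
#' For every raster: network-activity trace, burst detection and burst
#' metrics. When at least two subjects per genotype are present for a
#' metric, a pooled t-test between genotypes is added; with a single
#' subject (or one genotype) the statistics are skipped with a warning
#' and the per-subject tables are still produced. Every parameter used is
#' echoed in the returned `params` so a run is fully reproducible.
#'
#' @param recordings list of [Recording-class] objects or file paths
#'   (EDF/TSV).
#' @param rasters list of [SpikeRaster-class] objects or file paths
#'   (CSV).
#' @param epochLength band/staging epoch, seconds.
#' @param bands band table from [eegBands()].
#' @param thresholds staging thresholds from [stagingThresholds()].
#' @param spikeArgs,burstArgs named lists of overrides for
#'   [detectSpikes()]/[groupSpikeTrains()] and
#'   [networkActivity()]/[detectBursts()].
#' @return list with `eeg` (per-subject metric table, long format:
#'   `subject_id`, `genotype`, `metric`, `value`), `mea` (likewise per
#'   chip), `stats` (list of t-test results per metric, possibly empty)
#'   and `params`.
#' @export
runPipeline <- function(recordings = list(), rasters = list(),
                        epochLength = 10, bands = eegBands(),
                        thresholds = stagingThresholds(),
                        spikeArgs = list(), burstArgs = list()) {
  if (!length(recordings) && !length(rasters))
    stop("need at least one recording or raster")
  sa <- utils::modifyList(list(threshold = 200, minDur = 1, maxDur = 200,
                               intervalMin = 0.05, intervalMax = 0.5,
                               minSpikes = 3, minTrainDuration = 1), spikeArgs)
  ba <- utils::modifyList(list(bin = 0.01, sigma = 0.1, thresholdMult = 7,
                               boundaryFrac = 0.1), burstArgs)

  eeg_rows <- list()
  for (rec in recordings) {
    if (is.character(rec)) rec <- readRecording(rec)
    mask <- markArtifacts(rec, epochLength)
    bp <- bandPowerTimecourse(rec, bands, epochLength, mask)
    sp <- detectSpikes(eeg(rec), eegRate(rec), sa$threshold, sa$minDur,
                       sa$maxDur)
    tr <- groupSpikeTrains(sp, sa$intervalMin, sa$intervalMax,
                           sa$minSpikes, sa$minTrainDuration)
    ts <- summarizeTrains(tr)
    hyp <- tryCatch(scoreHypnogram(rec, mask, thresholds, epochLength),
                    error = function(e) NULL)
    vals <- c(setNames(as.numeric(bp$means),
                       paste0(names(bp$means), "_power_uV2")),
              spike_count = nrow(sp),
              spike_train_count = ts$train_count,
              total_train_duration_s = ts$total_train_duration,
              if (!is.null(hyp))
                setNames(as.numeric(stagePercentages(hyp)),
                         paste0("pct_", names(stagePercentages(hyp)))))
    eeg_rows[[length(eeg_rows) + 1L]] <-
      data.frame(subject_id = subjectID(rec), genotype = genotype(rec),
                 metric = names(vals), value = as.numeric(vals),
                 row.names = NULL)
  }

  mea_rows <- list()
  for (ras in rasters) {
    if (is.character(ras)) ras <- readRaster(ras)
    trace <- networkActivity(ras, ba$bin, ba$sigma)
    bursts <- detectBursts(trace, ras, ba$thresholdMult, ba$boundaryFrac)
    bm <- burstMetrics(bursts)
    md <- chipMetadata(ras)
    vals <- c(n_bursts = bm$n_bursts, mean_ibi_s = bm$mean_ibi_s,
              mean_burst_duration_s = bm$mean_duration_s,
              mean_spikes_per_burst = bm$mean_spikes_per_burst)
    mea_rows[[length(mea_rows) + 1L]] <-
      data.frame(subject_id = if (!is.null(md$chipID)) md$chipID else
                   paste0("chip", length(mea_rows) + 1L),
                 genotype = if (!is.null(md$genotype)) md$genotype else
                   "UNSPECIFIED",
                 metric = names(vals), value = as.numeric(vals),
                 row.names = NULL)
  }

  eeg_tab <- if (length(eeg_rows)) do.call(rbind, eeg_rows) else NULL
  mea_tab <- if (length(mea_rows)) do.call(rbind, mea_rows) else NULL
  stats_out <- list()
  for (tab in list(eeg = eeg_tab, mea = mea_tab)) {
    if (is.null(tab)) next
    for (m in unique(tab$metric)) {
      sub <- tab[tab$metric == m & is.finite(tab$value), ]
      ok <- length(unique(sub$genotype)) == 2L &&
        all(table(sub$genotype) >= 2L)
      if (ok) stats_out[[m]] <- ttestBetweenGenotypes(sub, m)
    }
  }
  if (!length(stats_out))
    warning("fewer than 2 subjects per genotype: group statistics skipped")
  list(eeg = eeg_tab, mea = mea_tab, stats = stats_out,
       params = list(epochLength = epochLength, bands = bands,
                     thresholds = thresholds, spike = sa, burst = ba))
}
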
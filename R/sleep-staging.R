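#' @include AllClasses.R spectral.R
NULL

#' Sleep-staging thresholds
#'
#' The anchor values of the rule-based scorer. Each feature contributes a
#' piecewise-linear membership that is 0 at one anchor, 1 at the other and
#' linear in between ("maximum probability at ratio X" semantics):
#' \itemize{
#' \item delta ratio: paradoxical/wake membership maximal at 0.5 and
#'   below, slow-wave-sleep membership maximal at 1 and above;
#' \item theta:delta ratio: wake/SWS membership maximal at 1.3 and below,
#'   paradoxical membership maximal at 3 and above;
#' \item EMG ratio: paradoxical/SWS membership maximal at 1 and below,
#'   wake membership maximal at 2.4 and above.
#' }
#' Any epoch with mean activity above `activityThreshold` (0.1), or with
#' an EMG ratio at or above `emgActiveFactor` (1.5) times the wake EMG
#' anchor (1.5 x 2.4 = 3.6), is scored active wake outright.
#'
#' @param deltaLow,deltaHigh delta-ratio anchors (0.5, 1).
#' @param thetaDeltaLow,thetaDeltaHigh theta:delta anchors (1.3, 3).
#' @param emgLow,emgHigh EMG-ratio anchors (1, 2.4).
#' @param activityThreshold activity level above which an epoch is active
#'   wake (0.1).
#' @param emgActiveFactor multiple of `emgHigh` above which an epoch is
#'   active wake (1.5).
#' @param ratioCeiling value assigned to theta:delta when the epoch delta
#'   power is zero.
#' @param emgBand EMG power band in Hz used for the EMG feature
#'   (30--100 Hz, inside the hardware low-pass).
#' @param baseline reference statistic for the delta and EMG ratios:
#'   recording-wide `"median"` (robust to seizure epochs; default) or
#'   `"mean"`.
#' @return a named list of thresholds, validated for ordering.
#' @export
stagingThresholds <- function(deltaLow = 0.5, deltaHigh = 1,
                              thetaDeltaLow = 1.3, thetaDeltaHigh = 3,
                              emgLow = 1, emgHigh = 2.4,
                              activityThreshold = 0.1,
                              emgActiveFactor = 1.5,
                              ratioCeiling = 100,
                              emgBand = c(30, 100),
                              baseline = c("median", "mean")) {
  th <- list(deltaLow = deltaLow, deltaHigh = deltaHigh,
             thetaDeltaLow = thetaDeltaLow, thetaDeltaHigh = thetaDeltaHigh,
             emgLow = emgLow, emgHigh = emgHigh,
             activityThreshold = activityThreshold,
             emgActiveFactor = emgActiveFactor,
             ratioCeiling = ratioCeiling, emgBand = emgBand,
             baseline = match.arg(baseline))
  if (!(deltaLow < deltaHigh && thetaDeltaLow < thetaDeltaHigh &&
        emgLow < emgHigh))
    stop("threshold anchors must be ordered: low < high for each feature")
  if (any(c(deltaLow, thetaDeltaLow, emgLow, activityThreshold,
            emgActiveFactor) <= 0))
    stop("thresholds must be positive")
  th
}

#' Per-epoch staging features
#'
#' For each scoring epoch: delta ratio (epoch delta power over the
#' recording-wide baseline of delta power), theta:delta ratio (within
#' epoch), EMG ratio (epoch 30--100 Hz EMG power over its recording-wide
#' baseline) and mean activity. Masked epochs keep their features and are
#' labelled artifact downstream. Band powers use the Hamming periodogram
#' of each epoch.
#'
#' @param rec a [Recording-class].
#' @param epochLength scoring epoch, seconds (default 10).
#' @param mask optional [ArtifactMask-class] with the same epoch length.
#' @param thresholds list from [stagingThresholds()].
#' @param bands band table; delta and theta rows are used.
#' @return data.frame with columns `epoch_index`, `delta_ratio`,
#'   `theta_delta_ratio`, `emg_ratio`, `mean_activity`, `artifact`.
#' @export
computeEpochFeatures <- function(rec, epochLength = 10, mask = NULL,
                                 thresholds = stagingThresholds(),
                                 bands = eegBands()) {
  stopifnot(is(rec, "Recording"))
  delta <- bands[bands$name == "delta", ]
  theta <- bands[bands$name == "theta", ]
  per_e <- round(rec@eegRate * epochLength)
  per_a <- round(rec@activityRate * epochLength)
  n_ep <- min(floor(length(rec@eeg) / per_e),
              floor(length(rec@activity) / per_a))
  if (n_ep < 1L) stop("recording shorter than one epoch")

  # slice channels per epoch (no full-session epoch matrices: a 72 h
  # session would not fit in memory twice)
  dpow <- tpow <- mpow <- act_m <- numeric(n_ep)
  eb <- thresholds$emgBand
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * per_e + 1L):(i * per_e)
    sp <- computePSD(rec@eeg[idx], rec@eegRate)
    dpow[i] <- bandPower(sp, delta$lo, delta$hi)
    tpow[i] <- bandPower(sp, theta$lo, theta$hi)
    spm <- computePSD(rec@emg[idx], rec@emgRate, fmax = Inf)
    mpow[i] <- bandPower(spm, eb[1], eb[2])
    act_m[i] <- mean(rec@activity[((i - 1L) * per_a + 1L):(i * per_a)])
  }
  base <- if (thresholds$baseline == "median") stats::median else mean
  d0 <- base(dpow)
  m0 <- base(mpow)
  if (d0 <= 0 || m0 <= 0)
    stop("flat recording: baseline delta or EMG power is zero")
  td <- ifelse(dpow > 0, tpow / dpow, thresholds$ratioCeiling)
  flags <- rep(FALSE, n_ep)
  if (!is.null(mask)) {
    stopifnot(is(mask, "ArtifactMask"))
    if (abs(mask@epochLength - epochLength) > 1e-9)
      stop("mask epoch length does not match epochLength")
    flags <- mask@flags[seq_len(n_ep)]
  }
  data.frame(epoch_index = seq_len(n_ep),
             delta_ratio = dpow / d0,
             theta_delta_ratio = pmin(td, thresholds$ratioCeiling),
             emg_ratio = mpow / m0,
             mean_activity = act_m,
             artifact = flags)
}

# linear ramp: 0 at `zero`, 1 at `one`, clipped outside (works for
# descending ramps when zero > one)
.ramp <- function(x, zero, one) pmin(1, pmax(0, (x - zero) / (one - zero)))

#' Stage membership scores for epoch features
#'
#' Each of the wake, slow-wave-sleep and paradoxical stages receives a
#' score in \[0, 1\]: the unweighted mean of its delta, theta:delta and
#' EMG memberships (the four inputs contribute equally; the fourth,
#' activity, acts as the active-wake override in [classifyEpoch()]).
#' Memberships are linear ramps between the anchors in
#' [stagingThresholds()], saturating at 0/1 beyond them.
#'
#' @param features data.frame from [computeEpochFeatures()] (vectorised
#'   over rows).
#' @param thresholds list from [stagingThresholds()].
#' @return data.frame with columns `WAKE`, `SWS`, `PARADOXICAL`.
#' @export
stageMembership <- function(features, thresholds = stagingThresholds()) {
  th <- thresholds
  d <- features$delta_ratio
  t <- features$theta_delta_ratio
  m <- features$emg_ratio
  sws_d <- .ramp(d, th$deltaLow, th$deltaHigh)
  low_d <- .ramp(d, th$deltaHigh, th$deltaLow)       # wake & paradoxical
  par_t <- .ramp(t, th$thetaDeltaLow, th$thetaDeltaHigh)
  low_t <- .ramp(t, th$thetaDeltaHigh, th$thetaDeltaLow)  # wake & SWS
  wake_m <- .ramp(m, th$emgLow, th$emgHigh)
  low_m <- .ramp(m, th$emgHigh, th$emgLow)           # SWS & paradoxical
  data.frame(WAKE = (low_d + low_t + wake_m) / 3,
             SWS = (sws_d + low_t + low_m) / 3,
             PARADOXICAL = (low_d + par_t + low_m) / 3)
}

#' Classify one or more epochs
#'
#' An epoch is active wake when its mean activity exceeds the activity
#' threshold (0.1) or its EMG ratio reaches 1.5 times the wake EMG anchor
#' (1.5 x 2.4 = 3.6); otherwise the stage with the highest membership
#' score wins, with ties broken in the order wake > SWS > paradoxical
#' (most to least common stage).
#'
#' @param scores data.frame from [stageMembership()].
#' @param features matching data.frame from [computeEpochFeatures()].
#' @param thresholds list from [stagingThresholds()].
#' @return character vector of stage labels.
#' @export
classifyEpoch <- function(scores, features,
                          thresholds = stagingThresholds()) {
  th <- thresholds
  sc <- as.matrix(scores[, c("WAKE", "SWS", "PARADOXICAL")])
  best <- c("WAKE", "SWS", "PARADOXICAL")[max.col(sc, ties.method = "first")]
  aw <- features$mean_activity > th$activityThreshold |
    features$emg_ratio >= th$emgActiveFactor * th$emgHigh
  ifelse(aw, "ACTIVE_WAKE", best)
}

#' Score a whole recording into a hypnogram
#'
#' Runs [computeEpochFeatures()], [stageMembership()] and
#' [classifyEpoch()] per epoch; masked epochs are labelled `"ARTIFACT"`
#' and stage percentages are computed over the non-artifact epochs only.
#'
#' @param rec a [Recording-class] spanning at least 10 epochs.
#' @param mask optional [ArtifactMask-class].
#' @param thresholds list from [stagingThresholds()].
#' @param epochLength scoring epoch, seconds.
#' @param features optionally, a precomputed feature table from
#'   [computeEpochFeatures()] (avoids recomputing spectra).
#' @return a [Hypnogram-class].
#' @export
scoreHypnogram <- function(rec, mask = NULL,
                           thresholds = stagingThresholds(),
                           epochLength = 10, features = NULL) {
  if (is.null(features))
    features <- computeEpochFeatures(rec, epochLength, mask, thresholds)
  if (nrow(features) < 10L)
    stop("recording must span at least 10 scoring epochs")
  labels <- classifyEpoch(stageMembership(features, thresholds),
                          features, thresholds)
  labels[features$artifact] <- "ARTIFACT"
  if (all(labels == "ARTIFACT")) stop("every epoch is artifact")
  Hypnogram(epochLength, labels)
}
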
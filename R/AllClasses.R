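.STAGES <- c("ACTIVE_WAKE", "WAKE", "SWS", "PARADOXICAL")
.STAGES_ART <- c(.STAGES, "ARTIFACT")
.GENOTYPES <- c("WT", "HET", "UNSPECIFIED")

#' Multichannel telemetry recording
#'
#' Container for one EEG/EMG/activity session as acquired by a wireless
#' telemetry implant: EEG and EMG in microvolts at a common sampling rate
#' (typically 500 Hz with a 0.1--100 Hz bandpass), plus an accelerometer
#' activity channel in arbitrary units (typically 200 Hz). Series lengths
#' must equal `round(rate * duration)`.
#'
#' @slot subjectID character scalar, animal/session identifier.
#' @slot genotype one of `"WT"`, `"HET"`, `"UNSPECIFIED"`.
#' @slot eeg,emg numeric vectors, microvolts.
#' @slot activity numeric vector, arbitrary units (all zero when the
#'   channel is absent; this switches the active-wake activity rule off).
#' @slot eegRate,emgRate,activityRate sampling rates in Hz; EEG and EMG
#'   rates must be equal.
#' @slot startTime character timestamp (`"%Y-%m-%d %H:%M:%S"`).
#' @slot duration session length in seconds.
#'
#' @seealso [Recording()], [readRecording()], [simulateEEGSession()]
#' @export
setClass("Recording",
  representation(
    subjectID = "character",
    genotype = "character",
    eeg = "numeric",
    emg = "numeric",
    activity = "numeric",
    eegRate = "numeric",
    emgRate = "numeric",
    activityRate = "numeric",
    startTime = "character",
    duration = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be a scalar")
  if (length(object@genotype) != 1L || !object@genotype %in% .GENOTYPES)
    msg <- c(msg, sprintf("genotype must be one of %s",
                          paste(.GENOTYPES, collapse = ", ")))
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be a positive scalar")
  rates <- c(object@eegRate, object@emgRate, object@activityRate)
  if (length(rates) != 3L || any(!is.finite(rates)) || any(rates <= 0))
    msg <- c(msg, "all sampling rates must be positive scalars")
  if (length(object@eegRate) == 1L && length(object@emgRate) == 1L &&
      object@eegRate != object@emgRate)
    msg <- c(msg, "EEG and EMG sampling rates must be equal")
  if (!length(msg) && length(object@duration) == 1L && object@duration > 0) {
    n_chk <- function(x, rate, lab) {
      if (length(x) != round(rate * object@duration))
        sprintf("%s length %d != round(rate * duration) = %d",
                lab, length(x), round(rate * object@duration))
      else NULL
    }
    msg <- c(msg,
             n_chk(object@eeg, object@eegRate, "eeg"),
             n_chk(object@emg, object@emgRate, "emg"),
             n_chk(object@activity, object@activityRate, "activity"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param eeg,emg numeric vectors in microvolts, sampled at `eegRate`.
#' @param activity numeric vector in arbitrary units at `activityRate`;
#'   `NULL` inserts a constant-zero channel.
#' @param eegRate,activityRate sampling rates in Hz.
#' @param subjectID,genotype,startTime session metadata.
#' @param duration seconds; defaults to `length(eeg) / eegRate`.
#' @return a validated [Recording-class] object.
#' @examples
#' rec <- Recording(eeg = sin(2 * pi * 2 * seq(0, 10, by = 1/500))[-1],
#'                  emg = rnorm(5000), eegRate = 500)
#' recDuration(rec)
#' @export
Recording <- function(eeg, emg, activity = NULL, eegRate = 500,
                      activityRate = 200, subjectID = "subject",
                      genotype = c("UNSPECIFIED", "WT", "HET"),
                      startTime = "2026-01-01 00:00:00",
                      duration = length(eeg) / eegRate) {
  genotype <- match.arg(genotype)
  if (is.null(activity))
    activity <- numeric(round(activityRate * duration))
  new("Recording",
      subjectID = as.character(subjectID), genotype = genotype,
      eeg = as.numeric(eeg), emg = as.numeric(emg),
      activity = as.numeric(activity),
      eegRate = as.numeric(eegRate), emgRate = as.numeric(eegRate),
      activityRate = as.numeric(activityRate),
      startTime = as.character(startTime), duration = as.numeric(duration))
}

#' Per-epoch artifact mask
#'
#' One logical flag per scoring epoch; `TRUE` marks an epoch containing an
#' amplitude artifact. Flagged epochs are excluded from sleep staging and
#' band-power averaging (but not from spike detection, whose amplitude
#' threshold coincides with the EEG artifact level).
#'
#' @slot epochLength epoch length in seconds.
#' @slot flags logical vector, one per epoch.
#' @seealso [markArtifacts()]
#' @export
setClass("ArtifactMask",
  representation(epochLength = "numeric", flags = "logical"))

setValidity("ArtifactMask", function(object) {
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    return("epochLength must be a positive scalar")
  if (anyNA(object@flags)) return("flags must not contain NA")
  TRUE
})

#' Power spectral density
#'
#' One-sided power spectral density in uV^2/Hz on a strictly ascending
#' frequency grid (<= 50 Hz for the cortical EEG convention used here,
#' unless computed with a higher `fmax`).
#'
#' @slot frequencies Hz, strictly ascending.
#' @slot power uV^2/Hz, non-negative, same length.
#' @slot binWidth native width of each frequency bin in Hz (used by the
#'   rectangle-rule band integrals).
#' @seealso [computePSD()], [rebinSpectrum()], [bandPower()]
#' @export
setClass("Spectrum",
  representation(frequencies = "numeric", power = "numeric",
                 binWidth = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@frequencies) != length(object@power))
    return("frequencies and power lengths differ")
  if (length(object@frequencies) == 0L)
    return("empty spectrum")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    return("frequencies must be strictly ascending")
  if (any(object@power < 0)) return("negative power density")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    return("binWidth must be a positive scalar")
  TRUE
})

Spectrum <- function(frequencies, power, binWidth) {
  new("Spectrum", frequencies = as.numeric(frequencies),
      power = as.numeric(power), binWidth = as.numeric(binWidth))
}

#' Hypnogram
#'
#' Per-epoch sleep-stage labels over a session, with stage percentages
#' computed over the non-artifact epochs. Stages are active wake, (quiet)
#' wake, slow-wave sleep and paradoxical sleep; epochs flagged by the
#' artifact mask carry the label `"ARTIFACT"` and do not enter the
#' percentages.
#'
#' @slot epochLength scoring epoch in seconds.
#' @slot stages character vector of per-epoch labels.
#' @slot percentages named numeric, percent of non-artifact epochs per
#'   stage; sums to 100.
#' @seealso [scoreHypnogram()]
#' @export
setClass("Hypnogram",
  representation(epochLength = "numeric", stages = "character",
                 percentages = "numeric"))

setValidity("Hypnogram", function(object) {
  if (!all(object@stages %in% .STAGES_ART))
    return("unknown stage label")
  if (!setequal(names(object@percentages), .STAGES))
    return("percentages must be named by the four stages")
  if (abs(sum(object@percentages) - 100) > 1e-6)
    return("stage percentages must sum to 100")
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    return("epochLength must be a positive scalar")
  TRUE
})

Hypnogram <- function(epochLength, stages) {
  stages <- as.character(stages)
  scored <- stages[stages != "ARTIFACT"]
  if (!length(scored)) stop("all epochs are artifact; nothing to score")
  pct <- 100 * vapply(.STAGES, function(s) mean(scored == s), numeric(1))
  new("Hypnogram", epochLength = as.numeric(epochLength),
      stages = stages, percentages = pct)
}

#' HD-MEA spike raster
#'
#' Spike times per electrode from a high-density microelectrode array
#' recording (e.g. a 30 s full-chip activity scan over 26,400 electrodes,
#' or a 300 s network scan of the 1024 highest-firing electrodes). Times
#' are seconds from recording start, sorted within electrode.
#'
#' @slot electrodeIDs integer electrode identifiers, unique.
#' @slot spikeTimes list of numeric vectors, one per electrode, sorted.
#' @slot duration recording length in seconds.
#' @slot chipMetadata list; recognised entries `nElectrodesTotal`, `div`
#'   (days in vitro) and `genotype`.
#' @seealso [readRaster()], [simulateMEARaster()], [networkActivity()]
#' @export
setClass("SpikeRaster",
  representation(electrodeIDs = "integer", spikeTimes = "list",
                 duration = "numeric", chipMetadata = "list"))

setValidity("SpikeRaster", function(object) {
  if (length(object@electrodeIDs) != length(object@spikeTimes))
    return("one spike-time vector per electrode required")
  if (anyDuplicated(object@electrodeIDs))
    return("electrode ids must be unique")
  if (length(object@duration) != 1L || object@duration <= 0)
    return("duration must be a positive scalar")
  for (st in object@spikeTimes) {
    if (length(st)) {
      if (is.unsorted(st)) return("spike times must be sorted per electrode")
      if (st[1L] < 0 || st[length(st)] >= object@duration)
        return("spike times must lie in [0, duration)")
    }
  }
  TRUE
})

#' Construct a SpikeRaster
#'
#' @param electrodeIDs integer ids, one per element of `spikeTimes`.
#' @param spikeTimes list of numeric spike-time vectors (seconds); unsorted
#'   input is sorted.
#' @param duration recording length in seconds.
#' @param chipMetadata optional list of chip-level metadata.
#' @return a validated [SpikeRaster-class].
#' @export
SpikeRaster <- function(electrodeIDs, spikeTimes, duration,
                        chipMetadata = list()) {
  new("SpikeRaster",
      electrodeIDs = as.integer(electrodeIDs),
      spikeTimes = lapply(spikeTimes, function(x) sort(as.numeric(x))),
      duration = as.numeric(duration),
      chipMetadata = chipMetadata)
}
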
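#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @aliases subjectID,Recording-method
setMethod("subjectID", "Recording", function(object) object@subjectID)

#' @rdname accessors
setMethod("genotype", "Recording", function(object) object@genotype)

#' @rdname accessors
setMethod("eeg", "Recording", function(object) object@eeg)

#' @rdname accessors
setMethod("emg", "Recording", function(object) object@emg)

#' @rdname accessors
setMethod("activity", "Recording", function(object) object@activity)

#' @rdname accessors
setMethod("eegRate", "Recording", function(object) object@eegRate)

#' @rdname accessors
setMethod("emgRate", "Recording", function(object) object@emgRate)

#' @rdname accessors
setMethod("activityRate", "Recording", function(object) object@activityRate)

#' @rdname accessors
setMethod("recDuration", "Recording", function(object) object@duration)

#' @rdname accessors
setMethod("startTime", "Recording", function(object) object@startTime)

#' @rdname accessors
setMethod("epochLength", "ArtifactMask", function(object) object@epochLength)

#' @rdname accessors
setMethod("artifactFlags", "ArtifactMask", function(object) object@flags)

#' @rdname accessors
setMethod("frequencies", "Spectrum", function(object) object@frequencies)

#' @rdname accessors
setMethod("psd", "Spectrum", function(object) object@power)

#' @rdname accessors
setMethod("epochLength", "Hypnogram", function(object) object@epochLength)

#' @rdname accessors
setMethod("stages", "Hypnogram", function(object) object@stages)

#' @rdname accessors
setMethod("stagePercentages", "Hypnogram", function(object) object@percentages)

#' @rdname accessors
setMethod("electrodeIDs", "SpikeRaster", function(object) object@electrodeIDs)

#' @rdname accessors
setMethod("spikeTimes", "SpikeRaster", function(object) object@spikeTimes)

#' @rdname accessors
setMethod("recDuration", "SpikeRaster", function(object) object@duration)

#' @rdname accessors
setMethod("nSpikes", "SpikeRaster",
          function(object) sum(lengths(object@spikeTimes)))

#' @rdname accessors
setMethod("chipMetadata", "SpikeRaster", function(object) object@chipMetadata)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (%s)\n", object@subjectID, object@genotype))
  cat(sprintf("  duration: %.1f s (%.2f h), start %s\n",
              object@duration, object@duration / 3600, object@startTime))
  cat(sprintf("  EEG/EMG: %d samples @ %g Hz; activity: %d samples @ %g Hz\n",
              length(object@eeg), object@eegRate,
              length(object@activity), object@activityRate))
})

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d epochs of %g s, %d flagged (%.1f%%)\n",
              length(object@flags), object@epochLength,
              sum(object@flags), 100 * mean(object@flags)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, %.3g-%.3g Hz (bin width %g Hz)\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), object@binWidth))
  cat(sprintf("  total power (rect. rule): %.4g uV^2\n",
              sum(object@power) * object@binWidth))
})

setMethod("show", "Hypnogram", function(object) {
  n <- length(object@stages)
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h), %d artifact\n",
              n, object@epochLength, n * object@epochLength / 3600,
              sum(object@stages == "ARTIFACT")))
  pct <- object@percentages
  cat(sprintf("  %s\n", paste(sprintf("%s %.1f%%", names(pct), pct),
                              collapse = ", ")))
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d electrodes, %d spikes over %g s\n",
              length(object@electrodeIDs), nSpikes(object),
              object@duration))
  md <- object@chipMetadata
  if (length(md))
    cat(sprintf("  metadata: %s\n",
                paste(names(md), unlist(lapply(md, format)),
                      sep = "=", collapse = ", ")))
})
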
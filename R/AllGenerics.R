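#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the S4 containers in \pkg{ephysuite}. Slot access by `@`
#' is never part of the public interface.
#'
#' @param object an \pkg{ephysuite} S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("genotype", function(object) standardGeneric("genotype"))

#' @rdname accessors
#' @export
setGeneric("eeg", function(object) standardGeneric("eeg"))

#' @rdname accessors
#' @export
setGeneric("emg", function(object) standardGeneric("emg"))

#' @rdname accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("eegRate", function(object) standardGeneric("eegRate"))

#' @rdname accessors
#' @export
setGeneric("emgRate", function(object) standardGeneric("emgRate"))

#' @rdname accessors
#' @export
setGeneric("activityRate", function(object) standardGeneric("activityRate"))

#' @rdname accessors
#' @export
setGeneric("recDuration", function(object) standardGeneric("recDuration"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("epochLength", function(object) standardGeneric("epochLength"))

#' @rdname accessors
#' @export
setGeneric("artifactFlags", function(object) standardGeneric("artifactFlags"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("psd", function(object) standardGeneric("psd"))

#' @rdname accessors
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))

#' @rdname accessors
#' @export
setGeneric("stagePercentages", function(object) standardGeneric("stagePercentages"))

#' @rdname accessors
#' @export
setGeneric("electrodeIDs", function(object) standardGeneric("electrodeIDs"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("chipMetadata", function(object) standardGeneric("chipMetadata"))
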
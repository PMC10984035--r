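#' @include AllClasses.R
NULL

.io_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(tolower(format), c("edf", "tsv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("edf", "tsv")) ext else
    stop("cannot infer format from extension '", ext, "'; pass `format`")
}

#' Read a continuous recording
#'
#' Reads an EEG/EMG/activity session from disk. Two formats are supported:
#' EDF (the acquisition system's 16-bit export format) and a lossless
#' tab-separated text layout written by [writeRecording()]. Channels are
#' identified by label (`EEG`, `EMG`, `Activity`, case-insensitive); an
#' absent activity channel becomes a constant-zero series, which switches
#' the active-wake activity rule off downstream. EEG/EMG units are
#' converted to microvolts (mV labels are scaled by 1000).
#'
#' @param path file path.
#' @param format `"edf"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return a [Recording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- .io_format(path, format)
  if (format == "tsv") return(.read_recording_tsv(path))

  h <- .edf_read(path)
  pick <- function(pat) which(grepl(pat, h$labels, ignore.case = TRUE))[1L]
  i_eeg <- pick("EEG")
  i_emg <- pick("EMG")
  i_act <- pick("Activ|Accel")
  if (is.na(i_eeg) || is.na(i_emg))
    stop("EDF file must declare EEG and EMG channels; found: ",
         paste(h$labels, collapse = ", "))
  if (h$rates[i_eeg] != h$rates[i_emg])
    stop("EEG and EMG sampling rates differ in file header")
  to_uV <- function(i) {
    x <- h$data[[i]]
    if (grepl("mV", h$units[i], ignore.case = TRUE)) x * 1000 else x
  }
  dur <- h$n_records * h$record_duration
  genotype <- "UNSPECIFIED"
  m <- regmatches(h$recording, regexec("genotype=(\\w+)", h$recording))[[1L]]
  if (length(m) == 2L && m[2L] %in% .GENOTYPES) genotype <- m[2L]
  if (is.na(i_act)) {
    act <- numeric(round(200 * dur))
    act_rate <- 200
  } else {
    act <- h$data[[i_act]]
    act_rate <- h$rates[i_act]
  }
  Recording(eeg = to_uV(i_eeg), emg = to_uV(i_emg), activity = act,
            eegRate = h$rates[i_eeg], activityRate = act_rate,
            subjectID = if (nzchar(h$patient)) h$patient else "subject",
            genotype = genotype,
            startTime = if (is.na(h$start_time)) "2026-01-01 00:00:00"
                        else h$start_time,
            duration = dur)
}

#' Write a continuous recording
#'
#' EDF output uses one-second data records and 16-bit quantization scaled
#' to each channel's absolute maximum, so a write/read round trip is exact
#' to within one quantization step; the duration and all sampling rates
#' must be whole numbers of seconds/Hz for this format. The `tsv` format
#' stores full-precision floats as text and has no such restriction.
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param format `"edf"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = NULL) {
  stopifnot(is(rec, "Recording"))
  validObject(rec)
  format <- .io_format(path, format)
  if (format == "tsv") return(.write_recording_tsv(rec, path))

  if (abs(rec@duration - round(rec@duration)) > 1e-9)
    stop("EDF output requires an integer number of seconds; use format='tsv'")
  rates <- c(rec@eegRate, rec@emgRate, rec@activityRate)
  if (any(abs(rates - round(rates)) > 1e-9))
    stop("EDF output requires integer sampling rates; use format='tsv'")
  channels <- list(
    list(label = "EEG", unit = "uV", data = rec@eeg,
         samples_per_record = as.integer(round(rec@eegRate))),
    list(label = "EMG", unit = "uV", data = rec@emg,
         samples_per_record = as.integer(round(rec@emgRate))),
    list(label = "Activity", unit = "au", data = rec@activity,
         samples_per_record = as.integer(round(rec@activityRate))))
  .edf_write(path, channels, rec@startTime,
             n_records = as.integer(round(rec@duration)),
             patient = rec@subjectID,
             recording = paste0("genotype=", rec@genotype))
  invisible(path)
}

.write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#ephysuite-recording\tv1", con)
  meta <- c(subject_id = rec@subjectID, genotype = rec@genotype,
            eeg_rate = format(rec@eegRate, digits = 17),
            activity_rate = format(rec@activityRate, digits = 17),
            start_time = rec@startTime,
            duration = format(rec@duration, digits = 17))
  writeLines(paste(names(meta), meta, sep = "\t"), con)
  wr <- function(name, x)
    writeLines(paste(name, paste(sprintf("%.17g", x), collapse = " "),
                     sep = "\t"), con)
  wr("eeg", rec@eeg)
  wr("emg", rec@emg)
  wr("activity", rec@activity)
  invisible(path)
}

.read_recording_tsv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#ephysuite-recording", lines[1L]))
    stop("not an ephysuite TSV recording: ", path)
  kv <- strsplit(lines[-1L], "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  val <- function(k) kv[[match(k, keys)]][2L]
  series <- function(k) as.numeric(strsplit(val(k), " ", fixed = TRUE)[[1L]])
  Recording(eeg = series("eeg"), emg = series("emg"),
            activity = series("activity"),
            eegRate = as.numeric(val("eeg_rate")),
            activityRate = as.numeric(val("activity_rate")),
            subjectID = val("subject_id"),
            genotype = val("genotype"),
            startTime = val("start_time"),
            duration = as.numeric(val("duration")))
}

#' Flag artifact epochs by amplitude
#'
#' An epoch is flagged when the absolute EEG exceeds `eegLimit` or the
#' absolute EMG exceeds `emgLimit` anywhere within it (half-open epoch
#' windows `[k*L, (k+1)*L)`). The defaults are the acquisition pipeline's
#' artifact levels: 0.2 mV on EEG and 1 mV on EMG. Flagged epochs are
#' excluded from sleep staging and band-power averages; spike detection
#' deliberately ignores this mask because the spike amplitude threshold
#' coincides with the EEG artifact level.
#'
#' @param rec a [Recording-class].
#' @param epochLength epoch length in seconds (default 10, the band-power
#'   and staging epoch).
#' @param eegLimit,emgLimit absolute-amplitude limits in microvolts.
#' @return an [ArtifactMask-class] with `floor(duration / epochLength)`
#'   flags.
#' @examples
#' rec <- Recording(eeg = numeric(30000), emg = numeric(30000), eegRate = 500)
#' sum(artifactFlags(markArtifacts(rec)))
#' @export
markArtifacts <- function(rec, epochLength = 10, eegLimit = 200,
                          emgLimit = 1000) {
  stopifnot(is(rec, "Recording"))
  if (eegLimit <= 0 || emgLimit <= 0) stop("artifact limits must be positive")
  if (epochLength <= 0 || epochLength > rec@duration)
    stop("epochLength must be in (0, duration]")
  n_ep <- floor(rec@duration / epochLength)
  # slice per epoch rather than materializing channel-sized copies, so
  # multi-day sessions stay within memory
  flag_chan <- function(x, rate, limit) {
    per <- round(rate * epochLength)
    vapply(seq_len(n_ep), function(k) {
      seg <- x[((k - 1L) * per + 1L):(k * per)]
      any(seg > limit) || any(seg < -limit)
    }, logical(1))
  }
  flags <- flag_chan(rec@eeg, rec@eegRate, eegLimit) |
    flag_chan(rec@emg, rec@emgRate, emgLimit)
  new("ArtifactMask", epochLength = as.numeric(epochLength), flags = flags)
}
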
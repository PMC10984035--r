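#' @include AllClasses.R
NULL

#' Detect EEG spikes by absolute amplitude threshold
#'
#' A candidate event is a maximal run of consecutive samples with
#' `|x| > threshold` (either polarity crosses the absolute threshold); it
#' is accepted when its duration -- time above threshold, i.e. run length
#' over the sampling rate -- lies within `[minDur, maxDur]`. Events are
#' maximal runs and therefore disjoint. This detector is applied to the
#' raw trace, not the artifact-masked one: the 200 uV default threshold
#' coincides with the EEG artifact level, so masking first would delete
#' every spike.
#'
#' @param x numeric EEG series, microvolts.
#' @param rate sampling rate, Hz.
#' @param threshold absolute amplitude threshold, microvolts (default 200).
#' @param minDur,maxDur spike duration bounds in milliseconds (defaults 1
#'   and 200).
#' @return data.frame with columns `onset_s` (time of the first
#'   supra-threshold sample), `duration_ms` and `peak_uV` (largest
#'   absolute amplitude in the run); zero rows when nothing qualifies.
#' @examples
#' x <- numeric(5000); x[1000:1002] <- 300
#' detectSpikes(x, 500)
#' @export
detectSpikes <- function(x, rate, threshold = 200, minDur = 1,
                         maxDur = 200) {
  if (threshold <= 0) stop("threshold must be positive")
  empty <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      peak_uV = numeric(0))
  if (!length(x)) return(empty)
  above <- abs(x) > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values
  dur_ms <- r$lengths[hit] / rate * 1000
  starts <- starts[hit]
  ends <- ends[hit]
  ok <- dur_ms >= minDur & dur_ms <= maxDur
  if (!any(ok)) return(empty)
  starts <- starts[ok]; ends <- ends[ok]
  peak <- vapply(seq_along(starts),
                 function(i) max(abs(x[starts[i]:ends[i]])), numeric(1))
  data.frame(onset_s = (starts - 1L) / rate,
             duration_ms = dur_ms[ok],
             peak_uV = peak)
}

#' Group spikes into spike trains
#'
#' Greedy left-to-right chaining on spike onsets: the current chain is
#' extended while the gap to the next onset lies in
#' `[intervalMin, intervalMax]`. A gap outside that range terminates the
#' chain -- including gaps *shorter* than `intervalMin`, which are treated
#' as parts of a single discharge rather than train members (set
#' `shortGapBreaks = FALSE` to instead ignore the lower bound and keep
#' chaining). A completed chain is emitted as a train when it has at
#' least `minSpikes` members and spans at least `minTrainDuration`
#' seconds (first to last onset).
#'
#' @param spikes data.frame from [detectSpikes()] (needs `onset_s`,
#'   sorted ascending).
#' @param intervalMin,intervalMax onset-gap bounds in seconds (defaults
#'   0.05 and 0.5).
#' @param minSpikes minimum chain size (default 3).
#' @param minTrainDuration minimum train span in seconds (default 1).
#' @param shortGapBreaks if `TRUE` (default) a gap below `intervalMin`
#'   breaks the chain; if `FALSE` it is tolerated.
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `n_spikes`, `first_spike`, `last_spike` (row indices into `spikes`).
#' @examples
#' sp <- data.frame(onset_s = c(0, 0.3, 0.6, 0.9, 1.2))
#' groupSpikeTrains(sp)
#' @export
groupSpikeTrains <- function(spikes, intervalMin = 0.05, intervalMax = 0.5,
                             minSpikes = 3, minTrainDuration = 1,
                             shortGapBreaks = TRUE) {
  onsets <- spikes$onset_s
  if (is.unsorted(onsets)) stop("spike onsets must be sorted ascending")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_spikes = integer(0),
                      first_spike = integer(0), last_spike = integer(0))
  if (!length(onsets)) return(empty)
  gaps <- diff(onsets)
  link <- gaps <= intervalMax & (!shortGapBreaks | gaps >= intervalMin)
  # chains are maximal runs of linked consecutive spikes
  chain_id <- cumsum(c(1L, !link))
  out <- lapply(split(seq_along(onsets), chain_id), function(idx) {
    span <- onsets[idx[length(idx)]] - onsets[idx[1L]]
    if (length(idx) >= minSpikes && span >= minTrainDuration)
      data.frame(start_s = onsets[idx[1L]], end_s = onsets[idx[length(idx)]],
                 duration_s = span, n_spikes = length(idx),
                 first_spike = idx[1L], last_spike = idx[length(idx)])
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out
  }
}

#' Summary totals over detected spike trains
#'
#' @param trains data.frame from [groupSpikeTrains()].
#' @return list with `train_count`, `total_train_duration` (s) and
#'   `mean_train_duration` (s; 0 for an empty list).
#' @export
summarizeTrains <- function(trains) {
  n <- nrow(trains)
  tot <- if (n) sum(trains$duration_s) else 0
  list(train_count = n,
       total_train_duration = tot,
       mean_train_duration = if (n) tot / n else 0)
}

#' Match detected event times against ground truth
#'
#' One-to-one greedy matching of detected onsets to true onsets within a
#' tolerance, for precision/recall bookkeeping in recovery experiments.
#'
#' @param truth,detected numeric vectors of event times, seconds.
#' @param tolerance maximum |detected - true| for a match, seconds.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
matchEventTimes <- function(truth, detected, tolerance = 0.02) {
  truth <- sort(truth)
  detected <- sort(detected)
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    cand <- which(!used & abs(truth - d) <= tolerance)
    if (length(cand)) {
      used[cand[which.min(abs(truth[cand] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (length(detected)) tp / length(detected) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_)
}
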
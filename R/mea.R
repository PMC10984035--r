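#' @include AllClasses.R
NULL

#' Read an HD-MEA spike raster
#'
#' Delimited text with columns `electrode_id` and `spike_time_s` (header
#' required; comma or tab separated). Metadata may be carried in leading
#' comment lines of the form `# key=value` (recognised keys:
#' `duration_s`, `n_electrodes_total`, `div`, `genotype`); an explicit
#' `duration` argument overrides the file. Rows are sorted per electrode
#' on load.
#'
#' @param path file path.
#' @param duration recording length in seconds; required when the file
#'   carries no `duration_s` header.
#' @return a [SpikeRaster-class].
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path, duration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  if (is.null(duration)) {
    if (is.null(meta$duration_s))
      stop("no duration_s header in file; pass `duration`")
    duration <- as.numeric(meta$duration_s)
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep)
  if (!all(c("electrode_id", "spike_time_s") %in% names(df)))
    stop("raster file needs electrode_id and spike_time_s columns")
  if (nrow(df) && (min(df$spike_time_s) < 0 ||
                   max(df$spike_time_s) >= duration))
    stop("spike times outside [0, duration)")
  ids <- sort(unique(as.integer(df$electrode_id)))
  st <- split(df$spike_time_s, factor(df$electrode_id, levels = ids))
  md <- list()
  if (!is.null(meta$n_electrodes_total))
    md$nElectrodesTotal <- as.integer(meta$n_electrodes_total)
  if (!is.null(meta$div)) md$div <- as.integer(meta$div)
  if (!is.null(meta$genotype)) md$genotype <- meta$genotype
  SpikeRaster(ids, st, duration, md)
}

#' Write an HD-MEA spike raster
#'
#' @param raster a [SpikeRaster-class].
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(raster, path) {
  stopifnot(is(raster, "SpikeRaster"))
  md <- raster@chipMetadata
  hdr <- c(sprintf("# duration_s=%.10g", raster@duration),
           if (!is.null(md$nElectrodesTotal))
             sprintf("# n_electrodes_total=%d", md$nElectrodesTotal),
           if (!is.null(md$div)) sprintf("# div=%d", md$div),
           if (!is.null(md$genotype)) sprintf("# genotype=%s", md$genotype))
  n <- lengths(raster@spikeTimes)
  df <- data.frame(electrode_id = rep(raster@electrodeIDs, n),
                   spike_time_s = unlist(raster@spikeTimes, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-electrode firing rates from an activity scan
#'
#' Firing rate is spike count over recording duration, per electrode (the
#' full-chip activity scan records every electrode for 30 s).
#'
#' @param raster a [SpikeRaster-class].
#' @return list with `rates` (data.frame `electrode_id`, `rate_hz`),
#'   `mean_rate_hz` and `max_rate_hz`.
#' @export
activityScanSummary <- function(raster) {
  stopifnot(is(raster, "SpikeRaster"))
  r <- lengths(raster@spikeTimes) / raster@duration
  list(rates = data.frame(electrode_id = raster@electrodeIDs, rate_hz = r),
       mean_rate_hz = if (length(r)) mean(r) else 0,
       max_rate_hz = if (length(r)) max(r) else 0)
}

#' Select the highest-firing electrodes
#'
#' The `k` electrodes with the highest firing rate (the network assay
#' records the 1024 highest-firing electrodes of the activity scan
#' simultaneously). Ties are broken toward the lower electrode id; when
#' fewer than `k` electrodes exist, all are returned with a warning.
#'
#' @param rates data.frame with `electrode_id` and `rate_hz` (as returned
#'   in `activityScanSummary()$rates`).
#' @param k number of electrodes to keep (default 1024).
#' @return integer vector of selected electrode ids, ordered by
#'   decreasing rate then increasing id.
#' @export
selectTopElectrodes <- function(rates, k = 1024) {
  stopifnot(k >= 1)
  if (nrow(rates) < k) {
    warning("only ", nrow(rates), " electrodes available (k = ", k, ")")
    k <- nrow(rates)
  }
  ord <- order(-rates$rate_hz, rates$electrode_id)
  as.integer(rates$electrode_id[ord[seq_len(k)]])
}

#' Smoothed population firing-rate trace
#'
#' Pools spikes over all electrodes into bins of width `bin`, converts to
#' spikes per second, and convolves with a unit-area Gaussian kernel of
#' standard deviation `sigma`, truncated at +/- 4 sigma (direct
#' discrete convolution with zero padding; output at bin centres, one
#' value per bin). This is the network-activity trace on which population
#' bursts are quantified.
#'
#' @param raster a [SpikeRaster-class].
#' @param bin bin width in seconds (default 0.01).
#' @param sigma kernel standard deviation in seconds (default 0.1;
#'   must be at least `bin`).
#' @return data.frame with columns `time_s` (bin centres) and
#'   `rate_hz` (population spikes/s).
#' @export
networkActivity <- function(raster, bin = 0.01, sigma = 0.1) {
  stopifnot(is(raster, "SpikeRaster"))
  if (bin <= 0) stop("bin must be positive")
  if (sigma < bin) stop("sigma must be at least the bin width")
  n_bins <- floor(raster@duration / bin)
  half <- ceiling(4 * sigma / bin)
  if (raster@duration < (2 * half + 1) * bin)
    stop("recording shorter than the kernel support")
  times <- unlist(raster@spikeTimes, use.names = FALSE)
  centres <- (seq_len(n_bins) - 0.5) * bin
  if (!length(times))
    return(data.frame(time_s = centres, rate_hz = numeric(n_bins)))
  counts <- tabulate(pmin(floor(times / bin) + 1L, n_bins), nbins = n_bins)
  kern <- stats::dnorm(seq(-half, half) * bin, sd = sigma) * bin
  padded <- c(numeric(half), counts / bin, numeric(half))
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  data.frame(time_s = centres,
             rate_hz = as.numeric(sm[(half + 1L):(half + n_bins)]))
}

#' Detect network bursts on a population trace
#'
#' The burst threshold is `median(trace) + thresholdMult * robust SD`,
#' with the robust SD taken as 1.4826 times the median absolute deviation
#' (burst periods would inflate a plain SD). Bursts are maximal
#' supra-threshold excursions; each burst's peak is the trace maximum in
#' the excursion, and its boundaries are extended outward to where the
#' trace falls below `boundaryFrac` times the peak height, clipping at
#' the trace minimum between adjacent peaks so bursts never overlap.
#' Peak height is measured above the baseline (the trace median) by
#' default, so that a dense background raster -- whose population rate
#' never approaches zero -- still yields sub-second burst windows; set
#' `boundaryRef = "absolute"` to reference the raw peak value instead.
#'
#' @param trace data.frame from [networkActivity()] over the same raster.
#' @param raster the [SpikeRaster-class] the trace came from (for spike
#'   and electrode counts per burst).
#' @param thresholdMult robust-SD multiple above the median (default 7:
#'   the smoothed population trace of a 300 s Poisson background has a
#'   correlation time of ~2 kernel SDs, i.e. thousands of effectively
#'   independent samples, so a 3-SD threshold fires several times per
#'   scan on noise alone while synchronized bursts sit tens of robust
#'   SDs above baseline).
#' @param boundaryFrac boundary level as a fraction of peak height
#'   (default 0.1).
#' @param boundaryRef `"baseline"` (default) references the fraction to
#'   the peak height above the trace median; `"absolute"` to the raw
#'   peak value.
#' @return data.frame with columns `peak_time_s`, `start_s`, `end_s`,
#'   `duration_s`, `peak_rate_hz`, `spike_count`, `n_active_electrodes`;
#'   zero rows when the trace never crosses threshold.
#' @export
detectBursts <- function(trace, raster, thresholdMult = 7,
                         boundaryFrac = 0.1,
                         boundaryRef = c("baseline", "absolute")) {
  boundaryRef <- match.arg(boundaryRef)
  x <- trace$rate_hz
  tt <- trace$time_s
  bin <- tt[2L] - tt[1L]
  empty <- data.frame(peak_time_s = numeric(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak_rate_hz = numeric(0), spike_count = integer(0),
                      n_active_electrodes = integer(0))
  if (!any(x > 0)) return(empty)
  thr <- stats::median(x) + thresholdMult * stats::mad(x)
  above <- x > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  n_b <- length(starts)
  peaks <- integer(n_b)
  for (i in seq_len(n_b)) {
    seg <- starts[i]:ends[i]
    peaks[i] <- seg[which.max(x[seg])]
  }
  # boundaries: walk out to boundaryFrac * peak, clipped at inter-peak minima
  lo_lim <- c(1L, vapply(seq_len(n_b)[-1L], function(i) {
    seg <- peaks[i - 1L]:peaks[i]
    seg[which.min(x[seg])]
  }, integer(1)))
  hi_lim <- c(lo_lim[-1L], length(x))
  base <- stats::median(x)
  b_start <- b_end <- integer(n_b)
  for (i in seq_len(n_b)) {
    level <- if (boundaryRef == "baseline")
      base + boundaryFrac * (x[peaks[i]] - base)
    else boundaryFrac * x[peaks[i]]
    s <- peaks[i]
    while (s > lo_lim[i] && x[s - 1L] >= level) s <- s - 1L
    e <- peaks[i]
    while (e < hi_lim[i] && x[e + 1L] >= level) e <- e + 1L
    b_start[i] <- s
    b_end[i] <- e
  }
  times <- raster@spikeTimes
  sc <- integer(n_b)
  ne <- integer(n_b)
  w_lo <- tt[b_start] - bin / 2
  w_hi <- tt[b_end] + bin / 2
  for (i in seq_len(n_b)) {
    in_w <- vapply(times, function(ts)
      sum(ts >= w_lo[i] & ts <= w_hi[i]), numeric(1))
    sc[i] <- as.integer(sum(in_w))
    ne[i] <- as.integer(sum(in_w > 0))
  }
  data.frame(peak_time_s = tt[peaks], start_s = w_lo, end_s = w_hi,
             duration_s = w_hi - w_lo, peak_rate_hz = x[peaks],
             spike_count = sc, n_active_electrodes = ne)
}

#' Burst-level summary metrics
#'
#' The inter-burst interval (IBI) is the time between successive burst
#' peaks; it is undefined (reported `NA`) with fewer than two bursts.
#'
#' @param bursts data.frame from [detectBursts()].
#' @return list with `n_bursts`, `mean_ibi_s`, `mean_duration_s`,
#'   `mean_spikes_per_burst`.
#' @export
burstMetrics <- function(bursts) {
  n <- nrow(bursts)
  list(n_bursts = n,
       mean_ibi_s = if (n >= 2L) mean(diff(bursts$peak_time_s)) else NA_real_,
       mean_duration_s = if (n) mean(bursts$duration_s) else 0,
       mean_spikes_per_burst = if (n) mean(bursts$spike_count) else 0)
}
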
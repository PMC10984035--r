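#' @include AllClasses.R
NULL

#' Configuration for the synthetic HD-MEA raster
#'
#' Emulates a network scan: independent homogeneous Poisson background
#' firing on every electrode, with synchronized population bursts planted
#' at renewal times (exponential gaps plus a refractory minimum
#' separation, so bursts are resolvable events as in a real culture,
#' which cannot re-burst instantly). During a burst, a random
#' `participationFraction` of electrodes fire extra spikes under a
#' Gaussian time envelope of SD `burstSigma`, at an added intensity of
#' `(burstRateMultiplier - 1)` times the reference rate (the background
#' rate, or 1 Hz when the background is zero so that bursts exist even on
#' a silent background). Burst peaks keep an `edgeMargin` from both ends
#' so every planted burst is fully contained in the recording.
#'
#' @param nElectrodes number of electrodes (default 1024, the network
#'   assay subset).
#' @param duration recording length, seconds (default 300).
#' @param backgroundRate per-electrode background rate, Hz.
#' @param burstRate planted burst rate, bursts/min.
#' @param burstSigma burst envelope SD, seconds.
#' @param burstRateMultiplier within-burst rate multiple at the envelope
#'   peak.
#' @param participationFraction fraction of electrodes recruited per
#'   burst.
#' @param minIBI refractory minimum separation between burst peaks,
#'   seconds. The default, `max(1, 6 * burstSigma)`, keeps adjacent
#'   bursts resolvable after detection-side smoothing: the observable
#'   envelope width is the planted SD combined with the analysis kernel
#'   SD (in quadrature), so six of *those* widths is the relevant
#'   separation, and cultured networks do not re-burst faster than about
#'   once a second anyway.
#' @param edgeMargin burst peaks are kept at least this far from the
#'   recording edges, seconds.
#' @param div,genotype chip metadata echoed into the raster.
#' @param seed integer RNG seed.
#' @return list of class `meaSynthConfig`.
#' @seealso [simulateMEARaster()]
#' @export
meaSynthConfig <- function(nElectrodes = 1024, duration = 300,
                           backgroundRate = 1, burstRate = 6,
                           burstSigma = 0.1, burstRateMultiplier = 10,
                           participationFraction = 0.6,
                           minIBI = max(1, 6 * burstSigma), edgeMargin = 0.5,
                           div = 21L, genotype = "UNSPECIFIED",
                           seed = 1) {
  if (backgroundRate < 0 || burstRate < 0) stop("rates must be >= 0")
  if (participationFraction < 0 || participationFraction > 1)
    stop("participationFraction must be in [0, 1]")
  structure(list(
    nElectrodes = nElectrodes, duration = duration,
    backgroundRate = backgroundRate, burstRate = burstRate,
    burstSigma = burstSigma, burstRateMultiplier = burstRateMultiplier,
    participationFraction = participationFraction, minIBI = minIBI,
    edgeMargin = edgeMargin, div = div, genotype = genotype,
    seed = seed), class = "meaSynthConfig")
}

#' Simulate an HD-MEA spike raster with planted network bursts
#'
#' @param cfg list from [meaSynthConfig()].
#' @return list with `raster` (a [SpikeRaster-class]) and `truth` (list
#'   with `burstPeaks` in seconds and the echoed `config`).
#' @export
simulateMEARaster <- function(cfg) {
  stopifnot(inherits(cfg, "meaSynthConfig"))
  set.seed(cfg$seed)
  n_el <- cfg$nElectrodes
  dur <- cfg$duration

  # burst peak times: exponential gaps + refractory minimum separation
  peaks <- numeric(0)
  if (cfg$burstRate > 0) {
    lambda <- cfg$burstRate / 60
    gap_rate <- 1 / max(1 / lambda - cfg$minIBI, 1e-3)
    t <- cfg$edgeMargin + stats::rexp(1L, gap_rate)
    while (t < dur - cfg$edgeMargin) {
      peaks <- c(peaks, t)
      t <- t + cfg$minIBI + stats::rexp(1L, gap_rate)
    }
  }

  ref_rate <- if (cfg$backgroundRate > 0) cfg$backgroundRate else 1
  extra_mean <- (cfg$burstRateMultiplier - 1) * ref_rate *
    cfg$burstSigma * sqrt(2 * pi)

  st <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    n_bg <- stats::rpois(1L, cfg$backgroundRate * dur)
    st[[e]] <- stats::runif(n_bg, 0, dur)
  }
  n_part <- round(cfg$participationFraction * n_el)
  for (p in peaks) {
    members <- sample.int(n_el, n_part)
    n_extra <- stats::rpois(n_part, extra_mean)
    for (j in seq_len(n_part)) {
      if (n_extra[j] == 0L) next
      ts <- stats::rnorm(n_extra[j], p, cfg$burstSigma)
      ts <- ts[abs(ts - p) <= 4 * cfg$burstSigma & ts >= 0 & ts < dur]
      st[[members[j]]] <- c(st[[members[j]]], ts)
    }
  }
  raster <- SpikeRaster(seq_len(n_el), st, dur,
                        list(nElectrodesTotal = n_el, div = cfg$div,
                             genotype = cfg$genotype))
  list(raster = raster,
       truth = list(burstPeaks = peaks, config = cfg))
}
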
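#' @include AllClasses.R synth-noise.R
NULL

.stage_mix_matrix <- function(occupancy, stay) {
  occupancy <- occupancy / sum(occupancy)
  T <- stay * diag(4) + (1 - stay) * matrix(occupancy, 4, 4, byrow = TRUE)
  dimnames(T) <- list(.STAGES, .STAGES)
  T
}

#' Configuration for the synthetic EEG/EMG/activity session
#'
#' The generator emulates a telemetry session: a first-order Markov chain
#' over the four sleep stages switching at epoch boundaries, with
#' stage-dependent band-limited EEG noise, band-limited (30--100 Hz) EMG
#' noise, a stage-dependent activity level, and epileptiform spike trains
#' inserted as biphasic templates. The default transition matrix is the
#' mixture form `stay * I + (1 - stay) * occupancy`, whose stationary
#' distribution is exactly `occupancy` (geometric bouts of ~10 epochs at
#' `stay = 0.85`).
#'
#' Default per-stage amplitudes are calibrated so the staging anchors are
#' reachable: slow-wave sleep carries 4.5x the delta RMS of wake,
#' paradoxical sleep 2.5x the theta RMS and the lowest EMG, wake an EMG
#' power between the wake anchor (2.4) and the active-wake override (3.6)
#' relative to the recording median, and active wake an activity level
#' well above the 0.1 threshold.
#'
#' @param duration session length, seconds (default 72 h = 259,200 s).
#' @param eegRate,activityRate sampling rates (500 and 200 Hz).
#' @param epochLength state-switching epoch, seconds (default 10).
#' @param occupancy stationary stage probabilities (active wake, wake,
#'   SWS, paradoxical).
#' @param stay diagonal weight of the mixture transition matrix.
#' @param transitionMatrix optional explicit 4x4 row-stochastic matrix
#'   (overrides `occupancy`/`stay`).
#' @param bandAmps 4x5 matrix of per-stage RMS amplitudes (uV) for the
#'   delta, theta, alpha, beta, gamma bands; rows in stage order.
#' @param emgAmps per-stage EMG RMS amplitude, uV.
#' @param activityLevels per-stage activity level, arbitrary units.
#' @param activityNoiseSD additive Gaussian noise on the activity channel.
#' @param amplitudeJitterSD log-normal SD of the per-epoch, per-band
#'   amplitude jitter (biological variability on top of the spectral
#'   estimation noise).
#' @param spikeTrainsPerHour expected epileptiform train rate.
#' @param spikesPerTrain integer range of spikes per train.
#' @param spikeISIRange inter-spike onset interval range, seconds.
#' @param spikeAmplitude,spikeDurationMs biphasic template peak (uV) and
#'   width (ms).
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical sessions.
#' @return list of class `eegSynthConfig`.
#' @seealso [simulateEEGSession()], [injectGenotypeEffect()]
#' @export
eegSynthConfig <- function(duration = 259200, eegRate = 500,
                           activityRate = 200, epochLength = 10,
                           occupancy = c(ACTIVE_WAKE = 0.10, WAKE = 0.20,
                                         SWS = 0.55, PARADOXICAL = 0.15),
                           stay = 0.85, transitionMatrix = NULL,
                           bandAmps = NULL,
                           emgAmps = c(25, 14, 10, 6),
                           activityLevels = c(0.5, 0, 0, 0),
                           activityNoiseSD = 0.02,
                           amplitudeJitterSD = 0.1,
                           spikeTrainsPerHour = 10,
                           spikesPerTrain = c(4, 8),
                           spikeISIRange = c(0.1, 0.4),
                           spikeAmplitude = 350, spikeDurationMs = 8,
                           seed = 1) {
  if (is.null(bandAmps)) {
    bandAmps <- rbind(ACTIVE_WAKE = c(10, 10, 6, 5, 4),
                      WAKE        = c(10, 10, 6, 5, 4),
                      SWS         = c(45, 10, 6, 5, 4),
                      PARADOXICAL = c(7, 25, 6, 5, 4))
    colnames(bandAmps) <- c("delta", "theta", "alpha", "beta", "gamma")
  }
  if (is.null(transitionMatrix))
    transitionMatrix <- .stage_mix_matrix(occupancy, stay)
  if (!all(dim(transitionMatrix) == c(4L, 4L)) ||
      any(transitionMatrix < 0) ||
      any(abs(rowSums(transitionMatrix) - 1) > 1e-8))
    stop("transitionMatrix must be 4x4 row-stochastic")
  if (duration <= 0) stop("duration must be positive")
  if (any(bandAmps < 0) || any(emgAmps < 0)) stop("amplitudes must be >= 0")
  structure(list(
    duration = duration, eegRate = eegRate, activityRate = activityRate,
    epochLength = epochLength, occupancy = occupancy / sum(occupancy),
    stay = stay, transitionMatrix = transitionMatrix,
    bandAmps = bandAmps, emgAmps = emgAmps,
    activityLevels = activityLevels, activityNoiseSD = activityNoiseSD,
    amplitudeJitterSD = amplitudeJitterSD,
    spikeTrainsPerHour = spikeTrainsPerHour,
    spikesPerTrain = spikesPerTrain, spikeISIRange = spikeISIRange,
    spikeAmplitude = spikeAmplitude, spikeDurationMs = spikeDurationMs,
    seed = seed), class = "eegSynthConfig")
}

.stationary <- function(T) {
  p <- rep(0.25, 4)
  for (i in 1:500) p <- as.numeric(p %*% T)
  p / sum(p)
}

#' Simulate a telemetry EEG/EMG/activity session
#'
#' Generates a [Recording-class] plus ground truth from an
#' [eegSynthConfig()]. States evolve as a Markov chain at epoch
#' granularity (no mid-epoch transitions, matching the epoch-granular
#' scorer); per epoch the EEG is a sum of band-limited Gaussian noise at
#' the stage's band amplitudes (with per-epoch log-normal jitter), the
#' EMG is 30--100 Hz noise at the stage amplitude and the activity
#' channel is the stage level plus clamped Gaussian noise. Spike trains
#' are inserted as biphasic templates at Poisson train times.
#'
#' @param cfg list from [eegSynthConfig()].
#' @return list with `recording` (a [Recording-class]), and `truth`: a
#'   list with `stages` (per-epoch labels), `spikeOnsets` (s),
#'   `trainStarts` (s) and the echoed `config`.
#' @export
simulateEEGSession <- function(cfg) {
  stopifnot(inherits(cfg, "eegSynthConfig"))
  set.seed(cfg$seed)
  L <- cfg$epochLength
  n_ep <- floor(cfg$duration / L)
  if (n_ep < 1L) stop("duration shorter than one epoch")
  n_eeg <- round(cfg$eegRate * L)
  n_act <- round(cfg$activityRate * L)

  # stage chain
  stages <- integer(n_ep)
  stages[1L] <- sample.int(4L, 1L, prob = .stationary(cfg$transitionMatrix))
  for (k in seq_len(n_ep - 1L))
    stages[k + 1L] <- sample.int(4L, 1L,
                                 prob = cfg$transitionMatrix[stages[k], ])

  bands <- eegBands()
  eeg <- numeric(n_ep * n_eeg)
  emg <- numeric(n_ep * n_eeg)
  act <- numeric(n_ep * n_act)
  jit <- cfg$amplitudeJitterSD
  for (k in seq_len(n_ep)) {
    s <- stages[k]
    amps <- cfg$bandAmps[s, ] * exp(stats::rnorm(5, 0, jit))
    e_amp <- cfg$emgAmps[s] * exp(stats::rnorm(1, 0, jit))
    i_eeg <- (k - 1L) * n_eeg + seq_len(n_eeg)
    eeg[i_eeg] <- bandNoise(n_eeg, cfg$eegRate, bands$lo, bands$hi, amps)
    emg[i_eeg] <- bandNoise(n_eeg, cfg$eegRate, 30, 100, e_amp)
    i_act <- (k - 1L) * n_act + seq_len(n_act)
    act[i_act] <- pmax(0, cfg$activityLevels[s] +
                         stats::rnorm(n_act, 0, cfg$activityNoiseSD))
  }

  # epileptiform spike trains
  dur_gen <- n_ep * L
  n_trains <- stats::rpois(1L, cfg$spikeTrainsPerHour * dur_gen / 3600)
  onsets <- numeric(0)
  train_starts <- numeric(0)
  if (n_trains > 0L) {
    starts <- sort(stats::runif(n_trains, 1, max(1, dur_gen - 10)))
    starts <- starts[c(TRUE, diff(starts) >= 5)]   # no overlapping trains
    for (t0 in starts) {
      n_sp <- sample(seq(cfg$spikesPerTrain[1], cfg$spikesPerTrain[2]), 1L)
      isi <- stats::runif(n_sp - 1L, cfg$spikeISIRange[1],
                          cfg$spikeISIRange[2])
      onsets <- c(onsets, t0 + c(0, cumsum(isi)))
    }
    train_starts <- starts
    ns <- max(2L, round(cfg$eegRate * cfg$spikeDurationMs / 1000))
    half <- ceiling(ns / 2)
    tmpl <- cfg$spikeAmplitude * c(rep(1, half), rep(-1, ns - half))
    onsets <- onsets[onsets < dur_gen - ns / cfg$eegRate]
    for (t0 in onsets) {
      i0 <- floor(t0 * cfg$eegRate) + 1L
      eeg[i0:(i0 + ns - 1L)] <- eeg[i0:(i0 + ns - 1L)] + tmpl
    }
  }

  rec <- Recording(eeg = eeg, emg = emg, activity = act,
                   eegRate = cfg$eegRate, activityRate = cfg$activityRate,
                   subjectID = "synthetic", genotype = "UNSPECIFIED",
                   duration = dur_gen)
  list(recording = rec,
       truth = list(stages = .STAGES[stages], epochLength = L,
                    spikeOnsets = onsets, trainStarts = train_starts,
                    config = cfg))
}

#' Apply a genotype effect to a synthetic configuration
#'
#' Maps a genotype label onto the generator parameters: wild type is the
#' identity; the heterozygote multiplies the delta-band amplitude, the
#' spike-train rate and (for MEA configs) the burst rate, shrinks the
#' burst refractory interval, and optionally tilts the stage occupancy
#' away from slow-wave sleep. Effect sizes default to the directionality
#' observed in the modelled phenotype: elevated delta power, more spike
#' trains, more bursts with shorter inter-burst intervals, less SWS.
#'
#' @param cfg an [eegSynthConfig()] or [meaSynthConfig()] list.
#' @param genotype `"WT"` or `"HET"`.
#' @param effects named list: `delta_amp_mult` (default sqrt(2), i.e. a
#'   doubling of delta power), `spike_rate_mult` (2), `burst_rate_mult`
#'   (2), `ibi_shrink` (0.5), `sws_occupancy_mult` (0.85).
#' @return the modified config (same class).
#' @export
injectGenotypeEffect <- function(cfg, genotype = c("HET", "WT"),
                                 effects = list()) {
  genotype <- match.arg(genotype)
  eff <- utils::modifyList(
    list(delta_amp_mult = sqrt(2), spike_rate_mult = 2,
         burst_rate_mult = 2, ibi_shrink = 0.5,
         sws_occupancy_mult = 0.85), effects)
  if (any(unlist(eff) <= 0)) stop("effect multipliers must be positive")
  if (genotype == "WT") return(cfg)
  if (inherits(cfg, "eegSynthConfig")) {
    cfg$bandAmps[, "delta"] <- cfg$bandAmps[, "delta"] * eff$delta_amp_mult
    cfg$spikeTrainsPerHour <- cfg$spikeTrainsPerHour * eff$spike_rate_mult
    if (eff$sws_occupancy_mult != 1) {
      mixture <- .stage_mix_matrix(cfg$occupancy, cfg$stay)
      if (!isTRUE(all.equal(unname(cfg$transitionMatrix),
                            unname(mixture)))) {
        warning("custom transition matrix: occupancy tilt skipped")
      } else {
        occ <- cfg$occupancy
        occ[3L] <- occ[3L] * eff$sws_occupancy_mult
        occ <- occ / sum(occ)
        cfg$occupancy <- occ
        cfg$transitionMatrix <- .stage_mix_matrix(occ, cfg$stay)
      }
    }
  } else if (inherits(cfg, "meaSynthConfig")) {
    cfg$burstRate <- cfg$burstRate * eff$burst_rate_mult
    cfg$minIBI <- cfg$minIBI * eff$ibi_shrink
  } else stop("cfg must be an eegSynthConfig or meaSynthConfig")
  cfg
}
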
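#' Configuration for the synthetic dyad generator
#'
#' Describes a simulated mother-infant dual-EEG cohort with known ground-truth
#' cross-brain coupling. Each member's signal is independent 1/f background
#' noise; within every condition block a shared narrow-band oscillator
#' (band-passed white noise) is added to the designated channels of both
#' members, with a constant cross-brain phase offset `lag_phase`, at an
#' amplitude proportional to the coupling strength `kappa` for that
#' (condition, band). Zero-lag coupling (`lag_phase` a multiple of pi) is
#' rejected when any `kappa > 0`, because the weighted Phase Lag Index is by
#' construction blind to it.
#'
#' @param n_dyads number of dyads in the cohort (default 33).
#' @param srate sampling rate in Hz (default 512).
#' @param channels electrode labels per person (default the canonical
#'   12-channel montage, [analysis_channels()]).
#' @param schedule data.frame with columns `condition` and `duration` (s);
#'   default the five-phase Still-Face Paradigm: FP1, SF1, FP2, SF2, RU at
#'   120 s each.
#' @param kappa numeric matrix of coupling strengths in `[0, 1]`, rows =
#'   conditions, columns = bands (`theta`, `alpha`). Default 0.5 in free-play
#'   and reunion phases and 0.35 in both still-face phases, i.e. a 0.15 drop
#'   under smartphone distraction in both bands.
#' @param lag_phase constant cross-brain phase offset delta in radians
#'   (default pi/4).
#' @param noise_exponent slope of the 1/f^a background-noise spectrum
#'   (default 1).
#' @param noise_sd background-noise RMS per channel in microvolts (default 10).
#' @param osc_amplitude common-oscillator RMS in microvolts at `kappa = 1`
#'   (default 2.5); chosen so that free-play global wPLI lands in the
#'   0.35-0.45 range typical of parent-infant cohorts.
#' @param artifact_rate movement-artifact bursts per minute on the infant's
#'   channels (default 3).
#' @param artifact_amplitude peak amplitude of a burst in microvolts
#'   (default 400).
#' @param artifact_duration burst duration in seconds (default 0.5).
#' @param coupling list with elements `mother` and `infant`: the channel
#'   subsets that receive the common oscillator. Cross-brain pairs in
#'   `mother x infant` are the coupled pairs recorded in the ground truth.
#'   Default: all channels of both members.
#' @param seed base RNG seed; dyad `i` uses `seed + i`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_dyads = 33L,
                         srate = 512,
                         channels = analysis_channels(),
                         schedule = default_schedule(),
                         kappa = default_kappa(schedule$condition),
                         lag_phase = pi / 4,
                         noise_exponent = 1,
                         noise_sd = 10,
                         osc_amplitude = 2.5,
                         artifact_rate = 3,
                         artifact_amplitude = 400,
                         artifact_duration = 0.5,
                         coupling = list(mother = channels, infant = channels),
                         seed = 1L) {
  stopifnot(n_dyads >= 1, srate > 0, length(channels) >= 1)
  if (!all(c("condition", "duration") %in% names(schedule)))
    stop("schedule needs columns 'condition' and 'duration'")
  if (any(schedule$duration <= 0))
    stop("schedule durations must be > 0")
  kappa <- as.matrix(kappa)
  if (is.null(rownames(kappa)) || is.null(colnames(kappa)))
    stop("kappa must have condition rownames and band colnames")
  if (!all(schedule$condition %in% rownames(kappa)))
    stop("kappa map is missing conditions: ",
         paste(setdiff(schedule$condition, rownames(kappa)), collapse = ", "))
  if (any(kappa < 0 | kappa > 1))
    stop("kappa values must lie in [0, 1]")
  if (any(kappa > 0) && isTRUE(all.equal(sin(lag_phase), 0)))
    stop("lag_phase must not be 0 (mod pi) when kappa > 0: ",
         "zero-lag coupling is invisible to wPLI")
  if (!all(coupling$mother %in% channels) || !all(coupling$infant %in% channels))
    stop("coupling channel subsets must be drawn from 'channels'")
  structure(list(
    n_dyads = as.integer(n_dyads), srate = srate, channels = channels,
    schedule = schedule, kappa = kappa, lag_phase = lag_phase,
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    osc_amplitude = osc_amplitude, artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    artifact_duration = artifact_duration,
    coupling = coupling, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default five-phase Still-Face Paradigm schedule
#'
#' Five contiguous 2-minute blocks: first free play (FP1), first still-face
#' (SF1), second free play (FP2), second still-face (SF2), reunion (RU) —
#' 10 minutes of interaction in total.
#'
#' @param duration block duration in seconds (default 120).
#' @return data.frame with columns `condition` and `duration`.
#' @export
default_schedule <- function(duration = 120) {
  data.frame(condition = c("FP1", "SF1", "FP2", "SF2", "RU"),
             duration = duration)
}

#' Default coupling-strength map
#'
#' Coupling 0.5 during free play and reunion, 0.35 during both still-face
#' phases (a drop of 0.15), identically in the theta and alpha bands.
#'
#' @param conditions condition labels (rows of the returned matrix).
#' @param base free-play/reunion coupling strength.
#' @param sf_drop reduction applied in conditions whose label starts "SF".
#' @return numeric matrix conditions x bands (`theta`, `alpha`).
#' @export
default_kappa <- function(conditions = c("FP1", "SF1", "FP2", "SF2", "RU"),
                          base = 0.5, sf_drop = 0.15) {
  k <- matrix(base, nrow = length(conditions), ncol = 2,
              dimnames = list(conditions, c("theta", "alpha")))
  sf <- grepl("^SF", conditions)
  k[sf, ] <- base - sf_drop
  k
}

#' Expand a generator configuration into ordered condition annotations
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `condition`, `onset` (s) and `duration`
#'   (s); blocks are contiguous and ordered as given.
#' @export
#' @examples
#' make_condition_schedule(synth_config(n_dyads = 1))
make_condition_schedule <- function(config) {
  sch <- config$schedule
  if (any(sch$duration <= 0)) stop("schedule durations must be > 0")
  data.frame(condition = sch$condition,
             onset = cumsum(c(0, sch$duration[-nrow(sch)])),
             duration = sch$duration)
}

# 1/f^a Gaussian noise of length n, unit RMS, via FFT spectral shaping.
pink_noise <- function(n, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  wf <- fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                # two-sided frequency index
  f[1] <- 1                          # DC bin kept flat
  shaped <- Re(fft(wf * f^(-exponent / 2), inverse = TRUE)) / n
  shaped / sqrt(mean(shaped^2))
}

# Band-passed white noise of length n with unit RMS; band in Hz.
narrowband_noise <- function(n, band, srate) {
  flt <- signal::butter(4, band / (srate / 2), type = "pass")
  x <- zero_phase(flt, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate one synthetic dyad recording with ground truth
#'
#' Builds the two members' channels x samples signal matrices: independent
#' 1/f background noise per channel, plus — on the configured coupling
#' channels, within each condition block — a shared band-limited oscillator at
#' amplitude `osc_amplitude * kappa[condition, band]`. The infant receives a
#' copy of the oscillator whose instantaneous phase is delayed by `lag_phase`
#' radians (implemented through the analytic signal, so the offset is constant
#' across the band). Movement-artifact bursts (low-frequency, high-amplitude,
#' Hann-windowed) are injected on the infant's channels at the configured
#' rate. Fully deterministic given `(config$seed, dyad_index)`.
#'
#' @param config a [synth_config()].
#' @param dyad_index positive integer identifying the dyad; the RNG is seeded
#'   with `config$seed + dyad_index`.
#' @return list with elements `recording` (a [dyad_recording()]) and `truth`
#'   (data.frame: dyad_id, condition, band, mother_channel, infant_channel,
#'   kappa for every cross-brain pair, 0 where uncoupled).
#' @export
generate_dyad <- function(config, dyad_index) {
  stopifnot(inherits(config, "synth_config"), dyad_index >= 1)
  set.seed(config$seed + as.integer(dyad_index))
  sch <- make_condition_schedule(config)
  srate <- config$srate
  chs <- config$channels
  nch <- length(chs)
  n_total <- round(sum(sch$duration) * srate)
  bands <- list(theta = c(3, 5), alpha = c(6, 9))
  if (!all(colnames(config$kappa) %in% names(bands)))
    stop("unknown band in kappa map: ",
         paste(setdiff(colnames(config$kappa), names(bands)), collapse = ", "))

  member_noise <- function() {
    m <- matrix(0, nch, n_total, dimnames = list(chs, NULL))
    if (config$noise_sd > 0)
      for (c in seq_len(nch))
        m[c, ] <- config$noise_sd * pink_noise(n_total, config$noise_exponent)
    m
  }
  mother <- member_noise()
  infant <- member_noise()

  # per-sample coupling gain per band, from the condition schedule
  cond_at <- rep(sch$condition, times = round(sch$duration * srate))[seq_len(n_total)]
  m_idx <- match(config$coupling$mother, chs)
  i_idx <- match(config$coupling$infant, chs)
  for (b in colnames(config$kappa)) {
    osc <- narrowband_noise(n_total, bands[[b]], srate)
    osc_i <- Re(analytic_signal(osc)[1, ] * exp(-1i * config$lag_phase))
    gain <- config$osc_amplitude * config$kappa[cond_at, b]
    for (c in m_idx) mother[c, ] <- mother[c, ] + gain * osc
    for (c in i_idx) infant[c, ] <- infant[c, ] + gain * osc_i
  }

  # movement-artifact bursts on the infant
  if (config$artifact_rate > 0) {
    n_bursts <- rpois(1, config$artifact_rate * sum(sch$duration) / 60)
    blen <- round(config$artifact_duration * srate)
    if (n_bursts > 0 && blen > 1) {
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blen)))
      tt <- seq_len(blen) / srate
      for (k in seq_len(n_bursts)) {
        at <- sample.int(n_total - blen, 1)
        carrier <- sin(2 * pi * runif(1, 1, 3) * tt + runif(1, 0, 2 * pi))
        burst <- config$artifact_amplitude * win * carrier
        scl <- runif(nch, 0.5, 1)
        infant[, at:(at + blen - 1)] <-
          infant[, at:(at + blen - 1)] + outer(scl, burst)
      }
    }
  }

  dyad_id <- sprintf("dyad%03d", as.integer(dyad_index))
  rec <- dyad_recording(
    mother = mother, infant = infant, srate = srate, channel_labels = chs,
    annotations = data.frame(onset = sch$onset, duration = sch$duration,
                             condition = sch$condition),
    dyad_id = dyad_id,
    infant_age = round(runif(1, 5, 12), 1),
    infant_sex = sample(c("F", "M"), 1)
  )

  grid <- expand.grid(mother_channel = config$coupling$mother,
                      infant_channel = config$coupling$infant,
                      stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(colnames(config$kappa), function(b) {
    do.call(rbind, lapply(sch$condition, function(cond) {
      data.frame(dyad_id = dyad_id, condition = cond, band = b,
                 grid, kappa = config$kappa[cond, b])
    }))
  }))
  list(recording = rec, truth = truth)
}

#' Generate a cohort of synthetic dyads
#'
#' @param config a [synth_config()].
#' @return list with elements `recordings` (list of [dyad_recording()]) and
#'   `truth` (row-bound ground-truth data.frame).
#' @export
generate_cohort <- function(config) {
  out <- lapply(seq_len(config$n_dyads), function(i) generate_dyad(config, i))
  list(recordings = lapply(out, `[[`, "recording"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}
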
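# Cross-brain phase synchrony: band-limited Hilbert phases, per-epoch wPLI
# (and PLV) over all mother x infant channel pairs, permutation-surrogate
# validation, and aggregation to trial-averaged and global synchrony.

#' Frequency band specification
#'
#' The two developmental bands of interest: infant theta (3-5 Hz) and infant
#' alpha (6-9 Hz). Custom edges are accepted for exploration.
#'
#' @param name band name; `"theta"` and `"alpha"` carry default edges.
#' @param low,high band edges in Hz; defaults follow `name`.
#' @return An object of class `band_spec` with fields `name`, `low`, `high`.
#' @export
#' @examples
#' band_spec("theta")
#' band_spec("alpha")
band_spec <- function(name, low = NULL, high = NULL) {
  defaults <- list(theta = c(3, 5), alpha = c(6, 9))
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(defaults))
      stop("no default edges for band '", name, "'; give low and high")
    low <- defaults[[name]][1]; high <- defaults[[name]][2]
  }
  stopifnot(low > 0, high > low)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Band-limit hyper-epochs and extract instantaneous phases
#'
#' For every retained hyper-epoch: zero-phase Butterworth band-pass (order 4)
#' in the requested band, then the analytic-signal (Hilbert) instantaneous
#' phase per channel and member. The phase difference for a mother-channel
#' `j` x infant-channel `k` pair is `phi_mother_j - phi_infant_k`.
#'
#' @param epochs a `hyper_epochs` object (12 analysis channels per member).
#' @param band a [band_spec()] or band name.
#' @return list of `phase_pair` objects, one per epoch, each with fields
#'   `phi_mother`, `phi_infant` (channels x samples, radians in (-pi, pi]),
#'   `band`, `condition`, `epoch_index`.
#' @export
bandpass_and_phase <- function(epochs, band) {
  stopifnot(inherits(epochs, "hyper_epochs"))
  if (is.character(band)) band <- band_spec(band)
  nyq <- epochs$recording$srate / 2
  if (band$high >= nyq) stop("band edge at or above Nyquist")
  if (nrow(epochs$info) == 0) stop("no epochs to process")
  flt <- signal::butter(4, c(band$low, band$high) / nyq, type = "pass")
  labs <- epochs$recording$channel_labels
  lapply(seq_len(nrow(epochs$info)), function(i) {
    s <- epoch_signals(epochs, i)
    phi_m <- instantaneous_phase(zero_phase(flt, s$mother))
    phi_i <- instantaneous_phase(zero_phase(flt, s$infant))
    rownames(phi_m) <- rownames(phi_i) <- labs
    structure(list(
      phi_mother = phi_m,
      phi_infant = phi_i,
      band = band$name,
      condition = epochs$info$condition[i],
      epoch_index = epochs$info$epoch_index[i]
    ), class = "phase_pair")
  })
}

#' Unwrap a phase series
#'
#' Removes the 2-pi jumps of a wrapped instantaneous-phase series so that
#' slopes (instantaneous frequencies) can be read off directly.
#'
#' @param phi numeric vector of wrapped phases in radians.
#' @return numeric vector of unwrapped phases.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  jumps <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  phi + jumps
}

#' Phase-difference series for one channel pair
#'
#' @param pp a `phase_pair`.
#' @param mother_channel,infant_channel row indices or labels.
#' @return numeric vector of wrapped phase differences in (-pi, pi].
#' @export
delta_phi <- function(pp, mother_channel, infant_channel) {
  d <- pp$phi_mother[mother_channel, ] - pp$phi_infant[infant_channel, ]
  Arg(exp(1i * d))
}

#' Weighted Phase Lag Index of a phase-difference series
#'
#' `wPLI = |mean(|sin d| * sign(sin d))| / mean(|sin d|)`, i.e. the magnitude
#' of the signed mean of `sin(delta phi)` normalized by the mean magnitude.
#' It is 1 when every sample's phase difference lies on one side of zero
#' (consistent lead or lag) and 0 when leads and lags balance. A series with
#' `sin(delta phi) = 0` everywhere (pure zero-lag coupling) returns 0 by
#' convention — blindness to zero-lag coupling is the measure's defence
#' against volume conduction.
#'
#' @param delta_phi numeric vector of phase differences in radians.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' wpli_pair(rep(pi / 2, 100))                 # 1: perfect nonzero-lag lock
#' wpli_pair(rep(c(pi / 2, -pi / 2), 50))      # 0: leads and lags cancel
#' wpli_pair(c(pi / 2, pi / 2, pi / 2, -pi / 2))  # 0.5
wpli_pair <- function(delta_phi) {
  if (!length(delta_phi)) stop("empty phase-difference series")
  s <- sin(delta_phi)
  den <- mean(abs(s))
  if (den == 0) return(0)
  abs(mean(s)) / den
}

#' Phase Locking Value of a phase-difference series
#'
#' Modulus of the mean unit phasor `|mean(exp(i delta phi))|`; 1 for a
#' constant phase difference (including zero lag), ~`sqrt(pi / (4N))` in
#' expectation for uniform noise.
#'
#' @param delta_phi numeric vector of phase differences in radians.
#' @return scalar in `[0, 1]`.
#' @export
plv_pair <- function(delta_phi) {
  if (!length(delta_phi)) stop("empty phase-difference series")
  Mod(mean(exp(1i * delta_phi)))
}

#' Surrogate validation of per-epoch channel-pair synchrony
#'
#' For each of the 144 mother x infant channel pairs, the observed wPLI is
#' compared with `n_surrogates` null values obtained by independently
#' permuting the time order of the mother's phase series (one fresh uniform
#' permutation per surrogate per pair), which destroys cross-member phase
#' relations while preserving each marginal phase distribution. A pair-epoch
#' is retained iff the observed wPLI strictly exceeds at least
#' `ceiling((1 - level) * n_surrogates)` surrogate values (ties count against
#' retention). Deterministic given the R RNG seed.
#'
#' @param pp a `phase_pair`.
#' @param n_surrogates number of permutations (default 200).
#' @param level significance level (default 0.05).
#' @return logical mother x infant matrix: `TRUE` where retained.
#' @export
surrogate_validate <- function(pp, n_surrogates = 200, level = 0.05) {
  stopifnot(inherits(pp, "phase_pair"), n_surrogates >= 20)
  res <- .surrogate_counts(pp$phi_mother, pp$phi_infant,
                           as.integer(n_surrogates), FALSE)
  res$wpli_below >= ceiling((1 - level) * n_surrogates)
}

#' Per-epoch cross-brain connectivity with optional surrogate validation
#'
#' Computes the full mother x infant wPLI (and PLV) matrices for one
#' hyper-epoch and, when `n_surrogates > 0`, the surrogate validity mask
#' (see [surrogate_validate()]). With `n_surrogates = 0` every pair is
#' marked valid.
#'
#' @param pp a `phase_pair`.
#' @param n_surrogates permutations for the null (default 200; 0 disables).
#' @param level significance level (default 0.05).
#' @param compute_plv also run the surrogate test on PLV and attach
#'   `plv_valid` (default FALSE).
#' @return An `epoch_connectivity` object: `wpli`, `plv` (matrices in
#'   `[0, 1]`), `valid` (logical matrix), `condition`, `band`, `epoch_index`.
#' @export
epoch_connectivity <- function(pp, n_surrogates = 200, level = 0.05,
                               compute_plv = FALSE) {
  stopifnot(inherits(pp, "phase_pair"))
  if (n_surrogates > 0) {
    res <- .surrogate_counts(pp$phi_mother, pp$phi_infant,
                             as.integer(n_surrogates), compute_plv)
    need <- ceiling((1 - level) * n_surrogates)
    valid <- res$wpli_below >= need
    plv_valid <- if (compute_plv) res$plv_below >= need else NULL
  } else {
    res <- .wpli_plv_matrices(pp$phi_mother, pp$phi_infant)
    valid <- matrix(TRUE, nrow(res$wpli), ncol(res$wpli))
    plv_valid <- NULL
  }
  dn <- list(rownames(pp$phi_mother), rownames(pp$phi_infant))
  dimnames(res$wpli) <- dimnames(res$plv) <- dimnames(valid) <- dn
  structure(list(wpli = res$wpli, plv = res$plv, valid = valid,
                 plv_valid = plv_valid, condition = pp$condition,
                 band = pp$band, epoch_index = pp$epoch_index),
            class = "epoch_connectivity")
}

#' Aggregate per-epoch connectivity to trial-averaged and global synchrony
#'
#' For one dyad and band: groups epoch-level wPLI matrices by condition,
#' averages each channel pair over the epochs in which it was retained by
#' the surrogate test (trial-averaged wPLI), and takes the mean of the
#' resulting 12 x 12 matrix as the scalar global wPLI. Exclusion granularity
#' follows `granularity`: `"pair_epoch"` (default) drops individual
#' non-validated pair-epoch values; `"epoch"` drops a whole epoch when fewer
#' than half of its pairs validate.
#'
#' @param epoch_conns list of `epoch_connectivity` objects (one band).
#' @param granularity `"pair_epoch"` or `"epoch"`.
#' @return data.frame rows per condition with the per-pair matrix in column
#'   `pair_matrix` (list column), `global_wpli`, `retention_fraction` and
#'   `n_epochs`; class `synchrony_rows`.
#' @export
aggregate_connectivity <- function(epoch_conns,
                                   granularity = c("pair_epoch", "epoch")) {
  granularity <- match.arg(granularity)
  stopifnot(length(epoch_conns) >= 1)
  bands <- unique(vapply(epoch_conns, `[[`, "", "band"))
  if (length(bands) != 1) stop("mixed bands; aggregate one band at a time")
  conds <- vapply(epoch_conns, `[[`, "", "condition")
  rows <- lapply(unique(conds), function(cond) {
    ec <- epoch_conns[conds == cond]
    w <- vapply(ec, `[[`, ec[[1]]$wpli, "wpli")            # nm x ni x nep
    v <- vapply(ec, `[[`, ec[[1]]$valid, "valid") * 1
    if (granularity == "epoch") {
      ep_ok <- apply(v, 3, mean) >= 0.5
      if (!any(ep_ok)) {
        warning("condition ", cond, ": no epoch retained")
        return(NULL)
      }
      w <- w[, , ep_ok, drop = FALSE]
      v <- array(1, dim(w))
    }
    n_ret <- apply(v, c(1, 2), sum)
    pair_sum <- apply(w * v, c(1, 2), sum)
    pair_matrix <- ifelse(n_ret > 0, pair_sum / n_ret, NA_real_)
    dimnames(pair_matrix) <- dimnames(ec[[1]]$wpli)
    if (all(n_ret == 0)) {
      warning("condition ", cond, ": no retained pair-epoch values")
      return(NULL)
    }
    data.frame(band = bands, condition = cond,
               global_wpli = mean(pair_matrix, na.rm = TRUE),
               retention_fraction = mean(v),
               n_epochs = dim(w)[3],
               pair_matrix = I(list(pair_matrix)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("synchrony_rows", class(out))
  out
}

#' Full per-dyad synchrony computation
#'
#' Runs the connectivity stage end to end for one preprocessed dyad:
#' hyper-epoch phase extraction per band, per-epoch wPLI with surrogate
#' validation, and aggregation to trial-averaged/global synchrony per
#' condition. The RNG is seeded `base_seed + dyad_index` so cohort runs are
#' reproducible dyad by dyad.
#'
#' @param epochs a `hyper_epochs` object (after channel selection and
#'   artifact rejection).
#' @param bands character vector of band names (default theta and alpha).
#' @param n_surrogates surrogate count (default 200; 0 disables validation).
#' @param level surrogate significance level (default 0.05).
#' @param granularity see [aggregate_connectivity()].
#' @param seed optional integer; when given, `set.seed(seed)` before the
#'   surrogate draws.
#' @return A `synchrony_table`: data.frame with one row per (band,
#'   condition), columns `dyad_id`, `infant_age`, `infant_sex`, `band`,
#'   `condition`, `global_wpli`, `retention_fraction`, `n_epochs` and the
#'   list column `pair_matrix`.
#' @export
dyad_synchrony <- function(epochs, bands = c("theta", "alpha"),
                           n_surrogates = 200, level = 0.05,
                           granularity = "pair_epoch", seed = NULL) {
  stopifnot(inherits(epochs, "hyper_epochs"))
  if (!is.null(seed)) set.seed(seed)
  rec <- epochs$recording
  out <- do.call(rbind, lapply(bands, function(b) {
    pps <- bandpass_and_phase(epochs, b)
    ecs <- lapply(pps, epoch_connectivity, n_surrogates = n_surrogates,
                  level = level)
    aggregate_connectivity(ecs, granularity = granularity)
  }))
  cbind(data.frame(dyad_id = rec$dyad_id, infant_age = rec$infant_age,
                   infant_sex = rec$infant_sex), out)
}

#' Preprocess and analyse one raw dyad recording
#'
#' Convenience wrapper chaining the standard stages: broad-band filtering
#' ([filter_raw()]), channel selection ([select_channels()]), hyper-epoch
#' segmentation ([make_hyper_epochs()]), amplitude-based artifact rejection
#' ([reject_artifacts()]) and [dyad_synchrony()].
#'
#' @param rec a raw [dyad_recording()].
#' @param mother_pp,infant_pp artifact thresholds (microvolts).
#' @param epoch_s,overlap epoch length (s) and fractional overlap.
#' @param ... passed to [dyad_synchrony()].
#' @return a `synchrony_table` (see [dyad_synchrony()]).
#' @export
process_dyad <- function(rec, mother_pp = 100, infant_pp = 200,
                         epoch_s = 2, overlap = 0.5, ...) {
  rec |>
    filter_raw() |>
    select_channels() |>
    make_hyper_epochs(epoch_s = epoch_s, overlap = overlap) |>
    reject_artifacts(mother_pp = mother_pp, infant_pp = infant_pp) |>
    dyad_synchrony(...)
}

#' Long-format per-pair synchrony table
#'
#' @param st a `synchrony_table` from [dyad_synchrony()].
#' @return data.frame (dyad_id, band, condition, mother_channel,
#'   infant_channel, trial_averaged_wpli).
#' @export
pairwise_long <- function(st) {
  do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    m <- st$pair_matrix[[i]]
    data.frame(dyad_id = st$dyad_id[i], band = st$band[i],
               condition = st$condition[i],
               mother_channel = rep(rownames(m), times = ncol(m)),
               infant_channel = rep(colnames(m), each = nrow(m)),
               trial_averaged_wpli = as.vector(m))
  }))
}
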
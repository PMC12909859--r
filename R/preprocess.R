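# Filtering, bad-channel repair, channel selection and hyper-epoch
# segmentation of time-locked dual recordings.

#' Broad-band filter a dual recording
#'
#' Applies, identically to both members, a zero-phase (forward-backward)
#' Butterworth high-pass, low-pass and band-stop (notch) cascade. Zero-phase
#' filtering introduces no group delay, so the cross-member phase relations
#' that the wPLI measures are untouched.
#'
#' @param rec a [dyad_recording()].
#' @param hp high-pass edge in Hz (default 1); `NULL` to skip.
#' @param lp low-pass edge in Hz (default 30); `NULL` to skip.
#' @param notch line-noise centre frequency in Hz (default 50); `NULL` to
#'   skip. The stop band is `notch` +/- 2 Hz.
#' @param order Butterworth order for the high/low-pass (default 4); the
#'   notch uses order 2.
#' @return the filtered [dyad_recording()].
#' @export
filter_raw <- function(rec, hp = 1, lp = 30, notch = 50, order = 4) {
  stopifnot(inherits(rec, "dyad_recording"))
  nyq <- rec$srate / 2
  if (!is.null(notch) && rec$srate <= 2 * notch)
    stop("sampling rate too low for a ", notch, " Hz notch")
  if (!is.null(lp) && lp >= nyq) stop("low-pass edge at or above Nyquist")
  filters <- list()
  if (!is.null(hp)) filters <- c(filters, list(
    signal::butter(order, hp / nyq, type = "high")))
  if (!is.null(lp)) filters <- c(filters, list(
    signal::butter(order, lp / nyq, type = "low")))
  if (!is.null(notch)) filters <- c(filters, list(
    signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")))
  for (flt in filters) {
    rec$mother <- zero_phase(flt, rec$mother)
    rec$infant <- zero_phase(flt, rec$infant)
  }
  rownames(rec$mother) <- rownames(rec$infant) <- rec$channel_labels
  rec
}

#' Repair bad channels by neighbour interpolation
#'
#' Replaces each flagged channel by the mean of its immediate montage
#' neighbours (the 12-channel neighbour map is built in; a custom map can be
#' supplied for other montages). At most 10% of a member's channels may be
#' repaired; beyond that the dyad should be excluded instead.
#'
#' @param rec a [dyad_recording()].
#' @param mother_bad,infant_bad character vectors of channel labels to
#'   repair.
#' @param neighbors named list mapping each label to its neighbour labels;
#'   default [montage_neighbors()] restricted to the recording's channels.
#' @return the repaired [dyad_recording()].
#' @export
interpolate_bad_channels <- function(rec, mother_bad = character(),
                                     infant_bad = character(),
                                     neighbors = montage_neighbors()) {
  stopifnot(inherits(rec, "dyad_recording"))
  cap <- floor(0.10 * length(rec$channel_labels))
  fix_member <- function(x, bad, who) {
    if (!length(bad)) return(x)
    if (length(bad) > cap)
      stop(length(bad), " bad ", who, " channels exceed the 10% cap (",
           cap, "); exclude this dyad instead of interpolating")
    miss <- setdiff(bad, rec$channel_labels)
    if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
    for (ch in bad) {
      nb <- intersect(setdiff(neighbors[[ch]], bad), rec$channel_labels)
      if (!length(nb))
        stop("no good neighbours available to interpolate ", ch)
      x[ch, ] <- colMeans(x[nb, , drop = FALSE])
    }
    x
  }
  rec$mother <- fix_member(rec$mother, mother_bad, "mother")
  rec$infant <- fix_member(rec$infant, infant_bad, "infant")
  rec
}

#' Restrict a recording to the canonical 12-channel analysis montage
#'
#' Both members are reduced to F3, F4, F7, F8, C3, C4, T7, T8, P3, P4, P7,
#' P8 — in that fixed order — regardless of the input channel count or
#' ordering.
#'
#' @param rec a [dyad_recording()].
#' @param channels target labels (default [analysis_channels()]).
#' @return the reduced [dyad_recording()].
#' @export
select_channels <- function(rec, channels = analysis_channels()) {
  stopifnot(inherits(rec, "dyad_recording"))
  miss <- setdiff(channels, rec$channel_labels)
  if (length(miss))
    stop("recording is missing analysis channel(s): ",
         paste(miss, collapse = ", "))
  idx <- match(channels, rec$channel_labels)
  rec$mother <- rec$mother[idx, , drop = FALSE]
  rec$infant <- rec$infant[idx, , drop = FALSE]
  rec$channel_labels <- channels
  rec
}

#' Segment a dual recording into overlapping hyper-epochs
#'
#' Cuts each annotated condition block into fixed-length segments (default
#' 2 s with 50% overlap, i.e. one epoch start every second). A hyper-epoch is
#' the time-locked pair of mother and infant segments for the same interval.
#' Epoch start times are half-open `[start, start + epoch_s)` from block
#' onset; a partial trailing window is discarded. At the defaults a 120-s
#' block yields 119 epochs of 1024 samples at 512 Hz — at least three cycles
#' of the lowest analysis frequency (3 Hz).
#'
#' @param rec a [dyad_recording()] with condition annotations.
#' @param epoch_s epoch length in seconds (default 2).
#' @param overlap fractional overlap of consecutive epochs in `[0, 1)`
#'   (default 0.5).
#' @return An object of class `hyper_epochs`: the recording plus an epoch
#'   table (`info`) with columns `condition`, `epoch_index` (within block),
#'   `start_s` (from recording start) and `start_sample`.
#' @export
make_hyper_epochs <- function(rec, epoch_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "dyad_recording"), epoch_s > 0,
            overlap >= 0, overlap < 1)
  if (is.null(rec$annotations)) stop("recording carries no annotations")
  if (any(rec$annotations$duration < epoch_s))
    stop("every annotation block must be at least one epoch long")
  n_samp <- round(epoch_s * rec$srate)
  step <- round(epoch_s * (1 - overlap) * rec$srate)
  if (step < 1) stop("overlap too close to 1 for this sampling rate")
  info <- do.call(rbind, lapply(seq_len(nrow(rec$annotations)), function(i) {
    a <- rec$annotations[i, ]
    block_start <- round(a$onset * rec$srate)
    block_len <- round(a$duration * rec$srate)
    n_ep <- (block_len - n_samp) %/% step + 1L
    starts <- block_start + (seq_len(n_ep) - 1L) * step
    data.frame(condition = a$condition, epoch_index = seq_len(n_ep),
               start_s = starts / rec$srate, start_sample = starts + 1L)
  }))
  structure(list(recording = rec, info = info, n_samples = n_samp,
                 epoch_s = epoch_s, overlap = overlap),
            class = "hyper_epochs")
}

#' @export
print.hyper_epochs <- function(x, ...) {
  cat("<hyper_epochs> ", nrow(x$info), " epochs of ", x$n_samples,
      " samples (", x$epoch_s, " s, ", x$overlap * 100, "% overlap), dyad ",
      x$recording$dyad_id, "\n", sep = "")
  print(table(x$info$condition))
  invisible(x)
}

# Extract the (mother, infant) signal pair for epoch row i of the table.
epoch_signals <- function(epochs, i) {
  idx <- epochs$info$start_sample[i] + 0:(epochs$n_samples - 1L)
  list(mother = epochs$recording$mother[, idx, drop = FALSE],
       infant = epochs$recording$infant[, idx, drop = FALSE])
}

#' Reject hyper-epochs by peak-to-peak amplitude
#'
#' An epoch is dropped when either member exceeds its peak-to-peak threshold
#' on any channel. The thresholds default to 100 microvolts for the mother
#' and 200 for the infant (infant EEG is allowed a larger excursion); the
#' study's own rejection criteria are not public, so amplitude screening is a
#' configurable stand-in, not a reconstruction.
#'
#' @param epochs a `hyper_epochs` object.
#' @param mother_pp,infant_pp peak-to-peak thresholds in microvolts
#'   (`Inf` disables screening for that member).
#' @return the `hyper_epochs` object with rejected epochs removed; the
#'   per-condition retention table is attached as attribute `"retention"`.
#' @export
reject_artifacts <- function(epochs, mother_pp = 100, infant_pp = 200) {
  stopifnot(inherits(epochs, "hyper_epochs"), mother_pp > 0, infant_pp > 0)
  keep <- vapply(seq_len(nrow(epochs$info)), function(i) {
    s <- epoch_signals(epochs, i)
    ppm <- apply(s$mother, 1, function(v) diff(range(v)))
    ppi <- apply(s$infant, 1, function(v) diff(range(v)))
    all(ppm <= mother_pp) && all(ppi <= infant_pp)
  }, logical(1))
  total <- table(epochs$info$condition)
  kept <- table(epochs$info$condition[keep])
  retention <- data.frame(condition = names(total),
                          n_total = as.integer(total),
                          n_retained = as.integer(kept[names(total)]))
  retention$n_retained[is.na(retention$n_retained)] <- 0L
  retention$fraction <- retention$n_retained / retention$n_total
  epochs$info <- epochs$info[keep, , drop = FALSE]
  rownames(epochs$info) <- NULL
  attr(epochs, "retention") <- retention
  epochs
}

#' Write an epoch manifest
#'
#' @param epochs a `hyper_epochs` object (typically after
#'   [reject_artifacts()]).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_epoch_manifest <- function(epochs, path) {
  df <- data.frame(dyad_id = epochs$recording$dyad_id, epochs$info)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
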
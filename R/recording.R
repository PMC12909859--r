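#' Time-locked dual (mother + infant) EEG recording
#'
#' Container for one dyad's synchronized two-person EEG: one channels x
#' samples matrix per member in microvolts, a shared sampling rate, condition
#' annotations and dyad metadata. Both members must be time-locked: equal
#' sample counts at the same rate. Annotation intervals must be
#' non-overlapping and lie within the recording.
#'
#' @param mother,infant numeric channels x samples matrices (microvolts).
#' @param srate sampling rate in Hz.
#' @param channel_labels electrode labels (10-20 names), one per row of each
#'   member's matrix; both members share the montage.
#' @param annotations data.frame with columns `onset` (s), `duration` (s),
#'   `condition`.
#' @param dyad_id character identifier.
#' @param infant_age infant age in months.
#' @param infant_sex `"F"` or `"M"`.
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(mother, infant, srate, channel_labels,
                           annotations = NULL, dyad_id = "dyad001",
                           infant_age = NA_real_, infant_sex = NA_character_) {
  mother <- as.matrix(mother); infant <- as.matrix(infant)
  if (ncol(mother) != ncol(infant))
    stop("time-locking broken: mother has ", ncol(mother),
         " samples but infant has ", ncol(infant))
  if (nrow(mother) != length(channel_labels) ||
      nrow(infant) != length(channel_labels))
    stop("channel_labels length must match the number of rows of both members")
  rownames(mother) <- rownames(infant) <- channel_labels
  dur <- ncol(mother) / srate
  if (!is.null(annotations)) {
    if (!all(c("onset", "duration", "condition") %in% names(annotations)))
      stop("annotations need columns onset, duration, condition")
    ann <- annotations[order(annotations$onset), , drop = FALSE]
    ends <- ann$onset + ann$duration
    if (any(ann$onset < 0) || any(ends > dur + 1e-9))
      stop("annotation intervals must lie within the recording")
    if (nrow(ann) > 1 && any(ann$onset[-1] < ends[-nrow(ann)] - 1e-9))
      stop("annotation intervals must not overlap")
  }
  structure(list(mother = mother, infant = infant, srate = srate,
                 channel_labels = channel_labels, annotations = annotations,
                 dyad_id = dyad_id, infant_age = infant_age,
                 infant_sex = infant_sex),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat("<dyad_recording> ", x$dyad_id, "\n",
      "  ", length(x$channel_labels), " channels x ", ncol(x$mother),
      " samples per member @ ", x$srate, " Hz (",
      round(ncol(x$mother) / x$srate, 1), " s)\n", sep = "")
  if (!is.null(x$annotations))
    cat("  conditions:", paste(x$annotations$condition, collapse = ", "), "\n")
  cat("  infant: age ", x$infant_age, " months, sex ", x$infant_sex, "\n",
      sep = "")
  invisible(x)
}

#' @export
format.dyad_recording <- function(x, ...) {
  paste0("<dyad_recording ", x$dyad_id, ": ", length(x$channel_labels), "ch x ",
         ncol(x$mother), " @ ", x$srate, "Hz>")
}
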
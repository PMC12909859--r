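# Minimal continuous EDF (16-bit) / BDF (24-bit) writing and reading for
# time-locked dual recordings.  Both members are stored in one file, mother
# channels first, labels prefixed "M:" / "I:".  Condition annotations and
# dyad metadata travel in a JSON sidecar next to the file (EDF+ annotation
# channels are out of scope).

std_1020_labels <- function() {
  c("Fp1", "Fp2", "Fpz", "AF3", "AF4", "AFz", "F3", "F4", "F7", "F8", "Fz",
    "F9", "F10", "FC1", "FC2", "FC5", "FC6", "FCz", "FT7", "FT8", "C3", "C4",
    "Cz", "T7", "T8", "T9", "T10", "CP1", "CP2", "CP5", "CP6", "CPz", "TP7",
    "TP8", "P3", "P4", "P7", "P8", "Pz", "P9", "P10", "PO3", "PO4", "POz",
    "O1", "O2", "Oz", "A1", "A2", "M1", "M2")
}

fmt_ascii <- function(x, width) {
  s <- as.character(x)
  long <- nchar(s) > width
  if (any(long)) {
    for (i in which(long)) {
      d <- width
      repeat {
        s[i] <- formatC(as.numeric(x[i]), digits = d, format = "g")
        if (nchar(s[i]) <= width || d <= 1) break
        d <- d - 1
      }
      if (nchar(s[i]) > width) stop("value does not fit header field: ", x[i])
    }
  }
  formatC(s, width = -width)  # left-justified, blank padded
}

#' Write a dyad recording
#'
#' `format = "edf"` / `"bdf"` write one continuous European Data Format
#' (16-bit) or BioSemi Data Format (24-bit) file holding both members
#' (mother channels first, labels prefixed `M:`/`I:`), plus a JSON sidecar
#' (`<path>.json`) with annotations and dyad metadata. `format = "csv"`
#' writes the packaged numeric layout: a directory with `mother.csv` and
#' `infant.csv` (one column per channel), `annotations.csv` and `meta.json`,
#' together with the ground-truth-friendly plain-text guarantees of CSV.
#'
#' @param rec a [dyad_recording()].
#' @param path output file (edf/bdf) or directory (csv).
#' @param format one of `"edf"`, `"bdf"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "bdf", "csv")) {
  format <- match.arg(format)
  if (format == "csv") return(write_recording_csv(rec, path))
  n <- ncol(rec$mother)
  srate <- rec$srate
  if (abs(srate - round(srate)) < 1e-9 && n %% round(srate) == 0) {
    spr <- as.integer(round(srate)); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / srate
  }
  labels <- c(paste0("M:", rec$channel_labels),
              paste0("I:", rec$channel_labels))
  x <- rbind(rec$mother, rec$infant)
  ns <- nrow(x)
  dig_max <- if (format == "edf") 32767 else 8388607
  pm <- pmax(apply(abs(x), 1, max), 1e-6) * 1.0001
  # scale with the values as printed in the header fields, so the reader
  # reconstructs with exactly the stored gain; width 7 leaves room for the
  # minus sign so the stored range stays symmetric
  pm <- as.numeric(fmt_ascii(pm, 7))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  put <- function(v, w) writeChar(paste(fmt_ascii(v, w), collapse = ""),
                                  con, eos = NULL)
  if (format == "bdf") {
    writeBin(as.raw(255L), con)
    put("BIOSEMI", 7)
  } else {
    put("0", 8)
  }
  put(rec$dyad_id, 80)                       # patient id
  put("dyadsync dual recording", 80)         # recording id
  put("01.01.26", 8); put("00.00.00", 8)
  put(hdr_bytes, 8)
  put(if (format == "bdf") "24BIT" else "", 44)
  put(n_rec, 8); put(rec_dur, 8); put(ns, 4)
  put(labels, 16)
  put(rep("", ns), 80)                       # transducer
  put(rep("uV", ns), 8)
  put(-pm, 8); put(pm, 8)
  put(rep(-dig_max, ns), 8); put(rep(dig_max, ns), 8)
  put(rep("", ns), 80)                       # prefiltering
  put(rep(spr, ns), 8)
  put(rep("", ns), 32)

  scale <- dig_max / pm
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round(x[, idx, drop = FALSE] * scale)  # ns x spr
    v <- as.integer(t(dig))                       # channel-major blocks
    if (format == "edf") {
      writeBin(v, con, size = 2, endian = "little")
    } else {
      vv <- ifelse(v < 0, v + 16777216, v)
      b <- rbind(vv %% 256, (vv %/% 256) %% 256, vv %/% 65536)
      writeBin(as.raw(b), con)
    }
  }
  sidecar <- list(dyad_id = rec$dyad_id, infant_age = rec$infant_age,
                  infant_sex = rec$infant_sex, srate = rec$srate,
                  annotations = rec$annotations)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

write_recording_csv <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    df <- as.data.frame(t(m))
    names(df) <- rec$channel_labels
    write.csv(df, file.path(path, f), row.names = FALSE)
  }
  wr(rec$mother, "mother.csv")
  wr(rec$infant, "infant.csv")
  write.csv(rec$annotations, file.path(path, "annotations.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(dyad_id = rec$dyad_id, srate = rec$srate,
                            infant_age = rec$infant_age,
                            infant_sex = rec$infant_sex),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dyad recording
#'
#' Reads EDF/BDF files written by [write_recording()] (or any continuous
#' single-rate EDF/BDF whose channel labels carry the `M:`/`I:` member
#' prefixes), or the packaged CSV directory layout. Errors if the two
#' members' sample counts differ (time-locking broken); warns about channel
#' labels not found in the standard 10-20 montage.
#'
#' @param path file or directory produced by [write_recording()].
#' @param format `"auto"` (by extension), `"edf"`, `"bdf"` or `"csv"`.
#' @return a [dyad_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "bdf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv"
              else tolower(tools::file_ext(path))
    if (!format %in% c("edf", "bdf", "csv"))
      stop("cannot infer format from path: ", path)
  }
  if (format == "csv") return(read_recording_csv(path))
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  readChar(con, 7)                           # rest of version field
  is_bdf <- first == as.raw(255L)
  if (format == "bdf" && !is_bdf) stop("not a BDF file: ", path)
  patient <- trimws(readChar(con, 80)); readChar(con, 80)
  readChar(con, 16)                          # date + time
  readChar(con, 8)                           # header bytes
  readChar(con, 44)
  n_rec <- as.integer(readChar(con, 8))
  rec_dur <- as.numeric(readChar(con, 8))
  ns <- as.integer(readChar(con, 4))
  rd <- function(w) trimws(substring(readChar(con, w * ns),
                                     (seq_len(ns) - 1) * w + 1, seq_len(ns) * w))
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  spr1 <- spr[1]
  srate <- spr1 / rec_dur
  x <- matrix(0, ns, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    if (is_bdf) {
      b <- as.integer(readBin(con, "raw", 3 * ns * spr1))
      vv <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
        65536 * b[c(FALSE, FALSE, TRUE)]
      v <- ifelse(vv >= 8388608, vv - 16777216, vv)
    } else {
      v <- readBin(con, "integer", ns * spr1, size = 2, endian = "little")
    }
    x[, ((r - 1) * spr1 + 1):(r * spr1)] <-
      matrix(v, nrow = spr1)[, seq_len(ns)] |> t()
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- x * gain + (pmin_ - dmin * gain)

  m_sel <- grepl("^M:", labels); i_sel <- grepl("^I:", labels)
  if (!any(m_sel) || !any(i_sel))
    stop("file does not carry M:/I: member-prefixed channel labels")
  ch_m <- sub("^M:", "", labels[m_sel]); ch_i <- sub("^I:", "", labels[i_sel])
  if (!identical(ch_m, ch_i))
    stop("mother and infant channel sets differ")
  validate_montage_labels(ch_m)

  sidecar <- paste0(path, ".json")
  ann <- NULL; meta <- list(dyad_id = patient, infant_age = NA_real_,
                            infant_sex = NA_character_)
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ann <- sc$annotations
    meta <- sc
  }
  dyad_recording(mother = x[m_sel, , drop = FALSE],
                 infant = x[i_sel, , drop = FALSE],
                 srate = srate, channel_labels = ch_m, annotations = ann,
                 dyad_id = meta$dyad_id, infant_age = meta$infant_age,
                 infant_sex = meta$infant_sex)
}

read_recording_csv <- function(path) {
  m <- read.csv(file.path(path, "mother.csv"), check.names = FALSE)
  i <- read.csv(file.path(path, "infant.csv"), check.names = FALSE)
  if (nrow(m) != nrow(i))
    stop("time-locking broken: mother has ", nrow(m),
         " samples but infant has ", nrow(i))
  if (!identical(names(m), names(i)))
    stop("mother and infant channel sets differ")
  validate_montage_labels(names(m))
  ann_f <- file.path(path, "annotations.csv")
  ann <- if (file.exists(ann_f)) read.csv(ann_f) else NULL
  if (!is.null(ann) && nrow(ann) == 0) ann <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dyad_recording(mother = t(as.matrix(m)), infant = t(as.matrix(i)),
                 srate = meta$srate, channel_labels = names(m),
                 annotations = ann, dyad_id = meta$dyad_id,
                 infant_age = meta$infant_age, infant_sex = meta$infant_sex)
}

validate_montage_labels <- function(labels) {
  if (anyDuplicated(labels))
    stop("duplicated channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  unknown <- setdiff(labels, std_1020_labels())
  if (length(unknown))
    warning("channel labels not in the standard 10-20 montage: ",
            paste(unknown, collapse = ", "))
  invisible(labels)
}
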
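# Recording I/O: delimited text (time_s,O1_uV,O2_uV) and a minimal
# two-channel EDF writer/reader (16-bit, one-second data records).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"delimited"` (CSV with header `time_s,O1_uV,O2_uV`,
#'   full-precision samples) or `"edf"` (European Data Format, 16-bit;
#'   physical dimension uV, symmetric physical range spanning the data).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "delimited") {
    n <- ncol(rec$samples)
    tt <- seq(0, n - 1) / rec$fs
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time_s,O1_uV,O2_uV", con)
    writeLines(sprintf("%.10g,%.17g,%.17g", tt, rec$samples[1, ], rec$samples[2, ]), con)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  n <- ncol(rec$samples)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate", call. = FALSE)
  n_rec <- n %/% fs
  if (n_rec * fs != n) stop("EDF export requires a whole number of seconds", call. = FALSE)
  ns <- 2L
  pmax_ <- max(abs(rec$samples), 1e-6)
  # symmetric physical range, printed to <= 7 ASCII chars (sign needs the
  # 8th); reparse the printed value so scaling is computed from what the
  # header actually stores
  digits <- 6
  repeat {
    pm_str <- sprintf("%.*g", digits, pmax_ * 1.0001)
    if (nchar(pm_str) <= 7 || digits == 1) break
    digits <- digits - 1
  }
  pm <- as.numeric(pm_str)
  dig_min <- -32768; dig_max <- 32767
  scale <- (2 * pm) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("X X X ", rec$subject_id), 80),
    edf_pad(paste0("Startdate X X X X group=", rec$group), 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    edf_pad("O1", 16), edf_pad("O2", 16),
    edf_pad("dry electrode", 80), edf_pad("dry electrode", 80),
    edf_pad("uV", 8), edf_pad("uV", 8),
    edf_pad(paste0("-", pm_str), 8), edf_pad(paste0("-", pm_str), 8),
    edf_pad(pm_str, 8), edf_pad(pm_str, 8),
    edf_pad(dig_min, 8), edf_pad(dig_min, 8),
    edf_pad(dig_max, 8), edf_pad(dig_max, 8),
    edf_pad("HP:0.5Hz LP:60Hz", 80), edf_pad("HP:0.5Hz LP:60Hz", 80),
    edf_pad(fs, 8), edf_pad(fs, 8),
    edf_pad("", 32), edf_pad("", 32)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  dig <- round((rec$samples + pm) / scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[1, idx]), con, size = 2, endian = "little")
    writeBin(as.integer(dig[2, idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Dispatches on file extension: `.edf` is parsed as EDF (the file must
#' contain exactly the two-channel O1/O2 occipital montage), anything else
#' as delimited text with header `time_s,O1_uV,O2_uV`.
#'
#' @param path Input file path.
#' @return An `eeg_recording` with `provenance` set to the file path.
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "O1_uV", "O2_uV")
  if (!identical(names(df), need)) {
    stop(sprintf("delimited recording must have columns %s (got: %s)",
                 paste(need, collapse = ","), paste(names(df), collapse = ",")),
         call. = FALSE)
  }
  dt <- diff(df$time_s)
  fs <- round(1 / stats::median(dt))
  samples <- rbind(O1 = df$O1_uV, O2 = df$O2_uV)
  id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(subject_id = id, group = "unknown", fs = fs,
                 duration = nrow(df) / fs, channels = c("O1", "O2"),
                 samples = samples, provenance = path),
            class = "eeg_recording")
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient <- rd(80); recording_field <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 2L) {
    stop(sprintf("expected the 2-channel O1/O2 occipital montage, found %d signals", ns),
         call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (spr[1] != spr[2]) stop("channels must share one sampling rate", call. = FALSE)
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2, endian = "little")
  m <- matrix(raw, nrow = sum(spr)) # one column per data record
  o1 <- as.vector(m[seq_len(spr[1]), ])
  o2 <- as.vector(m[spr[1] + seq_len(spr[2]), ])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- rbind(O1 = pmin_[1] + (o1 - dmin[1]) * scale[1],
                   O2 = pmin_[2] + (o2 - dmin[2]) * scale[2])
  id <- sub("^X X X ", "", patient)
  group <- if (grepl("group=", recording_field)) sub(".*group=(\\S+).*", "\\1", recording_field) else "unknown"
  structure(list(subject_id = id, group = group, fs = fs,
                 duration = n_rec * rec_dur, channels = labels,
                 samples = samples, provenance = path),
            class = "eeg_recording")
}

#' Quantization step of an EDF file's stored samples
#'
#' @param path EDF file.
#' @return Physical value (uV) of one digital unit per channel.
#' @export
edf_quantization_step <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44); rd(8); rd(8)
  ns <- as.integer(rd(4))
  for (i in seq_len(ns)) rd(16)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  (pmax_ - pmin_) / (dmax - dmin)
}
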
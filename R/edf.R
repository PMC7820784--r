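# Minimal European Data Format (EDF) writer: 16-bit little-endian samples,
# one data record per second (last record padded with the final sample).

pad <- function(x, width) formatC(as.character(x), width = width,
                                  flag = "-")

#' Write signals to an EDF file
#'
#' Standard EDF: an ASCII header (256 bytes plus 256 per signal) followed by
#' 16-bit little-endian data records of one second each. Each channel's
#' physical range is its data range, widened by +/-1 mV when the signal is
#' constant (EDF forbids a zero range); digital range is -32768..32767. If
#' the signal length is not a whole number of records the last record is
#' padded by repeating the final sample (the true sample count is
#' recoverable from `n_samples` here, and the padding is constant).
#'
#' @param signals numeric matrix, one row per channel.
#' @param dt sample interval, ms.
#' @param labels channel labels (length `nrow(signals)`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, dt, labels, path) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  ns <- nrow(signals)
  stopifnot(length(labels) == ns, dt > 0)
  fs <- round(1000 / dt)
  n_samp <- ncol(signals)
  n_rec <- ceiling(n_samp / fs)

  phys_min <- apply(signals, 1, min)
  phys_max <- apply(signals, 1, max)
  flat <- phys_max - phys_min == 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad(x, width), con, nchars = width,
                                     eos = NULL)
  now <- Sys.time()
  wr("0", 8)
  wr("X X X X", 80)                       # patient id
  wr("Startdate X X X X", 80)             # recording id
  wr(format(now, "%d.%m.%y"), 8)
  wr(format(now, "%H.%M.%S"), 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)                              # record duration, seconds
  wr(ns, 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)       # transducer
  for (i in seq_len(ns)) wr("mV", 8)
  for (i in seq_len(ns)) wr(formatC(phys_min[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(formatC(phys_max[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)       # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- matrix(0L, ns, n_rec * fs)
  for (i in seq_len(ns)) {
    x <- c(signals[i, ], rep(signals[i, n_samp], n_rec * fs - n_samp))
    dig[i, ] <- as.integer(round((x - phys_min[i]) /
                                   (phys_max[i] - phys_min[i]) * 65535 -
                                   32768))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[i, cols], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF header (and sample counts)
#'
#' Parses the fixed-layout ASCII header of an EDF file; used to verify
#' exports. Does not decode the sample data.
#'
#' @param path EDF file path.
#' @return list: `n_signals`, `n_records`, `record_duration` (s), `labels`,
#'   `sampling_rate` (Hz, per signal), `n_samples` (per signal),
#'   `phys_min`, `phys_max`.
#' @export
read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1)
    trimws(vapply(seq_len(n), function(i)
      readChar(con, width, useBytes = TRUE), character(1)))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- rd(16, ns)
  rd(80, ns); rd(8, ns)
  phys_min <- as.numeric(rd(8, ns))
  phys_max <- as.numeric(rd(8, ns))
  rd(8, ns); rd(8, ns); rd(80, ns)
  spr <- as.integer(rd(8, ns))
  list(n_signals = ns, n_records = n_rec, record_duration = rec_dur,
       labels = labels, sampling_rate = spr / rec_dur,
       n_samples = spr * n_rec, phys_min = phys_min, phys_max = phys_max)
}
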
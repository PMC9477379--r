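#' Write a continuous recording to European Data Format (EDF)
#'
#' Minimal EDF writer for continuous multi-channel recordings: one
#' fixed-duration data record per second (the trailing partial second is
#' zero-padded), 16-bit samples, physical range taken from the data per
#' channel.  Amplitudes survive the round trip to within the 16-bit
#' quantisation step of the channel's range.
#'
#' @param recording Channels x samples numeric matrix (uV) or a session
#'   list from [generate_session()].
#' @param path Output file path (conventionally `.edf`).
#' @param sampling_rate Hz (ignored for session lists); must be a whole
#'   number of samples per second.
#' @param channel_labels Labels (<= 16 ASCII chars each) when `recording`
#'   is a bare matrix without rownames.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, sampling_rate = NULL,
                      channel_labels = NULL) {
  if (is.list(recording) && !is.null(recording$recording)) {
    return(write_edf(recording$recording, path, recording$sampling_rate,
                     recording$channel_labels))
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate is required", call. = FALSE)
  if (abs(fs - round(fs)) > 1e-9) {
    stop("sampling_rate must be an integer number of Hz", call. = FALSE)
  }
  fs <- round(fs)
  labels <- channel_labels %||% rownames(recording) %||%
    paste0("ch", seq_len(nrow(recording)))
  ns <- nrow(recording)
  n_rec <- ceiling(ncol(recording) / fs)
  pad <- n_rec * fs - ncol(recording)
  if (pad > 0) recording <- cbind(recording, matrix(0, ns, pad))
  phys_min <- pmin(apply(recording, 1, min), -1)
  phys_max <- pmax(apply(recording, 1, max), 1)
  dig_min <- -32768
  dig_max <- 32767
  pad_str <- function(x, n) {
    x <- substr(as.character(x), 1, n)
    formatC(x, width = n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),                       # version
    pad_str("X X X X", 80),                # patient id (anonymous)
    pad_str("Startdate X X X X", 80),      # recording id
    pad_str("01.01.00", 8), pad_str("00.00.00", 8),
    pad_str(256 + 256 * ns, 8),            # header bytes
    pad_str("", 44),
    pad_str(n_rec, 8),
    pad_str("1", 8),                       # record duration, seconds
    pad_str(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) {
    writeChar(paste0(vapply(vals, pad_str, "", n = n), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16)
  field(rep("EEG", ns), 80)                # transducer
  field(rep("uV", ns), 8)
  field(formatC(phys_min, digits = 7, format = "g"), 8)
  field(formatC(phys_max, digits = 7, format = "g"), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                   # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)                   # reserved
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((recording[ch, sl] - phys_min[ch]) * gain[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Counterpart of [write_edf()]; reads continuous 16-bit EDF files with a
#' common sampling rate across channels.
#'
#' @param path EDF file path.
#' @return List with `recording` (channels x samples, physical units),
#'   `sampling_rate`, `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header bytes (re-derived)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns); rd(8 * ns)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1L) {
    stop("channels with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[1]) stop("truncated EDF file", call. = FALSE)
      out[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dig_min[ch]) * gain[ch] + phys_min[ch]
    }
  }
  rownames(out) <- labels
  list(recording = out, sampling_rate = fs, channel_labels = labels)
}
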
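#' Epoch container
#'
#' The central data structure of the analysis: a stimulus-locked amplitude
#' tensor (epochs x channels x time, microvolts) with its time axis in ms
#' relative to stimulus onset, channel labels, per-epoch condition labels and
#' a rejection mask.  Rejected epochs are excluded from every downstream
#' statistic.
#'
#' @param data Numeric array, epochs x channels x time, in microvolts.
#' @param time_ms Numeric time axis (ms relative to stimulus onset), length
#'   `dim(data)[3]`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, length `dim(data)[2]`.
#' @param labels Data.frame with one row per epoch: `name_id`, `is_target`,
#'   `block`, `repetition`.
#' @param rejected Logical rejection mask, one flag per epoch (default all
#'   `FALSE`).
#' @return An object of class `aerp_epochs`.
#' @export
aerp_epochs <- function(data, time_ms, sampling_rate, channel_labels,
                        labels, rejected = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(time_ms) == dim(data)[3],
            length(channel_labels) == dim(data)[2],
            nrow(labels) == dim(data)[1])
  if (is.null(rejected)) rejected <- rep(FALSE, dim(data)[1])
  stopifnot(length(rejected) == dim(data)[1])
  need <- c("name_id", "is_target", "block", "repetition")
  miss <- setdiff(need, names(labels))
  if (length(miss)) {
    stop("epoch labels are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(data = data,
                 time_ms = as.numeric(time_ms),
                 sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 labels = labels[, need],
                 rejected = as.logical(rejected)),
            class = "aerp_epochs")
}

#' @export
print.aerp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time %g..%g ms; %d target / %d non-target epochs; %d rejected\n",
              min(x$time_ms), max(x$time_ms),
              sum(x$labels$is_target), sum(!x$labels$is_target),
              sum(x$rejected)))
  invisible(x)
}

#' Number of usable (non-rejected) epochs
#' @param epochs An [aerp_epochs] object.
#' @return Integer count.
#' @export
n_surviving <- function(epochs) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  sum(!epochs$rejected)
}

#' Drop rejected epochs from the container
#' @param epochs An [aerp_epochs] object.
#' @return An [aerp_epochs] object containing only surviving epochs.
#' @export
drop_rejected <- function(epochs) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  keep <- !epochs$rejected
  aerp_epochs(epochs$data[keep, , , drop = FALSE], epochs$time_ms,
              epochs$sampling_rate, epochs$channel_labels,
              epochs$labels[keep, , drop = FALSE])
}

#' Read/write the plain-text epoch container
#'
#' The container is a pair of files sharing a path prefix:
#' `<prefix>_data.tsv`, the amplitude tensor flattened to one row per
#' (epoch, channel) with one column per time sample, and
#' `<prefix>_meta.json`, a sidecar with channel labels, sampling rate, time
#' axis and the epoch label table (event-table schema plus a `rejected`
#' column).  The round trip is lossless to the stored precision (amplitudes
#' written with 10 significant digits; labels exactly).
#'
#' @param epochs An [aerp_epochs] object.
#' @param prefix Path prefix (directory must exist).
#' @return `write_epoch_container()` returns `prefix` invisibly;
#'   `read_epoch_container()` returns an [aerp_epochs] object.
#' @export
write_epoch_container <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[1] * d[2])
  write.table(format(flat, digits = 10, trim = TRUE, scientific = TRUE),
              paste0(prefix, "_data.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(
    n_epochs = d[1], n_channels = d[2], n_times = d[3],
    sampling_rate = epochs$sampling_rate,
    time_ms = epochs$time_ms,
    channel_labels = epochs$channel_labels,
    labels = cbind(epochs$labels, rejected = epochs$rejected)
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epoch_container
#' @export
read_epoch_container <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  data_path <- paste0(prefix, "_data.tsv")
  if (!file.exists(meta_path)) {
    stop("epoch container sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("n_epochs", "n_channels", "n_times", "sampling_rate",
              "time_ms", "channel_labels", "labels")) {
    if (is.null(meta[[f]])) {
      stop("epoch container metadata is missing field '", f, "'",
           call. = FALSE)
    }
  }
  flat <- as.matrix(read.table(data_path, sep = "\t", header = FALSE))
  if (nrow(flat) != meta$n_epochs * meta$n_channels ||
      ncol(flat) != meta$n_times) {
    stop("epoch container data has dimensions ", nrow(flat), " x ",
         ncol(flat), " but metadata promises ",
         meta$n_epochs * meta$n_channels, " x ", meta$n_times, call. = FALSE)
  }
  dat <- array(flat, dim = c(meta$n_channels, meta$n_epochs, meta$n_times))
  dat <- aperm(dat, c(2, 1, 3))
  lab <- meta$labels
  lab$is_target <- as.logical(lab$is_target)
  aerp_epochs(dat, meta$time_ms, meta$sampling_rate, meta$channel_labels,
              lab[, c("name_id", "is_target", "block", "repetition")],
              rejected = as.logical(lab$rejected))
}
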
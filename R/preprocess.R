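#' Linear-phase FIR band-pass filter
#'
#' Hamming-windowed FIR band-pass (default 0.5–40 Hz) applied along time with
#' group-delay compensation, so the net shift is zero and DC is removed.
#' Filter order follows the usual window-method rule
#' `N = ceiling(3.3 * fs / transition)` (forced odd), with the transition
#' width set by the lower band edge — the narrower of the two edges — unless
#' overridden.
#'
#' @param recording Channels x samples numeric matrix (or a list with
#'   elements `recording` and `sampling_rate` as returned by
#'   [generate_session()]).
#' @param low,high Band edges in Hz; `0 < low < high < fs/2` required.
#' @param sampling_rate Sampling rate in Hz (ignored when `recording` is a
#'   session list).
#' @param transition_hz Transition bandwidth in Hz (default `low`).
#' @return Filtered object of the same shape as the input.
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 40,
                            sampling_rate = NULL, transition_hz = NULL) {
  if (is.list(recording) && !is.null(recording$recording)) {
    recording$recording <- bandpass_filter(recording$recording, low, high,
                                           recording$sampling_rate,
                                           transition_hz)
    return(recording)
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate is required", call. = FALSE)
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  if (is.null(transition_hz)) transition_hz <- low
  n_taps <- ceiling(3.3 * fs / transition_hz)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  b <- signal::fir1(n_taps - 1, c(low, high) / nyq, type = "pass")
  gd <- (n_taps - 1) / 2
  one_ch <- is.null(dim(recording))
  x <- if (one_ch) matrix(recording, nrow = 1) else recording
  n <- ncol(x)
  out <- t(apply(x, 1, function(ch) {
    y <- signal::fftfilt(b, c(ch, numeric(gd)))
    y[(gd + 1):(gd + n)]
  }))
  if (one_ch) drop(out) else {
    dimnames(out) <- dimnames(recording)
    out
  }
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies an internal anti-alias FIR low-pass (cut-off at 80% of the new
#' Nyquist) and keeps every `fs/target_rate`-th sample.  Re-expressing event
#' onsets needs no change: onsets are stored in ms and map to sample indices
#' at whatever rate the recording carries.
#'
#' @param recording Channels x samples matrix or session list.
#' @param target_rate New rate in Hz; must divide the current rate.
#' @param sampling_rate Current rate in Hz (ignored for session lists).
#' @return Decimated recording (same form as input); for session lists the
#'   `sampling_rate` element is updated.
#' @export
downsample <- function(recording, target_rate = 200, sampling_rate = NULL) {
  if (is.list(recording) && !is.null(recording$recording)) {
    recording$recording <- downsample(recording$recording, target_rate,
                                      recording$sampling_rate)
    recording$sampling_rate <- target_rate
    return(recording)
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate is required", call. = FALSE)
  if (target_rate > fs) stop("upsampling is not supported", call. = FALSE)
  if (target_rate == fs) return(recording)
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target_rate must divide the current sampling rate", call. = FALSE)
  }
  factor <- round(factor)
  nyq_new <- target_rate / 2
  cutoff <- 0.8 * nyq_new
  transition <- 0.4 * nyq_new
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  b <- signal::fir1(n_taps - 1, cutoff / (fs / 2), type = "low")
  gd <- (n_taps - 1) / 2
  one_ch <- is.null(dim(recording))
  x <- if (one_ch) matrix(recording, nrow = 1) else recording
  n <- ncol(x)
  keep <- seq(1, n, by = factor)
  out <- t(apply(x, 1, function(ch) {
    y <- signal::fftfilt(b, c(ch, numeric(gd)))
    y[(gd + 1):(gd + n)][keep]
  }))
  if (one_ch) drop(out) else {
    rownames(out) <- rownames(recording)
    out
  }
}

# Compact symmetric FastICA (tanh contrast) on whitened data.
# Returns the estimated source matrix S (components x samples) and the
# mixing matrix A with X_centered = A %*% S.
.fastica <- function(x, n_comp = nrow(x), max_iter = 200, tol = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(pos))
  K <- diag(1 / sqrt(eg$values[seq_len(n_comp)]), n_comp) %*%
    t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  z <- K %*% xc
  W <- qr.Q(qr(matrix(rnorm(n_comp^2), n_comp)))
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- tcrossprod(g, z) / ncol(z) - diag(rowMeans(gp), n_comp) %*% W
    sv <- svd(W1)
    W1 <- sv$u %*% t(sv$v)  # symmetric decorrelation
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% z
  A <- MASS_ginv_free(K) %*% t(W)   # unmix inverse: x_c = K^+ t(W) S
  list(S = S, A = A, mean = mu)
}

# Moore-Penrose pseudoinverse via SVD (kept local; MASS not imported).
MASS_ginv_free <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Remove ocular/motion artifact components (optional stage)
#'
#' Decomposes the recording with FastICA and zeroes every independent
#' component whose absolute correlation with any designated EOG-proxy
#' channel exceeds `threshold`, then re-projects the mixture.  With no
#' component above threshold the output equals the input up to numerical
#' tolerance.  The stage replaces a manual ICA inspection with a
#' reproducible automated rule and is off by default in the pipeline.
#'
#' @param recording Channels x samples matrix or session list.
#' @param eog_proxy_channels Character labels of frontal channels standing in
#'   for EOG (e.g. `c("Fp1", "Fp2")`).
#' @param threshold Absolute-correlation threshold in (0, 1]; default 0.8.
#' @param seed Seed for the ICA initialisation (deterministic output).
#' @param channel_labels Channel labels when `recording` is a bare matrix
#'   without rownames.
#' @return Cleaned recording of the same shape; attribute
#'   `"removed_components"` carries the number zeroed.
#' @export
remove_artifact_components <- function(recording, eog_proxy_channels,
                                       threshold = 0.8, seed = 1,
                                       channel_labels = NULL) {
  if (is.list(recording) && !is.null(recording$recording)) {
    recording$recording <- remove_artifact_components(
      recording$recording, eog_proxy_channels, threshold, seed,
      recording$channel_labels)
    return(recording)
  }
  labels <- channel_labels
  if (is.null(labels)) labels <- rownames(recording)
  if (is.null(labels)) stop("channel labels are required", call. = FALSE)
  if (nrow(recording) < 2) stop("at least 2 channels required", call. = FALSE)
  miss <- setdiff(eog_proxy_channels, labels)
  if (length(miss)) {
    stop("EOG proxy channel(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  ica <- .fastica(recording)
  proxies <- recording[match(eog_proxy_channels, labels), , drop = FALSE]
  bad <- apply(ica$S, 1, function(s) {
    max(abs(cor(s, t(proxies))))
  }) > threshold
  n_bad <- sum(bad)
  if (n_bad == 0) {
    out <- recording
  } else {
    S <- ica$S
    S[bad, ] <- 0
    out <- ica$A %*% S + ica$mean
    dimnames(out) <- dimnames(recording)
  }
  attr(out, "removed_components") <- n_bad
  out
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event, spanning the half-open window
#' `[t_min_ms, t_max_ms)` relative to onset (default \[-200, 800) ms, i.e.
#' exactly 200 samples at 200 Hz).  Events whose window does not fit inside
#' the recording are dropped with a warning.
#'
#' @param recording Channels x samples matrix or session list.
#' @param events Event data.frame ([generate_sequence()] schema); ignored
#'   when `recording` is a session list carrying its own events.
#' @param t_min_ms,t_max_ms Epoch window in ms relative to onset.
#' @param sampling_rate Rate in Hz (ignored for session lists).
#' @param channel_labels Labels when `recording` is a bare matrix.
#' @return An [aerp_epochs] object.
#' @export
epoch_data <- function(recording, events = NULL, t_min_ms = -200,
                       t_max_ms = 800, sampling_rate = NULL,
                       channel_labels = NULL) {
  if (is.list(recording) && !is.null(recording$recording)) {
    return(epoch_data(recording$recording,
                      events %||% recording$events,
                      t_min_ms, t_max_ms,
                      recording$sampling_rate,
                      recording$channel_labels))
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate is required", call. = FALSE)
  if (is.null(events)) stop("events are required", call. = FALSE)
  labels <- channel_labels %||% rownames(recording) %||%
    paste0("ch", seq_len(nrow(recording)))
  n_t <- round((t_max_ms - t_min_ms) * fs / 1000)
  time_ms <- t_min_ms + (seq_len(n_t) - 1) / fs * 1000
  onset_idx <- round(events$onset_ms * fs / 1000) + 1L
  start_idx <- onset_idx + round(t_min_ms * fs / 1000)
  ok <- start_idx >= 1L & (start_idx + n_t - 1L) <= ncol(recording)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge were dropped")
  }
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(recording), n_t))
  for (i in seq_along(keep)) {
    sl <- start_idx[keep[i]] + 0:(n_t - 1L)
    dat[i, , ] <- recording[, sl]
  }
  aerp_epochs(dat, time_ms = time_ms, sampling_rate = fs,
              channel_labels = labels,
              labels = events[keep, c("name_id", "is_target", "block",
                                      "repetition")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean amplitude over the pre-stimulus
#' window `[b_min_ms, b_max_ms)` (default \[-200, 0) ms).
#'
#' @param epochs An [aerp_epochs] object.
#' @param b_min_ms,b_max_ms Baseline window in ms.
#' @return The corrected [aerp_epochs] object.
#' @export
baseline_correct <- function(epochs, b_min_ms = -200, b_max_ms = 0) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  sel <- epochs$time_ms >= b_min_ms & epochs$time_ms < b_max_ms
  if (!any(sel)) {
    stop("baseline window [", b_min_ms, ", ", b_max_ms,
         ") ms contains no samples of the epoch time axis", call. = FALSE)
  }
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (3rd dim)
  epochs
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' Flags every epoch containing any sample with `|amplitude| > threshold`
#' on any channel.  Flags accumulate (previously rejected epochs stay
#' rejected).
#'
#' @param epochs An [aerp_epochs] object.
#' @param threshold_uV Rejection threshold in microvolts (> 0; default 100).
#' @return The [aerp_epochs] object with an updated `rejected` mask.
#' @export
reject_amplitude <- function(epochs, threshold_uV = 100) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  if (threshold_uV <= 0) stop("threshold must be positive", call. = FALSE)
  peak <- apply(abs(epochs$data), 1, max)
  epochs$rejected <- epochs$rejected | (peak > threshold_uV)
  epochs
}

#' Full preprocessing chain
#'
#' Fixed stage order: band-pass filter, decimation, optional ICA
#' artifact removal, epoching, baseline correction, amplitude rejection.
#'
#' @param session Session list from [generate_session()] (or a compatible
#'   list with `recording`, `events`, `sampling_rate`, `channel_labels`).
#' @param low,high Filter band edges in Hz.
#' @param target_rate Decimation target in Hz.
#' @param eog_proxy_channels If non-`NULL`, run
#'   [remove_artifact_components()] with these proxies.
#' @param ica_threshold Correlation threshold for component removal.
#' @param t_min_ms,t_max_ms Epoch window.
#' @param baseline_ms Length-2 baseline window in ms.
#' @param reject_uV Amplitude rejection threshold in microvolts.
#' @param seed Seed for the (optional) ICA stage.
#' @return An [aerp_epochs] object.
#' @export
preprocess <- function(session, low = 0.5, high = 40, target_rate = 200,
                       eog_proxy_channels = NULL, ica_threshold = 0.8,
                       t_min_ms = -200, t_max_ms = 800,
                       baseline_ms = c(-200, 0), reject_uV = 100,
                       seed = 1) {
  x <- bandpass_filter(session, low, high)
  x <- downsample(x, target_rate)
  if (!is.null(eog_proxy_channels)) {
    x <- remove_artifact_components(x, eog_proxy_channels, ica_threshold,
                                    seed = seed)
  }
  ep <- epoch_data(x, t_min_ms = t_min_ms, t_max_ms = t_max_ms)
  ep <- baseline_correct(ep, baseline_ms[1], baseline_ms[2])
  reject_amplitude(ep, reject_uV)
}
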
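#' ERP component specification
#'
#' A simulated ERP component is a Gaussian temporal envelope (peak latency,
#' envelope SD) projected onto the scalp through a per-channel topography and
#' scaled by a trial-level amplitude drawn from
#' `Normal(amplitude_mean, amplitude_sd)`.  Peak latency is jittered per
#' trial with SD `latency_jitter_sd`.  Negative components (N2) carry a
#' negative `amplitude_mean`.
#'
#' @param label Component name, e.g. `"P300"`, `"P200"`, `"N2"`.
#' @param peak_latency_ms Mean peak latency in ms after stimulus onset.
#' @param width_ms Gaussian envelope SD in ms (> 0).
#' @param amplitude_mean Mean peak amplitude in microvolts (signed).
#' @param amplitude_sd Trial-to-trial amplitude SD in microvolts.
#' @param latency_jitter_sd Trial-to-trial latency SD in ms.
#' @param topography Named per-channel weight vector in `[-1, 1]`; length
#'   must match the generator's channel count.
#' @param applies_to `"target"` or `"nontarget"` epochs.
#' @return An object of class `aerp_component`.
#' @export
component_spec <- function(label, peak_latency_ms, width_ms,
                           amplitude_mean, amplitude_sd = 0,
                           latency_jitter_sd = 0,
                           topography, applies_to = c("target", "nontarget")) {
  applies_to <- match.arg(applies_to)
  stopifnot(width_ms > 0, amplitude_sd >= 0, latency_jitter_sd >= 0,
            is.numeric(topography), all(abs(topography) <= 1))
  structure(list(label = label,
                 peak_latency_ms = peak_latency_ms,
                 width_ms = width_ms,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 latency_jitter_sd = latency_jitter_sd,
                 topography = topography,
                 applies_to = applies_to),
            class = "aerp_component")
}

# Per-condition component defaults.  Target P300 amplitudes are the four
# reported condition means (3.02 / 5.40 / 1.87 / 4.43 uV); latencies and the
# non-target P200 parameters are condition-wise means of the Pz (targets) and
# Fz (non-targets) measurement table.  The target N2 is a modest
# fronto-central negativity in 200-300 ms; its size is a documented
# assumption.
.condition_defaults <- function(mode, nontarget_type) {
  key <- paste(mode, nontarget_type, sep = "-")
  p300 <- switch(key,
    "passive-3CC" = list(amp = 3.02, lat = 507.5),
    "active-3CC"  = list(amp = 5.40, lat = 465.0),
    "passive-2CC" = list(amp = 1.87, lat = 422.5),
    "active-2CC"  = list(amp = 4.43, lat = 487.5),
    stop("unknown condition ", key, call. = FALSE))
  p200 <- switch(key,
    "passive-3CC" = list(amp = 3.33, lat = 225.0),
    "active-3CC"  = list(amp = 4.00, lat = 222.5),
    "passive-2CC" = list(amp = 2.04, lat = 242.5),
    "active-2CC"  = list(amp = 1.78, lat = 265.0))
  list(p300 = p300, p200 = p200, n2 = list(amp = -2.0, lat = 250))
}

#' Default condition-dependent component set
#'
#' Builds the three standard components for one experimental condition:
#' a parietal (Pz-focused) P300 on targets, a fronto-central N2 negativity on
#' targets, and a frontal (Fz-focused) P200 on non-targets.  Per-condition
#' P300 amplitudes default to the four reported condition means
#' (passive-3CC 3.02, active-3CC 5.40, passive-2CC 1.87, active-2CC 4.43
#' microvolts).
#'
#' @param mode `"active"` or `"passive"`.
#' @param nontarget_type `"3CC"` or `"2CC"`.
#' @param p300_amplitude Optional override of the target P300 mean amplitude
#'   (microvolts), e.g. a per-subject draw.
#' @param p200_amplitude Optional override of the non-target P200 mean
#'   amplitude.
#' @param montage Montage used for topographies.
#' @return List of `aerp_component` objects.
#' @export
condition_components <- function(mode = c("active", "passive"),
                                 nontarget_type = c("3CC", "2CC"),
                                 p300_amplitude = NULL,
                                 p200_amplitude = NULL,
                                 montage = aerp_montage()) {
  mode <- match.arg(mode)
  nontarget_type <- match.arg(nontarget_type)
  d <- .condition_defaults(mode, nontarget_type)
  if (is.null(p300_amplitude)) p300_amplitude <- d$p300$amp
  if (is.null(p200_amplitude)) p200_amplitude <- d$p200$amp
  list(
    component_spec("P300", d$p300$lat, width_ms = 60,
                   amplitude_mean = p300_amplitude, amplitude_sd = 2.0,
                   latency_jitter_sd = 25,
                   topography = topography_gaussian("Pz", 0.6, montage),
                   applies_to = "target"),
    component_spec("N2", d$n2$lat, width_ms = 35,
                   amplitude_mean = d$n2$amp, amplitude_sd = 1.0,
                   latency_jitter_sd = 15,
                   topography = topography_gaussian("FCz", 0.5, montage),
                   applies_to = "target"),
    component_spec("P200", d$p200$lat, width_ms = 25,
                   amplitude_mean = p200_amplitude, amplitude_sd = 1.0,
                   latency_jitter_sd = 10,
                   topography = topography_gaussian("Fz", 0.5, montage),
                   applies_to = "nontarget")
  )
}

#' Synthetic EEG generator configuration
#'
#' @param channel_labels Channel names; default is the 60-channel 10-10
#'   montage of [aerp_montage()].
#' @param sampling_rate Continuous-recording rate in Hz (> 80 so the 40 Hz
#'   band edge stays below Nyquist; default 1000).
#' @param components List of [component_spec()] objects; default is built per
#'   condition by [condition_components()] at generation time when `NULL`.
#' @param noise_1f_exponent Spectral exponent alpha of the 1/f^alpha
#'   background noise (power spectral density slope).
#' @param noise_sd Background noise SD per channel in microvolts within the
#'   0.5–40 Hz analysis band.
#' @param noise_band_hz Frequency band the background noise occupies.
#' @return An object of class `aerp_genconfig`.
#' @export
generator_config <- function(channel_labels = aerp_montage()$label,
                             sampling_rate = 1000,
                             components = NULL,
                             noise_1f_exponent = 1,
                             noise_sd = 8,
                             noise_band_hz = c(0.5, 40)) {
  stopifnot(sampling_rate > 80, noise_sd >= 0,
            length(noise_band_hz) == 2L, noise_band_hz[1] < noise_band_hz[2])
  structure(list(channel_labels = channel_labels,
                 sampling_rate = sampling_rate,
                 components = components,
                 noise_1f_exponent = noise_1f_exponent,
                 noise_sd = noise_sd,
                 noise_band_hz = noise_band_hz),
            class = "aerp_genconfig")
}

# 1/f^alpha band-limited Gaussian noise, columns independent.
# Returns an n x m matrix with per-column SD ~ noise_sd (analytic spectral
# normalisation, so realisations keep natural variability).
.pink_noise <- function(n, m, fs, alpha, sd_uV, band) {
  if (sd_uV == 0) return(matrix(0, n, m))
  freqs <- (seq_len(n) - 1) / n * fs
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # mirror for neg freqs
  gain <- numeric(n)
  inband <- freqs >= band[1] & freqs <= band[2]
  gain[inband] <- freqs[inband]^(-alpha / 2)
  # normalise expected variance to sd_uV^2
  gain <- gain * sd_uV / sqrt(mean(gain^2))
  w <- matrix(rnorm(n * m), n, m)
  sp <- mvfft(w) * gain
  Re(mvfft(sp, inverse = TRUE)) / n
}

.component_envelope <- function(time_ms, latency_ms, width_ms) {
  exp(-(time_ms - latency_ms)^2 / (2 * width_ms^2))
}

.match_topography <- function(comp, channel_labels) {
  topo <- comp$topography
  if (length(topo) != length(channel_labels)) {
    stop("component '", comp$label, "' topography has length ", length(topo),
         " but the configuration has ", length(channel_labels), " channels",
         call. = FALSE)
  }
  if (!is.null(names(topo))) {
    if (!all(channel_labels %in% names(topo))) {
      stop("component '", comp$label, "' topography is missing channels",
           call. = FALSE)
    }
    topo <- topo[channel_labels]
  }
  unname(topo)
}

#' Generate a continuous synthetic oddball EEG session
#'
#' Forward model: 1/f-shaped Gaussian background noise plus, for every
#' stimulus event, the condition-appropriate ERP components (Gaussian
#' temporal envelope x scalp topography x trial amplitude, latency jittered).
#' The recording extends from 0 to the last onset + 800 ms (plus padding for
#' filter transients).
#'
#' @param design An [session_design()] object.
#' @param config An [generator_config()] object.  When `config$components` is
#'   `NULL` they default to [condition_components()] for the design's
#'   condition.
#' @param seed Integer seed; output is a deterministic function of
#'   `(design, config, seed)`.
#' @param t_start_ms Onset of the first stimulus (leaves room for filter
#'   startup transients).
#' @param tail_pad_ms Extra recording after the last epoch ends.
#' @return List with elements `recording` (channels x samples matrix, uV),
#'   `events` (event data.frame), `sampling_rate`, `channel_labels`.
#' @examples
#' d <- session_design(n_blocks = 1, n_repetitions = 2)
#' s <- generate_session(d, generator_config(sampling_rate = 250), seed = 1)
#' dim(s$recording)
#' @export
generate_session <- function(design, config = generator_config(), seed,
                             t_start_ms = 5000, tail_pad_ms = 1000) {
  stopifnot(inherits(design, "aerp_design"), inherits(config, "aerp_genconfig"))
  events <- generate_sequence(design, seed = seed, t_start_ms = t_start_ms)
  comps <- config$components
  if (is.null(comps)) {
    comps <- condition_components(design$mode, design$nontarget_type)
  }
  fs <- config$sampling_rate
  n_ch <- length(config$channel_labels)
  n_samp <- ceiling((max(events$onset_ms) + 800 + tail_pad_ms) * fs / 1000)
  # noise seeded after the sequence draw; all randomness flows from `seed`
  rec <- t(.pink_noise(n_samp, n_ch, fs, config$noise_1f_exponent,
                       config$noise_sd, config$noise_band_hz))
  t_axis_ms <- (seq_len(n_samp) - 1) / fs * 1000
  for (comp in comps) {
    topo <- .match_topography(comp, config$channel_labels)
    sel <- if (comp$applies_to == "target") events$is_target else !events$is_target
    idx <- which(sel)
    amps <- rnorm(length(idx), comp$amplitude_mean, comp$amplitude_sd)
    lats <- rnorm(length(idx), comp$peak_latency_ms, comp$latency_jitter_sd)
    half_w <- 4 * comp$width_ms
    for (j in seq_along(idx)) {
      center <- events$onset_ms[idx[j]] + lats[j]
      s0 <- max(1L, floor((center - half_w) * fs / 1000) + 1L)
      s1 <- min(n_samp, ceiling((center + half_w) * fs / 1000) + 1L)
      if (s1 < s0) next
      env <- .component_envelope(t_axis_ms[s0:s1], center, comp$width_ms)
      rec[, s0:s1] <- rec[, s0:s1] + amps[j] * tcrossprod(topo, env)
    }
  }
  rownames(rec) <- config$channel_labels
  list(recording = rec, events = events,
       sampling_rate = fs, channel_labels = config$channel_labels)
}

#' Generate epoched synthetic data directly
#'
#' Emulates the output of the preprocessing chain without simulating the
#' continuous recording: band-limited 1/f noise plus condition-appropriate
#' components, sampled on the standard epoch time axis (default
#' \[-200, 800) ms at 200 Hz).  Epochs are *not* baseline-corrected; run
#' [baseline_correct()] (and [reject_amplitude()]) as in the ordinary chain.
#' Used for simulation studies where the continuous path would only add the
#' (verified separately) filter/decimation plumbing.
#'
#' @inheritParams generate_session
#' @param sampling_rate Epoch sampling rate in Hz (default 200).
#' @param t_min_ms,t_max_ms Epoch window, half-open `[t_min, t_max)` ms.
#' @return An [aerp_epochs] object.
#' @export
generate_epochs <- function(design, config = generator_config(sampling_rate = 200),
                            seed, sampling_rate = 200,
                            t_min_ms = -200, t_max_ms = 800) {
  stopifnot(inherits(design, "aerp_design"), inherits(config, "aerp_genconfig"))
  events <- generate_sequence(design, seed = seed)
  comps <- config$components
  if (is.null(comps)) {
    comps <- condition_components(design$mode, design$nontarget_type)
  }
  fs <- sampling_rate
  n_t <- round((t_max_ms - t_min_ms) * fs / 1000)
  time_ms <- t_min_ms + (seq_len(n_t) - 1) / fs * 1000
  n_ep <- nrow(events)
  n_ch <- length(config$channel_labels)
  noise <- .pink_noise(n_t, n_ep * n_ch, fs, config$noise_1f_exponent,
                       config$noise_sd, config$noise_band_hz)
  dat <- array(t(noise), dim = c(n_ep * n_ch, n_t))
  dim(dat) <- c(n_ch, n_ep, n_t)     # filled channel-fastest
  dat <- aperm(dat, c(2, 1, 3))      # epochs x channels x time
  for (comp in comps) {
    topo <- .match_topography(comp, config$channel_labels)
    idx <- which(if (comp$applies_to == "target") events$is_target
                 else !events$is_target)
    amps <- rnorm(length(idx), comp$amplitude_mean, comp$amplitude_sd)
    lats <- rnorm(length(idx), comp$peak_latency_ms, comp$latency_jitter_sd)
    # envelope per event (rows) x time (cols), scaled by trial amplitude
    env <- amps * exp(-(outer(-lats, time_ms, `+`))^2 / (2 * comp$width_ms^2))
    add <- aperm(outer(env, topo), c(1, 3, 2))   # events x channels x time
    dat[idx, , ] <- dat[idx, , , drop = FALSE] + add
  }
  aerp_epochs(dat, time_ms = time_ms, sampling_rate = fs,
              channel_labels = config$channel_labels,
              labels = events[, c("name_id", "is_target", "block",
                                  "repetition")])
}

# Documented counter scheme for deriving child seeds from a master seed:
# child_k = (master + 1000003 * k) mod (2^31 - 1), k = 1, 2, ...
.child_seed <- function(master, k) {
  as.integer((as.numeric(master) + 1000003 * k) %% 2147483647)
}

#' Generate a simulated cohort
#'
#' One session per subject per design, with per-subject P300/P200 mean
#' amplitudes drawn from a between-subject normal distribution and
#' per-session seeds derived deterministically from the master seed by a
#' counter scheme, so any subject/session can be regenerated in isolation.
#' Between-subject SDs default to `sqrt(12) * SE` of the reported group
#' means (SE printed for n = 12): P300 SE 0.76 / 0.72 / 0.81 / 0.73 uV for
#' passive-3CC / active-3CC / passive-2CC / active-2CC.
#'
#' @param n_subjects Number of subjects (>= 1; the study cohort is 12).
#' @param designs List of [session_design()] objects (one session each).
#' @param config Base [generator_config()]; per-session components are
#'   rebuilt with subject-level amplitudes unless `config$components` is set.
#' @param seed Master integer seed.
#' @param epoched If `TRUE` (default) sessions are generated with
#'   [generate_epochs()]; otherwise full continuous recordings via
#'   [generate_session()].
#' @param fun Optional reducer applied to each session element as soon as it
#'   is generated; only its return value is kept.  Use this for large
#'   cohorts so one session at a time is held in memory.
#' @return Nested list: `sessions[[subject]][[design]]`, each element a list
#'   with `subject`, `design`, `seed` and `epochs` (or `session`), or the
#'   value of `fun` applied to that list.
#' @export
generate_cohort <- function(n_subjects = 12L,
                            designs = list(session_design()),
                            config = generator_config(sampling_rate = 200),
                            seed,
                            epoched = TRUE,
                            fun = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  p300_se <- c("passive-3CC" = 0.76, "active-3CC" = 0.72,
               "passive-2CC" = 0.81, "active-2CC" = 0.73)
  counter <- 0L
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_sessions <- vector("list", length(designs))
    for (d in seq_along(designs)) {
      des <- designs[[d]]
      counter <- counter + 1L
      s_seed <- .child_seed(seed, counter)
      cfg <- config
      if (is.null(cfg$components)) {
        key <- paste(des$mode, des$nontarget_type, sep = "-")
        base <- .condition_defaults(des$mode, des$nontarget_type)
        set.seed(.child_seed(seed, 100000L + counter))
        subj_p300 <- rnorm(1, base$p300$amp, sqrt(12) * p300_se[[key]])
        subj_p200 <- rnorm(1, base$p200$amp, 1.0)
        cfg$components <- condition_components(des$mode, des$nontarget_type,
                                               p300_amplitude = subj_p300,
                                               p200_amplitude = subj_p200)
      }
      sess <- if (epoched) {
        list(subject = s, design = des, seed = s_seed,
             epochs = generate_epochs(des, cfg, seed = s_seed))
      } else {
        list(subject = s, design = des, seed = s_seed,
             session = generate_session(des, cfg, seed = s_seed))
      }
      subj_sessions[[d]] <- if (is.null(fun)) sess else fun(sess)
    }
    out[[s]] <- subj_sessions
  }
  out
}
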
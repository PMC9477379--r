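#' Across-trial average ERP waveform
#'
#' Arithmetic mean over surviving epochs of one stimulus class.
#'
#' @param epochs An [aerp_epochs] object.
#' @param stimulus_class `"target"`, `"nontarget"` or `"all"`.
#' @return Channels x time matrix (uV) with channel rownames; attribute
#'   `"n_epochs"` carries the trial count.
#' @export
erp_average <- function(epochs,
                        stimulus_class = c("target", "nontarget", "all")) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  stimulus_class <- match.arg(stimulus_class)
  keep <- !epochs$rejected
  keep <- switch(stimulus_class,
                 target = keep & epochs$labels$is_target,
                 nontarget = keep & !epochs$labels$is_target,
                 all = keep)
  if (!any(keep)) {
    stop("no surviving ", stimulus_class, " epochs", call. = FALSE)
  }
  avg <- colMeans(epochs$data[keep, , , drop = FALSE])
  rownames(avg) <- epochs$channel_labels
  attr(avg, "n_epochs") <- sum(keep)
  avg
}

#' Window amplitude and peak measures on an average waveform
#'
#' Mean amplitude over the window, plus the signed extremum matching the
#' component polarity (positive for P-components, negative for N-components)
#' and its latency.  Measures are taken on the across-trial average, not on
#' single trials.
#'
#' @param avg_waveform Channels x time matrix from [erp_average()], or a
#'   single time-course vector.
#' @param channel Channel label or index (ignored for a vector input).
#' @param window_ms Length-2 window in ms (half-open `[start, end)`).
#' @param time_ms Time axis in ms; taken from `colnames` when absent only if
#'   supplied explicitly.
#' @param polarity `+1` for positive components (P200/P300), `-1` for
#'   negative (N2).
#' @return List with `mean_amplitude`, `peak_amplitude` (uV, signed) and
#'   `peak_latency_ms` (`NA` with a flag for a flat-zero window).
#' @export
measure_window <- function(avg_waveform, channel = NULL, window_ms, time_ms,
                           polarity = 1) {
  x <- if (is.matrix(avg_waveform)) {
    ch <- if (is.character(channel)) match(channel, rownames(avg_waveform))
          else as.integer(channel)
    if (is.na(ch)) stop("channel not found", call. = FALSE)
    avg_waveform[ch, ]
  } else {
    avg_waveform
  }
  sel <- time_ms >= window_ms[1] & time_ms < window_ms[2]
  if (!any(sel)) stop("window outside the time axis", call. = FALSE)
  xv <- x[sel]
  tv <- time_ms[sel]
  mean_amp <- mean(xv)
  if (all(xv == 0)) {
    return(list(mean_amplitude = 0, peak_amplitude = 0,
                peak_latency_ms = NA_real_, flat = TRUE))
  }
  i <- which.max(polarity * xv)
  list(mean_amplitude = mean_amp,
       peak_amplitude = xv[i],
       peak_latency_ms = tv[i],
       flat = FALSE)
}

#' Mean and standard error of a sample
#' @param x Numeric vector.
#' @return List with `mean`, `se` (`sd/sqrt(n)`) and `n`.
#' @export
mean_se <- function(x) {
  list(mean = mean(x), se = sd(x) / sqrt(length(x)), n = length(x))
}

#' Paired condition contrast across subjects
#'
#' Two-sided t-test for a within-subject contrast between two conditions
#' (paired across subjects), with per-group Mean +/- SE.  Raw p-values are
#' reported; a Bonferroni correction over a set of contrasts can be applied
#' by the caller via `p.adjust` if wanted.
#'
#' @param measures Data.frame with columns `subject`, `condition`, `value`.
#' @param cond_a,cond_b The two condition labels to contrast (a minus b).
#' @param paired Use within-subject pairing (default `TRUE`; subjects must
#'   appear in both conditions exactly once).
#' @return Data.frame with one row: `cond_a`, `cond_b`, group means and SEs,
#'   `t`, `df`, `p`.
#' @export
compare_conditions <- function(measures, cond_a, cond_b, paired = TRUE) {
  need <- c("subject", "condition", "value")
  stopifnot(all(need %in% names(measures)))
  a <- measures[measures$condition == cond_a, ]
  b <- measures[measures$condition == cond_b, ]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("need at least 2 subjects per condition", call. = FALSE)
  }
  if (paired) {
    common <- intersect(a$subject, b$subject)
    if (anyDuplicated(a$subject) || anyDuplicated(b$subject) ||
        length(common) != nrow(a) || length(common) != nrow(b)) {
      stop("paired contrast requires each subject once in both conditions",
           call. = FALSE)
    }
    a <- a[match(common, a$subject), ]
    b <- b[match(common, b$subject), ]
  }
  if (paired && sd(a$value - b$value) == 0) {
    # degenerate constant differences: identical pairs carry no evidence
    # against the null; a constant non-zero shift is infinitely strong
    d <- mean(a$value - b$value)
    tt <- list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
               parameter = c(df = nrow(a) - 1),
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- t.test(a$value, b$value, paired = paired)
  }
  ma <- mean_se(a$value)
  mb <- mean_se(b$value)
  data.frame(cond_a = cond_a, cond_b = cond_b,
             mean_a = ma$mean, se_a = ma$se,
             mean_b = mb$mean, se_b = mb$se,
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             stringsAsFactors = FALSE)
}
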
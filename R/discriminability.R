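#' Signed r-squared discriminability between two trial groups
#'
#' The squared, signed separation index used to judge where in
#' channel-by-time space targets and non-targets differ:
#' \deqn{r^2 = \pm \left[ \frac{\sqrt{M_T M_N}\,(\bar X_T - \bar X_N)}
#'   {(M_T + M_N)\, s(X_T \cup X_N)} \right]^2}
#' where \eqn{M_T, M_N} are the group sizes, \eqn{s} is the sample standard
#' deviation (n-1 denominator) of the pooled amplitudes, and the sign is the
#' sign of the target-minus-non-target mean difference.  Under the matching
#' standard-deviation convention this equals the signed squared
#' point-biserial correlation between amplitude and group label.
#'
#' @param target_values Numeric vector of per-trial target amplitudes (uV).
#' @param nontarget_values Numeric vector of per-trial non-target amplitudes.
#' @return Signed scalar in `[-1, 1]`; `NA` when the pooled standard
#'   deviation is zero (a constant channel carries no discriminative
#'   information).
#' @examples
#' signed_r2(c(1, 3), c(0, 2))  # +0.15
#' @export
signed_r2 <- function(target_values, nontarget_values) {
  m_t <- length(target_values)
  m_n <- length(nontarget_values)
  if (m_t < 2 || m_n < 2) {
    stop("each group needs at least 2 trials", call. = FALSE)
  }
  s <- sd(c(target_values, nontarget_values))
  if (!is.finite(s) || s == 0) return(NA_real_)
  diff <- mean(target_values) - mean(nontarget_values)
  r <- sqrt(m_t * m_n) * diff / ((m_t + m_n) * s)
  sign(diff) * r^2
}

#' Discriminability map over channels and time
#'
#' Applies [signed_r2()] independently at every (channel, time point) of an
#' epoch set, using surviving (non-rejected) epochs only.
#'
#' @param epochs An [aerp_epochs] object with at least 2 surviving target and
#'   2 surviving non-target epochs.
#' @return An object of class `aerp_r2map`: list with `values` (channels x
#'   time signed r-squared matrix), `time_ms`, `channel_labels`, `n_target`,
#'   `n_nontarget`.
#' @export
r2_map <- function(epochs) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  keep <- !epochs$rejected
  tgt <- keep & epochs$labels$is_target
  non <- keep & !epochs$labels$is_target
  if (sum(tgt) < 2) stop("fewer than 2 surviving target epochs", call. = FALSE)
  if (sum(non) < 2) stop("fewer than 2 surviving non-target epochs",
                         call. = FALSE)
  m_t <- sum(tgt)
  m_n <- sum(non)
  n <- m_t + m_n
  # vectorised over the (channel, time) grid
  xt <- epochs$data[tgt, , , drop = FALSE]
  xn <- epochs$data[non, , , drop = FALSE]
  mean_t <- colMeans(xt)            # channels x time
  mean_n <- colMeans(xn)
  sum_all <- m_t * mean_t + m_n * mean_n
  ss_all <- colSums(xt^2) + colSums(xn^2)
  var_pool <- (ss_all - sum_all^2 / n) / (n - 1)
  var_pool[var_pool < 0] <- 0       # numerical guard
  s <- sqrt(var_pool)
  diff <- mean_t - mean_n
  r <- sqrt(m_t * m_n) * diff / ((m_t + m_n) * s)
  vals <- sign(diff) * r^2
  vals[s == 0] <- NA_real_
  dimnames(vals) <- list(epochs$channel_labels, NULL)
  structure(list(values = vals,
                 time_ms = epochs$time_ms,
                 channel_labels = epochs$channel_labels,
                 n_target = m_t,
                 n_nontarget = m_n),
            class = "aerp_r2map")
}

#' @export
print.aerp_r2map <- function(x, ...) {
  i <- which(abs(x$values) == max(abs(x$values), na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("Signed r-squared map: %d channels x %d time points (%d vs %d trials)\n",
              nrow(x$values), ncol(x$values), x$n_target, x$n_nontarget))
  cat(sprintf("  peak |r2| = %.4f at %s, %g ms\n",
              abs(x$values[i[1], i[2]]), x$channel_labels[i[1]],
              x$time_ms[i[2]]))
  invisible(x)
}

#' Write a discriminability map as a delimited matrix
#'
#' Rows are channels (first column `channel`), remaining columns one per
#' time point with the time in ms as header.
#'
#' @param map An `aerp_r2map` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_r2_map <- function(map, path) {
  stopifnot(inherits(map, "aerp_r2map"))
  df <- data.frame(channel = map$channel_labels, map$values,
                   check.names = FALSE)
  names(df) <- c("channel", format(map$time_ms, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
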
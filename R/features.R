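#' Constraint time window
#'
#' A half-open time window `[start, end)` ms constraining where a feature
#' interval may be selected.  The defaults follow the two canonical ERP
#' windows: `T1 = [100, 300)` ms (early P200/N2 range) and
#' `T2 = [300, 600)` ms (P300 range).  A Results-style early window of
#' 200–300 ms can be set explicitly.
#'
#' @param label Window label, e.g. `"T1"`.
#' @param start_ms,end_ms Window bounds in ms, `start < end`.
#' @return Object of class `aerp_window`.
#' @export
constraint_window <- function(label, start_ms, end_ms) {
  stopifnot(start_ms < end_ms)
  structure(list(label = label, start_ms = start_ms, end_ms = end_ms),
            class = "aerp_window")
}

#' Default constraint windows
#' @return List of two [constraint_window()] objects, `T1 = [100, 300)` and
#'   `T2 = [300, 600)` ms.
#' @export
default_windows <- function() {
  list(constraint_window("T1", 100, 300),
       constraint_window("T2", 300, 600))
}

#' Per-time selection score inside a constraint window
#'
#' At each time point the score aggregates discriminability over channels as
#' `score(t) = mean_ch |r2(ch, t)| + max_ch |r2(ch, t)|`.  Selection is
#' sign-agnostic, so magnitudes are used.
#'
#' @param map An `aerp_r2map` object.
#' @param window An [constraint_window()] object.
#' @return Named numeric vector (names = time in ms) of scores over the
#'   window's time points.
#' @export
score_trace <- function(map, window) {
  stopifnot(inherits(map, "aerp_r2map"), inherits(window, "aerp_window"))
  sel <- map$time_ms >= window$start_ms & map$time_ms < window$end_ms
  if (!any(sel)) {
    stop("window [", window$start_ms, ", ", window$end_ms,
         ") ms does not overlap the map time axis", call. = FALSE)
  }
  v <- abs(map$values[, sel, drop = FALSE])
  if (all(is.na(v))) stop("all map values are missing in the window",
                          call. = FALSE)
  sc <- colMeans(v, na.rm = TRUE) + apply(v, 2, max, na.rm = TRUE)
  names(sc) <- format(map$time_ms[sel], trim = TRUE)
  sc
}

#' Across-trial correlation of adjacent time points
#'
#' Cosine similarity (inner product over vector norms, no mean-centering)
#' between the across-trial amplitude vectors of one channel at two time
#' points.
#'
#' @param epochs An [aerp_epochs] object (surviving epochs are used).
#' @param channel Channel label or index.
#' @param t_ms,t_next_ms The two time points in ms (must lie on the epoch
#'   time axis).
#' @return Scalar in `[-1, 1]`; `NA` if either vector has zero norm.
#' @examples
#' # x(t) = (1, 0, 1), x(t+dt) = (1, 1, 0) -> 1 / (sqrt(2) * sqrt(2)) = 0.5
#' @export
adjacent_correlation <- function(epochs, channel, t_ms, t_next_ms) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  ch <- if (is.character(channel)) match(channel, epochs$channel_labels)
        else as.integer(channel)
  if (is.na(ch)) stop("channel not found", call. = FALSE)
  i1 <- match(TRUE, abs(epochs$time_ms - t_ms) < 1e-6)
  i2 <- match(TRUE, abs(epochs$time_ms - t_next_ms) < 1e-6)
  if (is.na(i1) || is.na(i2)) {
    stop("time point not on the epoch time axis", call. = FALSE)
  }
  keep <- !epochs$rejected
  x1 <- epochs$data[keep, ch, i1]
  x2 <- epochs$data[keep, ch, i2]
  .cosine(x1, x2)
}

.cosine <- function(x1, x2) {
  n1 <- sqrt(sum(x1^2))
  n2 <- sqrt(sum(x2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  sum(x1 * x2) / (n1 * n2)
}

# median-over-channels cosine for each adjacent time-index pair
.adjacent_c_trace <- function(epochs, idx) {
  keep <- !epochs$rejected
  dat <- epochs$data[keep, , , drop = FALSE]
  n_pair <- length(idx) - 1L
  if (n_pair < 1L) return(numeric(0))
  out <- numeric(n_pair)
  for (p in seq_len(n_pair)) {
    a <- dat[, , idx[p]]
    b <- dat[, , idx[p + 1L]]
    num <- colSums(a * b)
    den <- sqrt(colSums(a^2)) * sqrt(colSums(b^2))
    cs <- ifelse(den == 0, NA_real_, num / den)
    out[p] <- median(cs, na.rm = TRUE)
  }
  out
}

#' Select a contiguous feature time range inside a constraint window
#'
#' Implements the correlation-constrained range rule: a time point is
#' eligible when its score exceeds half the window's maximum score
#' (`score(t) > 0.5 * max score`), and two eligible neighbours may join the
#' same range only when their channel-aggregated (median over channels)
#' adjacent-time cosine correlation exceeds `c_threshold`.  The selected
#' range is the longest such contiguous run; ties are broken toward the run
#' containing the score maximum.  If no time point is eligible the single
#' maximal-score point is returned with a warning.
#'
#' @param map An `aerp_r2map` object.
#' @param epochs The [aerp_epochs] object the map was computed from.
#' @param window An [constraint_window()] object.
#' @param c_threshold Correlation threshold (default 0.7).
#' @return Object of class `aerp_range`: list with `window_label`,
#'   `t_start_ms`, `t_end_ms`, `times_ms` (the selected time points),
#'   `score_trace`, `correlation_trace`, `fallback` flag.
#' @export
select_range <- function(map, epochs, window, c_threshold = 0.7) {
  sc <- score_trace(map, window)
  sel_idx <- which(map$time_ms >= window$start_ms &
                     map$time_ms < window$end_ms)
  times <- map$time_ms[sel_idx]
  ctrace <- .adjacent_c_trace(epochs, sel_idx)
  pass <- sc > 0.5 * max(sc)
  fallback <- FALSE
  if (!any(pass)) {
    run <- which.max(sc)
    fallback <- TRUE
    warning("no time point passed the score criterion in window ",
            window$label, "; falling back to the single maximal-score point")
  } else {
    # links between consecutive eligible points require c > threshold
    n <- length(sc)
    link <- logical(max(n - 1L, 0L))
    if (n > 1L) {
      link <- pass[-n] & pass[-1L] & !is.na(ctrace) & ctrace > c_threshold
    }
    # enumerate maximal runs: each eligible point starts a run unless linked
    runs <- list()
    cur <- NULL
    for (i in seq_len(n)) {
      if (!pass[i]) {
        if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
        cur <- NULL
      } else if (is.null(cur)) {
        cur <- i
      } else if (link[i - 1L]) {
        cur <- c(cur, i)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- i
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
    lens <- vapply(runs, length, integer(1))
    best_len <- max(lens)
    cand <- which(lens == best_len)
    if (length(cand) > 1L) {
      imax <- which.max(sc)
      holds_max <- vapply(runs[cand], function(r) imax %in% r, logical(1))
      cand <- if (any(holds_max)) cand[which(holds_max)[1]] else cand[1]
    }
    run <- runs[[cand[1]]]
  }
  structure(list(window_label = window$label,
                 t_start_ms = times[min(run)],
                 t_end_ms = times[max(run)],
                 times_ms = times[run],
                 score_trace = sc,
                 correlation_trace = ctrace,
                 fallback = fallback),
            class = "aerp_range")
}

#' @export
print.aerp_range <- function(x, ...) {
  cat(sprintf("Selected range %s: %g..%g ms (%d time points)%s\n",
              x$window_label, x$t_start_ms, x$t_end_ms, length(x$times_ms),
              if (x$fallback) " [fallback: single max-score point]" else ""))
  invisible(x)
}

#' Averaged-amplitude feature matrix
#'
#' For every surviving epoch, channel and selected range, averages the
#' amplitudes over the range's time points: one feature per
#' (window, channel), so a default session (2 windows x 60 channels) yields
#' a 500 x 120 matrix.  Rows are labelled +1 (target) / -1 (non-target).
#'
#' @param epochs An [aerp_epochs] object.
#' @param ranges List of [select_range()] results (one per window).
#' @return Object of class `aerp_features`: list with `x` (matrix, columns
#'   named `<window>.<channel>`), `y` (+1/-1), `name_id`, `block`,
#'   `repetition`, `window` and `channel` column descriptors, and `target`
#'   (the target name).
#' @export
extract_features <- function(epochs, ranges) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  keep <- !epochs$rejected
  if (!any(keep)) stop("no surviving epochs", call. = FALSE)
  dat <- epochs$data[keep, , , drop = FALSE]
  blocks <- lapply(ranges, function(r) {
    stopifnot(inherits(r, "aerp_range"))
    idx <- match(r$times_ms, epochs$time_ms)
    if (anyNA(idx)) {
      stop("range ", r$window_label, " lies outside the epoch time axis",
           call. = FALSE)
    }
    m <- apply(dat[, , idx, drop = FALSE], c(1, 2), mean)
    colnames(m) <- paste(r$window_label, epochs$channel_labels, sep = ".")
    m
  })
  x <- do.call(cbind, blocks)
  lab <- epochs$labels[keep, ]
  y <- ifelse(lab$is_target, 1L, -1L)
  structure(list(x = x, y = y,
                 name_id = lab$name_id,
                 block = lab$block,
                 repetition = lab$repetition,
                 window = rep(vapply(ranges, `[[`, "", "window_label"),
                              each = length(epochs$channel_labels)),
                 channel = rep(epochs$channel_labels, length(ranges)),
                 target = unique(lab$name_id[lab$is_target])),
            class = "aerp_features")
}

#' @export
print.aerp_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$window), collapse = ", ")))
  cat(sprintf("  +1 (target): %d; -1 (non-target): %d\n",
              sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

#' Write a feature matrix as a delimited table
#'
#' Two header lines (`window`, `channel`) describe the columns; the data
#' rows append a final `label` column (+1/-1).
#'
#' @param features An `aerp_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "aerp_features"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(features$window, "label"), collapse = "\t"), con)
  writeLines(paste(c(features$channel, "label"), collapse = "\t"), con)
  write.table(cbind(format(features$x, digits = 10, trim = TRUE),
                    features$y),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
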
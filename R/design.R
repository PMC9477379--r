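#' Oddball session design
#'
#' Describes one experimental session of the name-stimulus oddball paradigm:
#' a handful of spoken names, exactly one of which (the subject's own name)
#' is the target, presented block by block in repetitions that each contain
#' every name once.  The default mirrors the standard session: 5 blocks of
#' 20 repetitions over 5 names (1 target + 4 non-targets), 600 ms stimuli
#' and an inter-stimulus interval drawn uniformly from 500–800 ms.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param n_repetitions Repetitions per block; each repetition presents every
#'   name exactly once.
#' @param names Character vector of name identifiers.
#' @param target Which entry of `names` is the target (the subject's own
#'   name).  Exactly one target is required.
#' @param stimulus_duration_ms Stimulus length in ms.
#' @param isi_range_ms Length-2 numeric, min/max inter-stimulus interval in
#'   ms (silence between stimulus offset and the next onset).
#' @param mode `"active"` (silent counting) or `"passive"` (listening only).
#' @param nontarget_type `"3CC"` or `"2CC"`: three- vs two-syllable
#'   (Chinese-character) non-target names.
#' @return An object of class `aerp_design`.
#' @examples
#' d <- session_design()
#' d$n_blocks * d$n_repetitions * length(d$names)  # 500 stimuli
#' @export
session_design <- function(n_blocks = 5L,
                           n_repetitions = 20L,
                           names = c("SON", "ON1", "ON2", "ON3", "ON4"),
                           target = "SON",
                           stimulus_duration_ms = 600,
                           isi_range_ms = c(500, 800),
                           mode = c("active", "passive"),
                           nontarget_type = c("3CC", "2CC")) {
  mode <- match.arg(mode)
  nontarget_type <- match.arg(nontarget_type)
  n_blocks <- as.integer(n_blocks)
  n_repetitions <- as.integer(n_repetitions)
  stopifnot(n_blocks >= 1L, n_repetitions >= 1L,
            length(isi_range_ms) == 2L,
            isi_range_ms[1] <= isi_range_ms[2],
            stimulus_duration_ms > 0)
  if (anyDuplicated(names)) stop("names must be unique", call. = FALSE)
  if (length(target) != 1L || !target %in% names) {
    stop("exactly one target is required and it must be one of `names`",
         call. = FALSE)
  }
  structure(list(n_blocks = n_blocks,
                 n_repetitions = n_repetitions,
                 names = names,
                 target = target,
                 stimulus_duration_ms = stimulus_duration_ms,
                 isi_range_ms = as.numeric(isi_range_ms),
                 mode = mode,
                 nontarget_type = nontarget_type),
            class = "aerp_design")
}

#' @export
print.aerp_design <- function(x, ...) {
  cat("Oddball session design\n")
  cat(sprintf("  %d blocks x %d repetitions x %d names = %d stimuli\n",
              x$n_blocks, x$n_repetitions, length(x$names),
              x$n_blocks * x$n_repetitions * length(x$names)))
  cat(sprintf("  target: %s; non-targets: %s\n", x$target,
              paste(setdiff(x$names, x$target), collapse = ", ")))
  cat(sprintf("  stimulus %g ms, ISI %g-%g ms, mode %s, non-target type %s\n",
              x$stimulus_duration_ms, x$isi_range_ms[1], x$isi_range_ms[2],
              x$mode, x$nontarget_type))
  invisible(x)
}

#' Generate a pseudo-random oddball stimulus sequence
#'
#' Produces the event table of one session.  Within each repetition every
#' name appears exactly once, and across the whole sequence two adjacent
#' stimuli are never the same name (the constraint also holds across
#' repetition and block boundaries).  Onsets accumulate stimulus duration
#' plus an inter-stimulus interval drawn uniformly from the design's ISI
#' range.
#'
#' @param design An [session_design()] object.
#' @param seed Integer seed; the sequence is a deterministic function of
#'   `(design, seed)`.
#' @param t_start_ms Onset of the first stimulus, in ms from recording start.
#' @return A data.frame of events with columns `onset_ms`, `name_id`,
#'   `is_target` (logical), `block`, `repetition` (both 0-based integers).
#' @examples
#' ev <- generate_sequence(session_design(), seed = 1)
#' nrow(ev)            # 500
#' sum(ev$is_target)   # 100
#' @export
generate_sequence <- function(design, seed, t_start_ms = 5000) {
  stopifnot(inherits(design, "aerp_design"))
  n_names <- length(design$names)
  if (n_names < 2L) {
    stop("at least 2 names are needed to satisfy the no-adjacent-repeat ",
         "constraint", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_rep_total <- design$n_blocks * design$n_repetitions
  seq_names <- character(n_rep_total * n_names)
  prev <- NA_character_
  k <- 0L
  for (r in seq_len(n_rep_total)) {
    # a permutation of distinct names has no internal repeats; only the
    # boundary with the previous repetition needs care
    repeat {
      perm <- sample(design$names)
      if (is.na(prev) || perm[1] != prev) break
    }
    seq_names[k + seq_len(n_names)] <- perm
    prev <- perm[n_names]
    k <- k + n_names
  }
  n_ev <- length(seq_names)
  isi <- runif(n_ev - 1L, design$isi_range_ms[1], design$isi_range_ms[2])
  onsets <- t_start_ms + c(0, cumsum(design$stimulus_duration_ms + isi))
  rep_global <- rep(seq_len(n_rep_total) - 1L, each = n_names)
  data.frame(onset_ms = onsets,
             name_id = seq_names,
             is_target = seq_names == design$target,
             block = as.integer(rep_global %/% design$n_repetitions),
             repetition = as.integer(rep_global %% design$n_repetitions),
             stringsAsFactors = FALSE)
}

#' Read or write an oddball event table
#'
#' Tab-separated, UTF-8, header exactly
#' `onset_ms name_id is_target block repetition`; times in ms as decimals,
#' block/repetition 0-based.
#'
#' @param events Event data.frame as returned by [generate_sequence()].
#' @param path File path.
#' @return `read_event_table()` returns the event data.frame;
#'   `write_event_table()` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  cols <- c("onset_ms", "name_id", "is_target", "block", "repetition")
  stopifnot(all(cols %in% names(events)))
  df <- events[, cols]
  df$is_target <- as.integer(df$is_target)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("onset_ms", "name_id", "is_target", "block", "repetition")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$is_target <- as.logical(df$is_target)
  df$block <- as.integer(df$block)
  df$repetition <- as.integer(df$repetition)
  df
}
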
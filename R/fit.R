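#' Fit the oddball target-detection model to an epoch set
#'
#' The package's core estimator.  Starting from cleaned, baseline-corrected
#' epochs it runs the full discriminative analysis:
#'
#' 1. signed r-squared discriminability map over channels x time
#'    ([r2_map()]);
#' 2. correlation-constrained selection of one contiguous time range per
#'    constraint window ([select_range()]; defaults `T1 = [100, 300)`,
#'    `T2 = [300, 600)` ms);
#' 3. averaged-amplitude features, one per (window, channel)
#'    ([extract_features()]);
#' 4. balanced target-vs-each-non-target linear SVM with stratified k-fold
#'    cross-validation, pairing-averaged accuracy and held-out decision
#'    values ([binary_pairing_cv()]);
#' 5. repetition-aggregated name identification for k = 1..K repetitions
#'    ([repetition_decision()]) and ROC/AUC over pooled held-out decision
#'    values ([roc_auc()]).
#'
#' @param epochs An [aerp_epochs] object (baseline-corrected; rejected
#'   epochs are excluded automatically).
#' @param windows List of [constraint_window()] objects (default
#'   [default_windows()]).
#' @param c_threshold Adjacent-time correlation threshold for range
#'   selection (default 0.7).
#' @param folds Cross-validation folds (default 10).
#' @param cost Linear SVM cost (default 1).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `aerp_fit` with elements `map`, `ranges`,
#'   `features`, `cv`, `repetition` (data.frame `k`, `accuracy`), `roc`,
#'   `auc`, `final_models` (per-pairing SVMs refit on all data, used by
#'   `predict`), and the call.
#' @examples
#' \donttest{
#' d <- session_design(n_blocks = 2, n_repetitions = 10)
#' ep <- generate_epochs(d, generator_config(sampling_rate = 200), seed = 7)
#' ep <- baseline_correct(ep)
#' fit <- aerp_fit(ep, seed = 7)
#' print(fit)
#' }
#' @export
aerp_fit <- function(epochs, windows = default_windows(), c_threshold = 0.7,
                     folds = 10, cost = 1, seed) {
  stopifnot(inherits(epochs, "aerp_epochs"))
  map <- r2_map(epochs)
  ranges <- lapply(windows, function(w) {
    select_range(map, epochs, w, c_threshold)
  })
  features <- extract_features(epochs, ranges)
  cv <- binary_pairing_cv(features, folds = folds, cost = cost, seed = seed)
  n_rep <- max(features$repetition) + 1L
  rep_acc <- vapply(seq_len(n_rep), function(k) {
    repetition_decision(cv$decisions, cv$target, k)$accuracy
  }, numeric(1))
  roc <- roc_auc(cv$decisions$decision_value, cv$decisions$is_target)
  # refit per-pairing models on all data for predict()
  mu <- colMeans(features$x)
  sg <- apply(features$x, 2, sd)
  sg[sg == 0] <- 1
  others <- names(cv$pairing_accuracy)
  final_models <- lapply(others, function(on) {
    rows <- features$name_id %in% c(cv$target, on)
    xs <- scale(features$x[rows, , drop = FALSE], mu, sg)
    e1071::svm(xs, factor(features$y[rows], levels = c(1, -1)),
               kernel = "linear", cost = cost, scale = FALSE)
  })
  names(final_models) <- others
  structure(list(map = map, ranges = ranges, features = features, cv = cv,
                 repetition = data.frame(k = seq_len(n_rep),
                                         accuracy = rep_acc),
                 roc = roc$points, auc = roc$auc,
                 final_models = final_models,
                 scaling = list(center = mu, scale = sg),
                 c_threshold = c_threshold, folds = folds, cost = cost,
                 seed = seed, call = match.call()),
            class = "aerp_fit")
}

#' @export
print.aerp_fit <- function(x, ...) {
  cat("Oddball ERP target-detection fit\n")
  for (r in x$ranges) {
    cat(sprintf("  %s range: %g..%g ms\n", r$window_label, r$t_start_ms,
                r$t_end_ms))
  }
  cat(sprintf("  single-trial accuracy: %.2f %% (mean of %d pairings, %d-fold CV)\n",
              x$cv$accuracy, length(x$cv$pairing_accuracy), x$folds))
  cat(sprintf("  AUC: %.3f; name identification at k = %d repetitions: %.1f %%\n",
              x$auc, max(x$repetition$k),
              x$repetition$accuracy[nrow(x$repetition)]))
  invisible(x)
}

#' @export
summary.aerp_fit <- function(object, ...) {
  out <- list(
    n_epochs = nrow(object$features$x),
    n_features = ncol(object$features$x),
    ranges = do.call(rbind, lapply(object$ranges, function(r) {
      data.frame(window = r$window_label, t_start_ms = r$t_start_ms,
                 t_end_ms = r$t_end_ms, n_points = length(r$times_ms),
                 fallback = r$fallback)
    })),
    pairing_accuracy = object$cv$pairing_accuracy,
    accuracy = object$cv$accuracy,
    auc = object$auc,
    repetition = object$repetition,
    peak = {
      v <- object$map$values
      i <- which(abs(v) == max(abs(v), na.rm = TRUE), arr.ind = TRUE)[1, ]
      data.frame(channel = object$map$channel_labels[i[1]],
                 time_ms = object$map$time_ms[i[2]],
                 signed_r2 = v[i[1], i[2]])
    }
  )
  class(out) <- "summary.aerp_fit"
  out
}

#' @export
print.summary.aerp_fit <- function(x, ...) {
  cat("Oddball ERP target-detection fit\n")
  cat(sprintf("  %d epochs, %d features\n", x$n_epochs, x$n_features))
  cat("  Selected ranges:\n")
  print(x$ranges, row.names = FALSE)
  cat(sprintf("  Peak discriminability: signed r2 = %.4f at %s, %g ms\n",
              x$peak$signed_r2, x$peak$channel, x$peak$time_ms))
  cat(sprintf("  Single-trial accuracy %.2f %%; AUC %.3f\n", x$accuracy,
              x$auc))
  cat(sprintf("  Name identification: %.1f %% at k = 1, %.1f %% at k = %d\n",
              x$repetition$accuracy[1],
              x$repetition$accuracy[nrow(x$repetition)],
              x$repetition$k[nrow(x$repetition)]))
  invisible(x)
}

#' Feature weights of the fitted classifier
#'
#' Primal weight vector `w = t(coefs) %*% SV` of each pairing's linear SVM
#' (refit on all data, on the standardised feature scale), averaged over the
#' four pairings.  Large |weight| marks (window, channel) features driving
#' the target/non-target separation.
#'
#' @param object An `aerp_fit` object.
#' @param ... Unused.
#' @return Named numeric vector, one weight per feature column.
#' @export
coef.aerp_fit <- function(object, ...) {
  ws <- vapply(object$final_models, function(m) {
    w <- crossprod(m$coefs, m$SV)[1, ]
    # orient toward the target (+1) class
    pr <- predict(m, m$SV[1, , drop = FALSE], decision.values = TRUE)
    if (!startsWith(colnames(attr(pr, "decision.values"))[1], "1")) w <- -w
    w
  }, numeric(ncol(object$features$x)))
  out <- rowMeans(ws)
  names(out) <- colnames(object$features$x)
  out
}

#' Predict target/non-target for new epochs
#'
#' Extracts features from `newdata` with the fitted time ranges, applies the
#' training standardisation and averages the decision values of the
#' per-pairing SVMs (positive = target).
#'
#' @param object An `aerp_fit` object.
#' @param newdata An [aerp_epochs] object on the same channels/time axis, or
#'   `NULL` for the training epochs.
#' @param ... Unused.
#' @return Data.frame with `name_id`, `decision_value`, `class`
#'   (+1 target / -1 non-target by the sign of the decision value).
#' @export
predict.aerp_fit <- function(object, newdata = NULL, ...) {
  feats <- if (is.null(newdata)) object$features
           else extract_features(newdata, object$ranges)
  xs <- scale(feats$x, object$scaling$center, object$scaling$scale)
  dvs <- vapply(object$final_models, function(m) {
    pr <- predict(m, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    if (!startsWith(colnames(attr(pr, "decision.values"))[1], "1")) dv <- -dv
    dv
  }, numeric(nrow(xs)))
  dv <- rowMeans(dvs)
  data.frame(name_id = feats$name_id,
             decision_value = dv,
             class = ifelse(dv > 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Plot an oddball fit
#'
#' Two panels: the per-window selection score over time with the selected
#' ranges shaded, and the ROC curve of the pooled held-out decision values.
#'
#' @param x An `aerp_fit` object.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.aerp_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  all_t <- unlist(lapply(x$ranges, function(r) as.numeric(names(r$score_trace))))
  all_s <- unlist(lapply(x$ranges, `[[`, "score_trace"))
  plot(all_t, all_s, type = "n", xlab = "time (ms)",
       ylab = "score(t) = mean + max |signed r2|",
       main = "Window selection", ...)
  for (r in x$ranges) {
    tt <- as.numeric(names(r$score_trace))
    polygon(c(r$t_start_ms, r$t_end_ms, r$t_end_ms, r$t_start_ms),
            c(0, 0, max(all_s), max(all_s)),
            col = "grey90", border = NA)
    lines(tt, r$score_trace)
  }
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}
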
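# stratified fold assignment: within each class, a random permutation is
# dealt round-robin into `folds` groups; deterministic given the RNG state
.stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has ", length(idx), " samples, fewer than ",
           folds, " folds", call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold
}

# train/predict one linear SVM with per-fold standardisation; returns the
# held-out decision values oriented so positive favours the target class
.svm_fold <- function(x_tr, y_tr, x_te, cost) {
  mu <- colMeans(x_tr)
  sg <- apply(x_tr, 2, sd)
  sg[sg == 0] <- 1
  x_tr <- scale(x_tr, mu, sg)
  x_te <- scale(x_te, mu, sg)
  yf <- factor(y_tr, levels = c(1, -1))
  fit <- e1071::svm(x_tr, yf, kernel = "linear", cost = cost, scale = FALSE)
  pr <- predict(fit, x_te, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  # e1071 orients decision values toward the first label of "<a>/<b>"
  if (!startsWith(colnames(attr(pr, "decision.values"))[1], "1")) dv <- -dv
  list(pred = as.integer(as.character(pr)), dv = dv)
}

#' Binary target-vs-non-target SVM with pairing-averaged cross-validation
#'
#' Because the classes are strongly unbalanced (1 target name vs 4 non-target
#' names, 100 trials each), classification is run as four balanced binary
#' problems — the target name against each non-target name — each evaluated
#' with stratified k-fold cross-validation of a linear SVM.  The final
#' single-trial accuracy is the mean of the four pairing accuracies.
#' Held-out decision values (signed margins, positive = target) are retained
#' for every trial: non-target trials get the value from their own pairing,
#' target trials the mean over the four pairings in which they appear.
#'
#' @param features An `aerp_features` object (see [extract_features()]).
#' @param folds Number of cross-validation folds (default 10).
#' @param cost Linear SVM regularisation constant (default 1, untuned).
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `aerp_cv`: list with `pairings` (per-pairing
#'   data.frames of fold accuracies), `pairing_accuracy` (%), `accuracy`
#'   (mean %, the headline single-trial accuracy), `decisions` (per-trial
#'   data.frame: `name_id`, `is_target`, `block`, `repetition`,
#'   `decision_value`), `folds`, `cost`, `seed`.
#' @export
binary_pairing_cv <- function(features, folds = 10, cost = 1, seed) {
  stopifnot(inherits(features, "aerp_features"))
  set.seed(as.integer(seed))
  target <- features$target
  if (length(target) != 1L) {
    stop("features must contain exactly one target name", call. = FALSE)
  }
  others <- setdiff(unique(features$name_id), target)
  if (length(others) < 1L) stop("no non-target names present", call. = FALSE)
  tgt_rows <- which(features$name_id == target)
  dv_tgt <- matrix(NA_real_, length(tgt_rows), length(others))
  pairings <- list()
  pair_acc <- numeric(length(others))
  dec_rows <- list()
  for (p in seq_along(others)) {
    on_rows <- which(features$name_id == others[p])
    rows <- c(tgt_rows, on_rows)
    x <- features$x[rows, , drop = FALSE]
    y <- features$y[rows]
    fold <- .stratified_folds(y, folds)
    acc <- numeric(folds)
    dv <- numeric(length(rows))
    for (f in seq_len(folds)) {
      te <- fold == f
      r <- .svm_fold(x[!te, , drop = FALSE], y[!te],
                     x[te, , drop = FALSE], cost)
      acc[f] <- mean(r$pred == y[te]) * 100
      dv[te] <- r$dv
    }
    pair_acc[p] <- mean(acc)
    pairings[[others[p]]] <- data.frame(fold = seq_len(folds),
                                        accuracy = acc)
    dv_tgt[, p] <- dv[seq_along(tgt_rows)]
    dec_rows[[p]] <- data.frame(row = on_rows,
                                decision_value = dv[-seq_along(tgt_rows)])
  }
  dec <- rbind(data.frame(row = tgt_rows, decision_value = rowMeans(dv_tgt)),
               do.call(rbind, dec_rows))
  dec <- dec[order(dec$row), ]
  decisions <- data.frame(name_id = features$name_id[dec$row],
                          is_target = features$y[dec$row] == 1L,
                          block = features$block[dec$row],
                          repetition = features$repetition[dec$row],
                          decision_value = dec$decision_value,
                          stringsAsFactors = FALSE)
  structure(list(pairings = pairings,
                 pairing_accuracy = stats::setNames(pair_acc, others),
                 accuracy = mean(pair_acc),
                 decisions = decisions,
                 target = target,
                 folds = folds, cost = cost, seed = seed),
            class = "aerp_cv")
}

#' @export
print.aerp_cv <- function(x, ...) {
  cat(sprintf("Linear SVM, %d-fold stratified CV, %d balanced pairings\n",
              x$folds, length(x$pairing_accuracy)))
  cat(sprintf("  pairing accuracies: %s %%\n",
              paste(sprintf("%.1f", x$pairing_accuracy), collapse = ", ")))
  cat(sprintf("  mean single-trial accuracy: %.2f %%\n", x$accuracy))
  invisible(x)
}

#' Repetition-aggregated name identification
#'
#' Within each block, every name's held-out decision values over its first
#' `k` presentations are averaged; the name with the highest mean decision
#' value is called the target.  Accuracy is the fraction of blocks whose
#' call matches the true target name.  Exact ties are resolved toward the
#' lowest name index (alphabetical order of the name identifiers) and
#' flagged.
#'
#' @param decisions Per-trial decision data.frame (element `decisions` of an
#'   `aerp_cv` object).
#' @param target The true target name identifier.
#' @param k Number of repetitions to aggregate (1-based; must not exceed the
#'   repetitions available).
#' @return List with `calls` (per-block data.frame: `block`, `call`, `tie`)
#'   and `accuracy` (%).
#' @export
repetition_decision <- function(decisions, target, k) {
  stopifnot(k >= 1)
  if (k > max(decisions$repetition) + 1L) {
    stop("k = ", k, " exceeds the ", max(decisions$repetition) + 1L,
         " repetitions available", call. = FALSE)
  }
  sub <- decisions[decisions$repetition < k, ]
  names_all <- sort(unique(decisions$name_id))
  blocks <- sort(unique(decisions$block))
  calls <- data.frame(block = blocks, call = NA_character_, tie = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(blocks)) {
    b <- sub[sub$block == blocks[i], ]
    mv <- vapply(names_all, function(nm) {
      mean(b$decision_value[b$name_id == nm])
    }, numeric(1))
    top <- which(mv == max(mv))
    calls$call[i] <- names_all[top[1]]   # lowest-index tie-break
    calls$tie[i] <- length(top) > 1L
  }
  if (any(calls$tie)) {
    message(sum(calls$tie), " block(s) had tied decision values; ",
            "lowest name index used")
  }
  list(calls = calls, accuracy = mean(calls$call == target) * 100)
}

#' ROC curve and AUC from decision values
#'
#' Threshold sweep over the unique decision values; the area under the curve
#' is computed by the trapezoidal rule and equals the Mann-Whitney U
#' statistic normalised by `n_pos * n_neg` (ties counted half).
#'
#' @param decision_values Numeric vector of signed margins.
#' @param labels Logical (or +1/-1) vector, `TRUE`/+1 = positive class.
#' @return List with `points` (data.frame `fpr`, `tpr`, monotone
#'   non-decreasing) and `auc`.
#' @export
roc_auc <- function(decision_values, labels) {
  if (is.numeric(labels)) labels <- labels > 0
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(decision_values, decreasing = TRUE)
  lab <- labels[ord]
  dv <- decision_values[ord]
  # collapse tied thresholds
  grp <- cumsum(!duplicated(dv))
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
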
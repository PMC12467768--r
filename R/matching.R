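## 10-candidate annotation-matching evaluation over encodings.

#' One-hot feature expansion of an encoding
#'
#' The 21 upper-triangle cells are nominal relation codes, so each is
#' expanded into five indicator features (codes 1..5; 0 is the implicit
#' baseline), giving 105 binary features and avoiding fake ordinality.
#'
#' @param encodings list of `cae_matrix` objects.
#' @return numeric matrix, encodings x 105.
#' @export
cae_features <- function(encodings) {
  X <- t(vapply(encodings, cae_upper, integer(21)))
  out <- matrix(0, nrow(X), 21 * 5)
  cn <- character(21 * 5)
  for (cell in seq_len(21)) {
    for (code in 1:5) {
      col <- (cell - 1) * 5 + code
      out[, col] <- as.numeric(X[, cell] == code)
      cn[col] <- paste0("c", colnames(X)[cell] %||% cell, "_", code)
    }
  }
  colnames(out) <- cn
  rownames(out) <- rownames(X)
  out
}

#' Train an annotation matcher
#'
#' A margin-based multi-class classifier (support vector machine, one
#' against one with probability calibration) over one-hot encoded relation
#' features; its per-label calibrated scores drive the 10-candidate
#' matching task.
#'
#' @param encodings list of `cae_matrix` training examples.
#' @param labels label per example (>= 2 labels, each >= 2 examples).
#' @param kernel `"linear"`, `"poly"` or `"rbf"`.
#' @param seed integer seed (probability calibration is resampling-based).
#' @param cost soft-margin cost (default 10; the one-hot features are
#'   binary and noiseless, so a hard margin is appropriate).
#' @param gamma kernel width for the rbf/poly kernels (default 0.1 on the
#'   105 binary features).
#' @return object of class `cae_matcher`.
#' @export
train_matcher <- function(encodings, labels, kernel = c("rbf", "linear",
                                                        "poly"), seed = 1,
                          cost = 10, gamma = 0.1) {
  kernel <- match.arg(kernel)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 labels", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("every label needs at least 2 training examples", call. = FALSE)
  }
  X <- cae_features(encodings)
  svm_kernel <- c(rbf = "radial", linear = "linear", poly = "polynomial")
  fit <- with_seed(seed, e1071::svm(X, labels, kernel = svm_kernel[[kernel]],
                                    probability = TRUE, scale = FALSE,
                                    cost = cost, gamma = gamma))
  structure(list(fit = fit, labels = levels(labels), kernel = kernel,
                 seed = seed),
            class = "cae_matcher")
}

#' Score candidate encodings for a query label
#'
#' @param matcher a `cae_matcher`.
#' @param label query label; a bag of part labels may be given as a
#'   character vector or a `";"`-separated string (scores are summed).
#' @param encodings list of candidate `cae_matrix` objects.
#' @return numeric score per candidate; unseen labels score 0 with a
#'   warning.
#' @export
matcher_scores <- function(matcher, label, encodings) {
  stopifnot(inherits(matcher, "cae_matcher"))
  labs <- unlist(strsplit(as.character(label), ";"), use.names = FALSE)
  labs <- trimws(labs)
  X <- cae_features(encodings)
  pred <- stats::predict(matcher$fit, X, probability = TRUE)
  prob <- attr(pred, "probabilities")
  scores <- numeric(nrow(X))
  for (l in labs) {
    if (l %in% colnames(prob)) {
      scores <- scores + prob[, l]
    } else {
      warning("unseen label '", l, "' scored 0", call. = FALSE)
    }
  }
  scores
}

#' Run the 10-candidate annotation-matching task
#'
#' For each trial, scores the 10 candidate figures for the query label and
#' chooses the argmax (ties broken by the lowest candidate index, logged in
#' the per-trial table). Chance is 0.1.
#'
#' @param matcher a `cae_matcher`.
#' @param trials data.frame with columns `trial_id`, `query_label`,
#'   `cand1`..`cand10`, `correct`.
#' @param encodings named list of `cae_matrix` objects covering the
#'   candidates.
#' @param condition optional condition tag (e.g. `"whole_black"`) recorded
#'   in the result.
#' @return object of class `matching_result`: list with `accuracy`,
#'   `n_trials`, `chance` (0.1), `condition` and the per-trial `detail`
#'   table (chosen id, correctness, tie flag).
#' @export
run_matching <- function(matcher, trials, encodings, condition = "whole") {
  cand_cols <- paste0("cand", 1:10)
  stopifnot(all(c("query_label", cand_cols, "correct") %in% names(trials)))
  detail <- data.frame(trial_id = trials$trial_id %||% seq_len(nrow(trials)),
                       chosen = NA_character_, correct = NA, tie = FALSE)
  keep <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    cands <- as.character(unlist(trials[i, cand_cols], use.names = FALSE))
    if (!all(cands %in% names(encodings))) {
      warning("trial ", detail$trial_id[i],
              " skipped: missing candidate encoding", call. = FALSE)
      next
    }
    sc <- matcher_scores(matcher, trials$query_label[i], encodings[cands])
    best <- which(sc == max(sc))
    detail$tie[i] <- length(best) > 1
    chosen <- cands[min(best)]
    detail$chosen[i] <- chosen
    detail$correct[i] <- chosen == trials$correct[i]
    keep[i] <- TRUE
  }
  acc <- mean(detail$correct[keep])
  structure(list(accuracy = acc, n_trials = sum(keep), chance = 0.1,
                 condition = condition, detail = detail),
            class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat("<matching_result>", x$condition, ": accuracy",
      format(x$accuracy, digits = 3), "over", x$n_trials,
      "trials (chance 0.1)\n")
  invisible(x)
}

#' Build matching trials from a labelled figure set
#'
#' Each figure becomes one trial: its label is the query, itself the correct
#' candidate, and 9 distractors are drawn without replacement from the other
#' figures.
#'
#' @param ids figure ids.
#' @param labels query label per figure.
#' @param seed integer seed for distractor draws.
#' @return trials data.frame suitable for [run_matching()].
#' @export
make_matching_trials <- function(ids, labels, seed = 1) {
  stopifnot(length(ids) >= 10, length(ids) == length(labels))
  with_seed(seed, {
    rows <- lapply(seq_along(ids), function(i) {
      distract <- sample(setdiff(ids, ids[i]), 9)
      cands <- sample(c(ids[i], distract))
      out <- data.frame(trial_id = i, query_label = labels[i])
      out[paste0("cand", 1:10)] <- as.list(cands)
      out$correct <- ids[i]
      out
    })
    do.call(rbind, rows)
  })
}
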
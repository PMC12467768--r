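## Local feature density via decision-tree classification efficiency at
## varying matrix granularity.
##
## At scale s the classifier sees the best single s-piece submatrix (chosen
## on the training folds by summed Gini gain of its cells); s = 2 is the
## "local" scale (one connection), s = 7 the "global" scale (full matrix).

gini_impurity <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  1 - sum(p^2)
}

gini_gain <- function(x, y) {
  parent <- gini_impurity(y)
  parts <- split(y, x, drop = TRUE)
  child <- sum(vapply(parts, function(g) {
    length(g) / length(y) * gini_impurity(g)
  }, numeric(1)))
  parent - child
}

## feature frame: 21 factor columns (nominal relation codes), named "ci_j"
cae_feature_frame <- function(encodings) {
  X <- t(vapply(encodings, cae_upper, integer(21)))
  out <- as.data.frame(lapply(as.data.frame(X), factor, levels = 0:5))
  names(out) <- paste0("c", colnames(X))
  out
}

## cells (column indices into the 21-vector) belonging to a piece subset
subset_cells <- function(pieces_in) {
  pr <- ut_pairs()
  which(pr[, 1] %in% pieces_in & pr[, 2] %in% pieces_in)
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- shuffle(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Classification efficiency across matrix granularity scales
#'
#' For each scale `s`, selects (per training fold, by summed Gini gain) the
#' most informative single s-piece submatrix, fits a CART decision tree on
#' its relation-code cells, and reports cross-validated accuracy. Scale 2
#' (one connection) is the local scale; scale 7 (full matrix) the global
#' scale. Chance is the majority-class frequency, which is robust to class
#' imbalance.
#'
#' @param encodings list of `cae_matrix` objects.
#' @param labels class label per encoding (>= 2 classes, >= 5 examples
#'   each).
#' @param scales integer scales in 2..7 (default local and global only).
#' @param cv_folds stratified cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @param max_depth CART depth cap.
#' @return object of class `granularity_profile`: list with `accuracy`
#'   (named by scale), `chance`, `per_figure` (out-of-fold true-class
#'   probability, figures x scales), `scales`, `n`.
#' @export
granularity_profile <- function(encodings, labels, scales = c(2L, 7L),
                                cv_folds = 5, seed = 1, max_depth = 12) {
  labels <- factor(labels)
  n <- length(encodings)
  stopifnot(n == length(labels))
  if (nlevels(labels) < 2) {
    stop("degenerate-target error: need at least 2 classes", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < cv_folds)) {
    stop("stratification error: every class needs at least cv_folds = ",
         cv_folds, " examples", call. = FALSE)
  }
  scales <- sort(unique(as.integer(scales)))
  stopifnot(all(scales >= 2 & scales <= 7))
  X <- cae_feature_frame(encodings)
  fold <- stratified_folds(labels, cv_folds, seed)
  chance <- max(counts) / n

  subsets_by_scale <- lapply(scales, function(s) {
    utils::combn(7, s, simplify = FALSE)
  })
  names(subsets_by_scale) <- as.character(scales)

  acc <- stats::setNames(numeric(length(scales)), as.character(scales))
  per_fig <- matrix(NA_real_, n, length(scales),
                    dimnames = list(names(encodings), as.character(scales)))
  correct <- matrix(NA, n, length(scales))

  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0.001,
                               minsplit = 5, minbucket = 2, xval = 0)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- !tr
    gains <- vapply(seq_len(21), function(c_i) {
      gini_gain(X[tr, c_i], labels[tr])
    }, numeric(1))
    for (si in seq_along(scales)) {
      subs <- subsets_by_scale[[si]]
      scores <- vapply(subs, function(p) sum(gains[subset_cells(p)]),
                       numeric(1))
      cells <- subset_cells(subs[[which.max(scores)]])
      df_tr <- cbind(.y = labels[tr], X[tr, cells, drop = FALSE])
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                          control = ctrl)
      pred <- predict(fit, X[te, cells, drop = FALSE], type = "class")
      prob <- predict(fit, X[te, cells, drop = FALSE], type = "prob")
      correct[te, si] <- pred == labels[te]
      per_fig[te, si] <- prob[cbind(seq_len(sum(te)),
                                    match(labels[te], colnames(prob)))]
    }
  }
  for (si in seq_along(scales)) acc[si] <- mean(correct[, si])
  structure(list(accuracy = acc, chance = chance, per_figure = per_fig,
                 scales = scales, n = n),
            class = "granularity_profile")
}

#' @export
print.granularity_profile <- function(x, ...) {
  cat("<granularity_profile> n =", x$n, " chance =",
      format(x$chance, digits = 3), "\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

lfd_share <- function(acc_local, acc_global, chance) {
  e_local <- max(0, acc_local - chance)
  g_global <- max(0, acc_global - acc_local)
  if (e_local + g_global == 0) return(0.5)
  e_local / (e_local + g_global)
}

#' Local feature density
#'
#' The share of cognitive discriminability contributed by local (single
#' connection) features: `lfd = eL / (eL + gG)` where `eL` is the
#' above-chance accuracy of the best single connection and `gG` the
#' *additional* accuracy gained by the full matrix beyond the local scale
#' (both floored at 0). Returns 0.5 when neither scale beats chance. High
#' values mean the figure's category is carried by individual connections;
#' low values mean it is carried by the global configuration.
#'
#' @param profile a `granularity_profile` containing scales 2 and 7.
#' @return scalar in \[0, 1\].
#' @export
lfd <- function(profile) {
  stopifnot(inherits(profile, "granularity_profile"))
  a <- profile$accuracy
  if (!all(c("2", "7") %in% names(a))) {
    stop("profile must contain the local (2) and global (7) scales",
         call. = FALSE)
  }
  lfd_share(a[["2"]], a[["7"]], profile$chance)
}

#' Per-figure local feature density
#'
#' Applies the [lfd()] share formula to each figure's out-of-fold true-class
#' probabilities at the local and global scales, giving a per-figure score.
#'
#' @param profile a `granularity_profile` containing scales 2 and 7.
#' @return numeric vector, one value in \[0, 1\] per figure.
#' @export
lfd_per_figure <- function(profile) {
  stopifnot(inherits(profile, "granularity_profile"))
  pf <- profile$per_figure
  if (!all(c("2", "7") %in% colnames(pf))) {
    stop("profile must contain the local (2) and global (7) scales",
         call. = FALSE)
  }
  vapply(seq_len(nrow(pf)), function(i) {
    lfd_share(pf[i, "2"], pf[i, "7"], profile$chance)
  }, numeric(1))
}

#' Local deviation index
#'
#' Absolute deviation of each figure's local feature density from the
#' central (median) value of the set.
#'
#' @param lfd_values numeric vector of per-figure LFD values (length >= 3).
#' @return numeric vector of nonnegative deviations.
#' @export
local_deviation <- function(lfd_values) {
  if (length(lfd_values) < 3) {
    stop("local_deviation needs at least 3 figures", call. = FALSE)
  }
  abs(lfd_values - stats::median(lfd_values))
}

#' Fit a decision tree for one representation dimension
#'
#' CART (Gini) classification of a labelled encoding set on the 21
#' upper-triangle relation cells; returns the fitted tree together with the
#' Gini importance of every cell, ranked, identifying the critical local
#' connections for the dimension.
#'
#' @param encodings list of `cae_matrix` objects.
#' @param target class label per encoding.
#' @param max_depth CART depth cap (default 4).
#' @param seed integer seed (cross-validation inside rpart is disabled, so
#'   the fit is deterministic; the seed is recorded for provenance).
#' @return list with `tree` (the rpart fit), `importance` (named, sorted,
#'   sums to 1 when any split occurs), `seed`.
#' @export
fit_dimension_tree <- function(encodings, target, max_depth = 4, seed = 1) {
  target <- factor(target)
  if (nlevels(target) < 2) {
    stop("degenerate-target error: target has a single class", call. = FALSE)
  }
  X <- cae_feature_frame(encodings)
  df <- cbind(.y = target, X)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0.001,
                               minsplit = 5, minbucket = 2, xval = 0)
  fit <- with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                      control = ctrl))
  imp <- stats::setNames(rep(0, 21), names(X))
  vi <- fit$variable.importance
  if (!is.null(vi) && sum(vi) > 0) imp[names(vi)] <- vi / sum(vi)
  list(tree = fit, importance = sort(imp, decreasing = TRUE), seed = seed)
}
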
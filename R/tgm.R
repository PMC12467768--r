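## Temporal generalization across familiarity and cluster-based inference.

#' Familiarity split of trials
#'
#' Default presentation-based split: unfamiliar = presentations 1-2,
#' familiar = presentations 4-5 (presentation 3, where reaction times have
#' just stabilized, is dropped). An RT-quantile split is available when the
#' metadata carries reaction times.
#'
#' @param meta trial metadata with `presentation` (and `rt` for the RT
#'   split).
#' @param method `"presentation"` or `"rt"`.
#' @return factor with levels `unfamiliar`, `familiar` (`NA` = dropped).
#' @export
familiarity_split <- function(meta, method = c("presentation", "rt")) {
  method <- match.arg(method)
  if (method == "presentation") {
    out <- ifelse(meta$presentation <= 2, "unfamiliar",
                  ifelse(meta$presentation >= 4, "familiar", NA))
  } else {
    stopifnot("rt" %in% names(meta))
    qs <- stats::quantile(meta$rt, c(1 / 3, 2 / 3), na.rm = TRUE)
    out <- ifelse(meta$rt >= qs[2], "unfamiliar",
                  ifelse(meta$rt <= qs[1], "familiar", NA))
  }
  factor(out, levels = c("unfamiliar", "familiar"))
}

#' Temporal generalization matrix
#'
#' Trains a shrinkage-LDA classifier at every timepoint on the training
#' split and tests it at every timepoint on the testing split. With
#' disjoint splits the classifier is trained once per train-timepoint; when
#' the splits share trials, stratified cross-validation is used and
#' accuracies are averaged across validation folds.
#'
#' @param epochs a single subject's `epoch_set`.
#' @param labels logical contrast per trial (`NA` dropped).
#' @param train_idx,test_idx trial indices (into the epoch set) of the two
#'   splits.
#' @param cv_folds folds used when the splits overlap.
#' @param seed integer seed.
#' @param shrinkage passed to [lda_shrink()].
#' @return object of class `tg_matrix`: list with `acc` (train-time x
#'   test-time), `times`, `chance`.
#' @export
temporal_generalization <- function(epochs, labels, train_idx, test_idx,
                                    cv_folds = 5, seed = 1,
                                    shrinkage = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  ok <- !is.na(labels)
  train_idx <- train_idx[ok[train_idx]]
  test_idx <- test_idx[ok[test_idx]]
  if (!length(train_idx) || !length(test_idx)) {
    stop("split error: empty familiarity split", call. = FALSE)
  }
  y_tr <- as.logical(labels[train_idx])
  y_te <- as.logical(labels[test_idx])
  if (length(unique(y_tr)) < 2) {
    stop("contrast error: training split has a single class", call. = FALSE)
  }
  data <- epochs$data
  n_t <- dim(data)[3]
  acc <- matrix(0, n_t, n_t)
  overlap <- length(intersect(train_idx, test_idx)) > 0
  if (!overlap) {
    for (t1 in seq_len(n_t)) {
      Xtr <- data[train_idx, , t1, drop = TRUE]
      if (is.null(dim(Xtr))) Xtr <- matrix(Xtr, ncol = dim(data)[2])
      fit <- lda_shrink(Xtr, y_tr, shrinkage = shrinkage)
      for (t2 in seq_len(n_t)) {
        Xte <- data[test_idx, , t2, drop = TRUE]
        if (is.null(dim(Xte))) Xte <- matrix(Xte, ncol = dim(data)[2])
        acc[t1, t2] <- mean(lda_predict(fit, Xte) == y_te)
      }
    }
  } else {
    fold <- stratified_folds(y_tr, cv_folds, seed)
    for (f in seq_len(cv_folds)) {
      tr <- train_idx[fold != f]
      te <- test_idx[test_idx %in% train_idx[fold == f]]
      if (!length(te)) next
      ytr <- as.logical(labels[tr]); yte <- as.logical(labels[te])
      for (t1 in seq_len(n_t)) {
        Xtr <- data[tr, , t1, drop = TRUE]
        if (is.null(dim(Xtr))) Xtr <- matrix(Xtr, ncol = dim(data)[2])
        fit <- lda_shrink(Xtr, ytr, shrinkage = shrinkage)
        for (t2 in seq_len(n_t)) {
          Xte <- data[te, , t2, drop = TRUE]
          if (is.null(dim(Xte))) Xte <- matrix(Xte, ncol = dim(data)[2])
          acc[t1, t2] <- acc[t1, t2] +
            mean(lda_predict(fit, Xte) == yte) / cv_folds
        }
      }
    }
  }
  structure(list(acc = acc, times = epochs$times, chance = 0.5),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat("<tg_matrix>", nrow(x$acc), "x", ncol(x$acc),
      "train x test timepoints\n")
  invisible(x)
}

## 4-connected component labeling of a logical matrix
label_clusters <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
                q[2] <= ncol(mask) && mask[q[1], q[2]] &&
                lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- cur
              queue[[length(queue) + 1]] <- q
            }
          }
        }
      }
    }
  }
  lab
}

cluster_masses <- function(tmap, thresh, sign) {
  mask <- if (sign > 0) tmap > thresh else tmap < -thresh
  lab <- label_clusters(mask)
  if (max(lab) == 0) return(list(masses = numeric(0), labels = lab))
  masses <- vapply(seq_len(max(lab)), function(k) {
    sum(abs(tmap[lab == k]))
  }, numeric(1))
  list(masses = masses, labels = lab)
}

#' Cluster-based permutation test for temporal generalization matrices
#'
#' One-sample test of subject TG matrices against chance: the t map across
#' subjects is thresholded (cluster-forming p = `p_thresh`, two-sided) and
#' 4-connected cluster masses are compared with a sign-flip permutation
#' null (maximum cluster mass). Above- and below-chance clusters are tested
#' separately.
#'
#' @param tgms list of `tg_matrix` objects (one per subject).
#' @param n_perm sign-flip permutations.
#' @param p_thresh cluster-forming p value.
#' @param alpha cluster-level significance level.
#' @param seed integer seed.
#' @return list with `tmap`, `pos_mask`, `neg_mask` (significant cluster
#'   cells), and `clusters` (sign, mass, p per candidate cluster).
#' @export
tgm_cluster_test <- function(tgms, n_perm = 1000, p_thresh = 0.05,
                             alpha = 0.05, seed = 1) {
  stopifnot(length(tgms) >= 2)
  arr <- simplify2array(lapply(tgms, function(m) m$acc - m$chance))
  n_sub <- dim(arr)[3]
  thresh <- stats::qt(1 - p_thresh / 2, df = n_sub - 1)
  tmap_of <- function(a) {
    mu <- apply(a, c(1, 2), mean)
    sdv <- apply(a, c(1, 2), stats::sd)
    sdv[sdv == 0] <- Inf
    mu / (sdv / sqrt(n_sub))
  }
  tmap <- tmap_of(arr)
  pos <- cluster_masses(tmap, thresh, +1)
  neg <- cluster_masses(tmap, thresh, -1)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      flips <- sample(c(-1, 1), n_sub, replace = TRUE)
      a <- sweep(arr, 3, flips, `*`)
      tm <- tmap_of(a)
      m <- c(cluster_masses(tm, thresh, +1)$masses,
             cluster_masses(tm, thresh, -1)$masses)
      if (length(m)) max(m) else 0
    }, numeric(1))
  })
  cluster_p <- function(mass) (sum(null_max >= mass) + 1) / (n_perm + 1)
  rows <- list()
  pos_mask <- matrix(FALSE, nrow(tmap), ncol(tmap))
  neg_mask <- matrix(FALSE, nrow(tmap), ncol(tmap))
  for (k in seq_along(pos$masses)) {
    pk <- cluster_p(pos$masses[k])
    rows[[length(rows) + 1]] <- data.frame(sign = "above", cluster = k,
                                           mass = pos$masses[k], p = pk)
    if (pk <= alpha) pos_mask[pos$labels == k] <- TRUE
  }
  for (k in seq_along(neg$masses)) {
    pk <- cluster_p(neg$masses[k])
    rows[[length(rows) + 1]] <- data.frame(sign = "below", cluster = k,
                                           mass = neg$masses[k], p = pk)
    if (pk <= alpha) neg_mask[neg$labels == k] <- TRUE
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(0), cluster = integer(0),
               mass = numeric(0), p = numeric(0))
  list(tmap = tmap, pos_mask = pos_mask, neg_mask = neg_mask,
       clusters = clusters)
}

#' Above/below-diagonal mass of a TG contrast
#'
#' Summarizes where significant generalization sits relative to the
#' diagonal: training-time later than testing-time cells sit above the
#' diagonal (slower processing in the training split).
#'
#' @param mask logical train x test matrix (e.g. `pos_mask`).
#' @return list with `above`, `below`, `on` cell counts.
#' @export
diagonal_mass <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(above = sum(idx[, 1] > idx[, 2]), below = sum(idx[, 1] < idx[, 2]),
       on = sum(idx[, 1] == idx[, 2]))
}
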
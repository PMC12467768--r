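## Time-resolved multivariate decoding with shrinkage-regularized LDA.

#' Fit a shrinkage-regularized LDA discriminant
#'
#' Two-class linear discriminant with analytic (Ledoit-Wolf style)
#' shrinkage of the pooled covariance toward a scaled identity; the
#' shrinkage intensity is estimated from the data unless given.
#'
#' @param X numeric matrix (observations x features).
#' @param y logical class vector.
#' @param shrinkage `NULL` (analytic estimate) or a fixed value in \[0, 1\].
#' @return list with `w` (discriminant vector), `b` (threshold),
#'   `shrinkage`.
#' @export
lda_shrink <- function(X, y, shrinkage = NULL) {
  y <- as.logical(y)
  n <- nrow(X)
  stopifnot(n == length(y), any(y), any(!y))
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2, m1)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2, m0)
  S <- crossprod(Xc) / (n - 2)
  nu <- mean(diag(S))
  if (is.null(shrinkage)) {
    ## Schafer-Strimmer analytic intensity for the scaled-identity target
    W2 <- crossprod(Xc^2) / (n - 2)  # E[w^2] per entry, approx
    var_s <- (W2 - S^2) * (n / ((n - 1) * (n - 2)))
    target <- diag(nu, ncol(X))
    denom <- sum((S - target)^2)
    shrinkage <- if (denom <= 0) 1 else min(1, max(0, sum(var_s) / denom))
  }
  S_sh <- (1 - shrinkage) * S + shrinkage * diag(nu, ncol(X))
  w <- tryCatch(solve(S_sh, m1 - m0),
                error = function(e) {
                  solve(S_sh + diag(1e-8 * max(nu, 1e-12), ncol(X)),
                        m1 - m0)
                })
  list(w = w, b = sum(w * (m1 + m0)) / 2, shrinkage = shrinkage)
}

lda_predict <- function(fit, X) as.numeric(X %*% fit$w) > fit$b

#' Time-resolved pairwise decoding of one contrast
#'
#' At every timepoint, a shrinkage-LDA classifier on the channel vectors is
#' evaluated with stratified k-fold cross-validation; accuracy is the mean
#' over held-out trials (chance 0.5) and the channel weights are the
#' fold-averaged discriminant vectors.
#'
#' @param epochs a single subject's `epoch_set`.
#' @param labels logical vector, one per trial (`NA` trials are dropped).
#' @param cv_folds stratified folds.
#' @param seed integer seed (fold assignment).
#' @param shrinkage passed to [lda_shrink()].
#' @return object of class `decoding_curve`: list with `times`, `accuracy`,
#'   `weights` (channels x time), `chance` (0.5), `n_folds`, `n_trials`.
#' @export
decode_timecourse <- function(epochs, labels, cv_folds = 5, seed = 1,
                              shrinkage = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- !is.na(labels)
  labels <- as.logical(labels[keep])
  data <- epochs$data[keep, , , drop = FALSE]
  if (length(unique(labels)) < 2) {
    stop("contrast error: both classes must be present", call. = FALSE)
  }
  if (min(table(labels)) < cv_folds) {
    stop("contrast error: each class needs at least cv_folds trials",
         call. = FALSE)
  }
  fold <- stratified_folds(labels, cv_folds, seed)
  n_t <- dim(data)[3]
  acc <- numeric(n_t)
  W <- matrix(0, dim(data)[2], n_t)
  A <- matrix(0, dim(data)[2], n_t)
  for (ti in seq_len(n_t)) {
    X <- data[, , ti, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = dim(data)[2])
    correct <- logical(length(labels))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- lda_shrink(X[tr, , drop = FALSE], labels[tr],
                        shrinkage = shrinkage)
      correct[!tr] <- lda_predict(fit, X[!tr, , drop = FALSE]) ==
        labels[!tr]
      W[, ti] <- W[, ti] + fit$w / cv_folds
    }
    acc[ti] <- mean(correct)
    ## forward-model activation pattern: data covariance times the
    ## discriminant (interpretable channel topography)
    Xc <- sweep(X, 2, colMeans(X))
    A[, ti] <- crossprod(Xc) %*% W[, ti] / (nrow(X) - 1)
  }
  structure(list(times = epochs$times, accuracy = acc, weights = W,
                 patterns = A, chance = 0.5, n_folds = cv_folds,
                 n_trials = length(labels)),
            class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat("<decoding_curve>", length(x$times), "timepoints; peak accuracy",
      format(max(x$accuracy), digits = 3), "at",
      format(x$times[which.max(x$accuracy)], digits = 3), "s\n")
  invisible(x)
}

#' Tertile-pair contrast labels with covariate control
#'
#' Builds high-vs-low labels for one dimension and optionally equalizes the
#' composition of non-target dimensions across the two classes by
#' subsampling within covariate cells.
#'
#' @param epochs an `epoch_set` (its metadata must carry `figure_id`).
#' @param stim_table stimulus records.
#' @param dimension column of `stim_table`: logical columns give a binary
#'   contrast, numeric columns a high-vs-low tertile contrast.
#' @param covariates optional character vector of numeric columns whose
#'   tertile composition is equalized across classes by subsampling.
#' @param seed integer seed for the subsampling.
#' @return logical vector per trial (`NA` = excluded).
#' @export
contrast_labels <- function(epochs, stim_table, dimension,
                            covariates = NULL, seed = 1) {
  v <- stim_table[[dimension]]
  if (is.null(v)) stop("unknown dimension column: ", dimension,
                       call. = FALSE)
  per_fig <- if (is.logical(v)) {
    ifelse(v, "high", "low")
  } else {
    as.character(tertile_assign(v))
  }
  fig_lab <- stats::setNames(per_fig, stim_table$figure_id)
  lab_chr <- fig_lab[epochs$meta$figure_id]
  labels <- ifelse(lab_chr == "high", TRUE,
                   ifelse(lab_chr == "low", FALSE, NA))
  if (!is.null(covariates)) {
    cells <- interaction(lapply(covariates, function(cv) {
      tertile_assign(stim_table[[cv]])[match(epochs$meta$figure_id,
                                             stim_table$figure_id)]
    }), drop = TRUE)
    labels <- with_seed(seed, {
      for (cl in levels(cells)) {
        in_cell <- which(!is.na(labels) & cells == cl)
        n1 <- sum(labels[in_cell]); n0 <- sum(!labels[in_cell])
        if (n1 == n0) next
        over <- in_cell[labels[in_cell] == (n1 > n0)]
        drop_n <- abs(n1 - n0)
        labels[over[sample.int(length(over), drop_n)]] <- NA
      }
      labels
    })
  }
  labels
}

#' Group-level significance of decoding curves
#'
#' One-sample Wilcoxon signed-rank tests against the chance level at every
#' timepoint across subjects, BH-FDR corrected over timepoints.
#'
#' @param curves list of `decoding_curve` objects (one per subject) or a
#'   subjects x time accuracy matrix.
#' @param chance chance level (default 0.5).
#' @param q FDR level.
#' @param alternative test sidedness (default `"two.sided"`).
#' @return list with `times` (if available), `mean`, `se`, `p`, `p_fdr`,
#'   `mask` (logical, `p_fdr <= q`).
#' @export
decode_group_test <- function(curves, chance = 0.5, q = 0.05,
                              alternative = "two.sided") {
  if (is.list(curves) && inherits(curves[[1]], "decoding_curve")) {
    acc <- do.call(rbind, lapply(curves, `[[`, "accuracy"))
    times <- curves[[1]]$times
  } else {
    acc <- as.matrix(curves)
    times <- NULL
  }
  p <- apply(acc, 2, function(v) {
    if (stats::sd(v) == 0) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = chance,
                                        alternative = alternative)$p.value)
  })
  p_fdr <- stats::p.adjust(p, method = "BH")
  list(times = times, mean = colMeans(acc),
       se = apply(acc, 2, stats::sd) / sqrt(nrow(acc)),
       p = p, p_fdr = p_fdr, mask = p_fdr <= q)
}

#' Image-level pairwise decoding (neural RDM input)
#'
#' For every unordered image pair and timepoint, cross-validated
#' shrinkage-LDA accuracy with folds grouped by presentation cycle so that
#' trials of one image never straddle the train/test split. Pairs lacking
#' usable trials are imputed by the row/column mean and flagged.
#'
#' @param epochs a single subject's `epoch_set` (metadata needs
#'   `figure_id`, `presentation`).
#' @param image_ids images to include (default: all in the metadata).
#' @param seed integer seed.
#' @param shrinkage passed to [lda_shrink()].
#' @return object of class `rdm_series`: list with `d` (n x n x time
#'   dissimilarity array, accuracy scale), `ids`, `times`, `imputed`
#'   (logical n x n).
#' @export
decode_pairwise_images <- function(epochs, image_ids = NULL, seed = 1,
                                   shrinkage = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            all(c("figure_id", "presentation") %in% names(epochs$meta)))
  if (is.null(image_ids)) image_ids <- unique(epochs$meta$figure_id)
  n <- length(image_ids)
  n_t <- dim(epochs$data)[3]
  D <- array(0, dim = c(n, n, n_t),
             dimnames = list(image_ids, image_ids, NULL))
  imputed <- matrix(FALSE, n, n, dimnames = list(image_ids, image_ids))
  trials_of <- lapply(image_ids, function(im) {
    which(epochs$meta$figure_id == im)
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- trials_of[[i]]; tj <- trials_of[[j]]
      if (length(ti) < 2 || length(tj) < 2) {
        imputed[i, j] <- imputed[j, i] <- TRUE
        D[i, j, ] <- D[j, i, ] <- NA
        next
      }
      idx <- c(ti, tj)
      y <- rep(c(TRUE, FALSE), c(length(ti), length(tj)))
      ## fold = presentation cycle, so an image's trials stay together
      pres <- epochs$meta$presentation[idx]
      folds <- as.integer(factor(pres))
      usable <- length(unique(folds)) >= 2
      if (!usable) {
        imputed[i, j] <- imputed[j, i] <- TRUE
        D[i, j, ] <- D[j, i, ] <- NA
        next
      }
      for (tt in seq_len(n_t)) {
        X <- epochs$data[idx, , tt, drop = TRUE]
        if (is.null(dim(X))) X <- matrix(X, ncol = dim(epochs$data)[2])
        correct <- rep(NA, length(y))
        for (f in unique(folds)) {
          tr <- folds != f
          if (length(unique(y[tr])) < 2) next
          fit <- lda_shrink(X[tr, , drop = FALSE], y[tr],
                            shrinkage = shrinkage)
          correct[!tr] <- lda_predict(fit, X[!tr, , drop = FALSE]) == y[!tr]
        }
        acc <- mean(correct, na.rm = TRUE)
        D[i, j, tt] <- D[j, i, tt] <- acc
      }
    }
  }
  ## impute flagged pairs by the row/column mean at each timepoint
  if (any(imputed)) {
    for (tt in seq_len(n_t)) {
      sl <- D[, , tt]
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i != j && is.na(sl[i, j])) {
            fill <- mean(c(sl[i, ], sl[, j]), na.rm = TRUE)
            sl[i, j] <- if (is.finite(fill)) fill else 0.5
          }
        }
      }
      D[, , tt] <- sl
    }
  }
  structure(list(d = D, ids = image_ids, times = epochs$times,
                 imputed = imputed),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat("<rdm_series>", length(x$ids), "stimuli x", dim(x$d)[3],
      "timepoints\n")
  invisible(x)
}
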
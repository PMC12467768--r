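## Representational similarity analysis: candidate model RDMs,
## time-resolved GLM, model-space MDS and stimulus embeddings.

model_rdm <- function(name, m, imputed = NULL) {
  m <- as.matrix(m)
  diag(m) <- 0
  structure(list(name = name, d = m, imputed = imputed),
            class = "model_rdm")
}

#' @export
print.model_rdm <- function(x, ...) {
  cat("<model_rdm>", x$name, ":", nrow(x$d), "x", ncol(x$d), "\n")
  invisible(x)
}

jaccard_distance <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Build the six candidate model RDMs
#'
#' Semantic models: animacy and object level are same/different (0/1) on
#' the binary animacy label and the nine-group assignment; abstraction is
#' the absolute score difference. Feature models: local feature density is
#' the absolute score difference, feature level the Jaccard distance
#' between part-tag sets, and connections the encoding distance
#' ([cae_distance()]). Stimuli without an encoding (e.g. natural-image
#' controls) get connections entries imputed at the maximum observed
#' distance and flagged.
#'
#' @param stim_table stimulus records (`figure_id`, `animacy_binary`,
#'   `abstraction`, `lfd`, and `group_index` for the object-level model).
#' @param encodings named list of `cae_matrix` objects (missing ids are
#'   imputed and flagged).
#' @param part_tags named list of character vectors of part tags per
#'   figure (for the feature-level model).
#' @return named list of six `model_rdm` objects in the order animacy,
#'   abstraction, lfd, object_level, feature_level, connections.
#' @export
build_model_rdms <- function(stim_table, encodings = NULL,
                             part_tags = NULL) {
  ids <- stim_table$figure_id
  n <- length(ids)
  same_diff <- function(v) outer(v, v, FUN = "!=") * 1
  abs_diff <- function(v) abs(outer(v, v, FUN = "-"))
  out <- list()
  out$animacy <- model_rdm("animacy", same_diff(stim_table$animacy_binary))
  out$abstraction <- model_rdm("abstraction",
                               abs_diff(stim_table$abstraction))
  out$lfd <- model_rdm("lfd", abs_diff(stim_table$lfd))
  if (!is.null(stim_table$group_index)) {
    out$object_level <- model_rdm("object_level",
                                  same_diff(stim_table$group_index))
  }
  if (!is.null(part_tags)) {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- jaccard_distance(part_tags[[ids[i]]],
                                               part_tags[[ids[j]]])
      }
    }
    out$feature_level <- model_rdm("feature_level", m)
  }
  if (!is.null(encodings)) {
    have <- ids %in% names(encodings)
    m <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (have[i] && have[j]) {
          m[i, j] <- m[j, i] <- cae_distance(encodings[[ids[i]]],
                                             encodings[[ids[j]]])
        }
      }
    }
    imputed <- is.na(m); diag(imputed) <- FALSE
    if (any(imputed)) m[is.na(m)] <- max(m, na.rm = TRUE)
    diag(m) <- 0
    out$connections <- model_rdm("connections", m, imputed = imputed)
  }
  for (nm in names(out)) dimnames(out[[nm]]$d) <- list(ids, ids)
  out
}

#' Model-space MDS
#'
#' Model-model distance is one minus the Pearson correlation of the
#' lower-triangle entries; classical MDS projects the models to 2-D.
#'
#' @param models list of `model_rdm` objects (>= 3).
#' @return list with `coords` (models x 2) and `dist` (model distance
#'   matrix).
#' @export
model_space_mds <- function(models) {
  stopifnot(length(models) >= 3)
  V <- vapply(models, function(m) lower_tri_vec(m$d),
              numeric(sum(lower.tri(models[[1]]$d))))
  colnames(V) <- vapply(models, `[[`, character(1), "name")
  D <- 1 - stats::cor(V)
  coords <- suppressWarnings(stats::cmdscale(D, k = 2))
  while (ncol(coords) < 2) coords <- cbind(coords, 0)
  rownames(coords) <- colnames(V)
  list(coords = coords, dist = D)
}

## Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Time-resolved GLM of neural RDMs on candidate models
#'
#' For every subject and timepoint, the z-scored lower triangle of the
#' neural RDM is regressed (ordinary least squares, intercept included) on
#' the z-scored model predictors. Group statistics are computed on the
#' across-subject betas: mean, SE, Wilcoxon signed-rank p versus zero,
#' BH-FDR corrected over timepoints within each model.
#'
#' @param neural list of `rdm_series`, one per subject, sharing stimulus
#'   order.
#' @param models list of `model_rdm` objects with the same stimulus order.
#' @param q FDR level.
#' @param scale_neural `"center"` (default; betas keep the neural
#'   dissimilarity scale, so a planted `2 x model` series recovers beta 2)
#'   or `"z"` (response z-scored per timepoint).
#' @return object of class `beta_series`: list with `times`, `models`,
#'   `beta` (subjects x models x time), `mean`, `se`, `p`, `p_fdr`, `mask`.
#' @export
timewise_glm <- function(neural, models, q = 0.05,
                         scale_neural = c("center", "z")) {
  scale_neural <- match.arg(scale_neural)
  stopifnot(length(neural) >= 1, length(models) >= 1)
  ids <- neural[[1]]$ids
  for (nr in neural) stopifnot(identical(nr$ids, ids))
  mnames <- vapply(models, `[[`, character(1), "name")
  Z <- vapply(models, function(m) {
    stopifnot(all(rownames(m$d) == ids))
    zscore(lower_tri_vec(m$d))
  }, numeric(length(lower_tri_vec(models[[1]]$d))))
  X <- cbind(intercept = 1, Z)
  ## collinearity check
  sv <- svd(scale(Z, scale = FALSE))$d
  if (min(sv) < 1e-8 * max(sv)) {
    warning("condition-number warning: model predictors are collinear; ",
            "using a pseudo-inverse fit", call. = FALSE)
  }
  Xp <- pinv(X)
  n_t <- dim(neural[[1]]$d)[3]
  n_m <- length(models)
  n_s <- length(neural)
  beta <- array(NA_real_, dim = c(n_s, n_m, n_t),
                dimnames = list(names(neural), mnames, NULL))
  for (s in seq_len(n_s)) {
    Y <- vapply(seq_len(n_t), function(tt) {
      v <- lower_tri_vec(neural[[s]]$d[, , tt])
      if (scale_neural == "z") zscore(v) else v - mean(v)
    }, numeric(nrow(X)))
    B <- Xp %*% Y
    beta[s, , ] <- B[-1, , drop = FALSE]
  }
  mean_b <- apply(beta, c(2, 3), mean)
  se_b <- apply(beta, c(2, 3), stats::sd) / sqrt(n_s)
  p <- matrix(1, n_m, n_t, dimnames = list(mnames, NULL))
  if (n_s >= 2) {
    for (m in seq_len(n_m)) {
      for (tt in seq_len(n_t)) {
        v <- beta[, m, tt]
        if (stats::sd(v) > 0) {
          p[m, tt] <- suppressWarnings(
            stats::wilcox.test(v, mu = 0)$p.value)
        }
      }
    }
  }
  ## joint BH correction over models x timepoints
  p_fdr <- matrix(stats::p.adjust(p, method = "BH"), n_m, n_t,
                  dimnames = dimnames(p))
  structure(list(times = neural[[1]]$times, models = mnames, beta = beta,
                 mean = mean_b, se = se_b, p = p, p_fdr = p_fdr,
                 mask = p_fdr <= q),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("<beta_series>", length(x$models), "models x", ncol(x$mean),
      "timepoints x", dim(x$beta)[1], "subjects\n")
  invisible(x)
}

#' Peak latency per model of a beta series
#'
#' @param bs a `beta_series`.
#' @return named numeric vector of peak times (seconds) of the group-mean
#'   betas.
#' @export
beta_peak_latencies <- function(bs) {
  stopifnot(inherits(bs, "beta_series"))
  stats::setNames(bs$times[apply(bs$mean, 1, which.max)], bs$models)
}

## ---- stimulus embeddings -------------------------------------------------

## exact t-SNE (small n): perplexity-calibrated affinities + momentum
## gradient descent
tsne_embed <- function(D, k = 2, perplexity = 10, seed = 1,
                       n_iter = 400, momentum = 0.8, eta = 50) {
  n <- nrow(D)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D[i, -i]^2
    lo <- 1e-10; hi <- 1e10
    for (it in 1:60) {
      beta <- sqrt(lo * hi)
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw <= 0) { hi <- beta; next }
      pr <- w / sw
      H <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      if (H > target) lo <- beta else hi <- beta
    }
    P[i, -i] <- pr
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * k, sd = 1e-3), n, k)
    V <- matrix(0, n, k)
    for (iter in seq_len(n_iter)) {
      ex <- if (iter <= 100) 4 else 1
      Dy2 <- as.matrix(stats::dist(Y))^2
      Q_num <- 1 / (1 + Dy2)
      diag(Q_num) <- 0
      Q <- pmax(Q_num / sum(Q_num), 1e-12)
      L <- (ex * P - Q) * Q_num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      V <- momentum * V - eta * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

## fraction of low-dimensional neighbors that are truthful to the
## high-dimensional ranks (standard trustworthiness score)
trustworthiness <- function(D, Y, k = 5) {
  n <- nrow(D)
  k <- min(k, n - 2)
  Dy <- as.matrix(stats::dist(Y))
  penalty <- 0
  for (i in seq_len(n)) {
    rank_high <- rank(D[i, -i], ties.method = "first")
    names(rank_high) <- setdiff(seq_len(n), i)
    low_nn <- order(Dy[i, -i])[seq_len(k)]
    low_ids <- setdiff(seq_len(n), i)[low_nn]
    r <- rank_high[as.character(low_ids)]
    penalty <- penalty + sum(pmax(0, r - k))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' Embed stimuli from a neural RDM
#'
#' @param D stimulus dissimilarity matrix (e.g. the mean neural RDM at one
#'   timepoint).
#' @param method `"mds"` (classical) or `"tsne"` (exact t-SNE with
#'   perplexity-calibrated affinities).
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity.
#' @return list with `coords` (n x 2), `method`, `trustworthiness`.
#' @export
stimulus_embedding <- function(D, method = c("mds", "tsne"), seed = 1,
                               perplexity = 10) {
  method <- match.arg(method)
  D <- as.matrix(D)
  coords <- if (method == "mds") {
    X <- suppressWarnings(stats::cmdscale(D, k = 2))
    while (ncol(X) < 2) X <- cbind(X, 0)
    X
  } else {
    tsne_embed(D, k = 2, perplexity = perplexity, seed = seed)
  }
  rownames(coords) <- rownames(D)
  list(coords = coords, method = method,
       trustworthiness = trustworthiness(D, coords))
}

#' Average an RDM series across subjects
#'
#' @param neural list of `rdm_series` with a shared stimulus order.
#' @return an `rdm_series` holding the element-wise mean.
#' @export
mean_rdm_series <- function(neural) {
  ids <- neural[[1]]$ids
  for (nr in neural) stopifnot(identical(nr$ids, ids))
  arr <- simplify2array(lapply(neural, `[[`, "d"))
  structure(list(d = apply(arr, c(1, 2, 3), mean), ids = ids,
                 times = neural[[1]]$times, imputed = NULL),
            class = "rdm_series")
}

#' Neural RDM at (or averaged around) one time
#'
#' @param rdms an `rdm_series`.
#' @param at time in seconds.
#' @param halfwidth seconds averaged on each side.
#' @return n x n dissimilarity matrix.
#' @export
rdm_at <- function(rdms, at, halfwidth = 0) {
  idx <- which(abs(rdms$times - at) <= halfwidth + 1e-9)
  if (!length(idx)) idx <- which.min(abs(rdms$times - at))
  sl <- rdms$d[, , idx, drop = FALSE]
  apply(sl, c(1, 2), mean)
}
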
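## Distance between encodings, MDS embedding, animacy-separability test.

## The two large triangles and the two small triangles are physically
## identical, so their labels are arbitrary; distances minimize over the
## 2 x 2 = 4 relabelings of these pairs (a group, which preserves the
## triangle inequality of the underlying normalized L1 metric).
identical_piece_permutations <- function() {
  base <- 1:7
  swaps <- list(c(), c(1, 2), c(4, 5), c(1, 2, 4, 5))
  lapply(swaps, function(s) {
    p <- base
    if (length(s) >= 2) { p[s[1]] <- s[2]; p[s[2]] <- s[1] }
    if (length(s) == 4) { p[s[3]] <- s[4]; p[s[4]] <- s[3] }
    p
  })
}

#' Distance between two cognitive-associative encodings
#'
#' Normalized L1 distance over the 21 upper-triangle relation codes,
#' minimized over the four relabelings of the two identical-piece pairs
#' (large-triangle pair, small-triangle pair):
#' `d = min_pi sum_{i<j} |m1[i,j] - m2[pi(i),pi(j)]| / 21`, so `d` lies in
#' `[0, 5]`.
#'
#' @param m1,m2 `cae_matrix` objects (or plain 7 x 7 matrices).
#' @return nonnegative scalar distance.
#' @export
cae_distance <- function(m1, m2) {
  m1 <- unclass(cae_matrix(m1)); m2 <- unclass(cae_matrix(m2))
  ut <- upper.tri(m1)
  min(vapply(identical_piece_permutations(), function(p) {
    sum(abs(m1[ut] - m2[p, p][ut]))
  }, numeric(1))) / 21
}

#' Pairwise encoding distance matrix
#'
#' @param encodings named list of `cae_matrix` objects.
#' @return symmetric matrix of [cae_distance()] values with figure ids as
#'   dimnames.
#' @export
cae_distance_matrix <- function(encodings) {
  n <- length(encodings)
  ids <- names(encodings)
  if (is.null(ids)) ids <- paste0("fig", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- cae_distance(encodings[[i]], encodings[[j]])
    }
  }
  D
}

## one SMACOF majorization run from a given start configuration
smacof_run <- function(D, X, max_iter = 300, eps = 1e-8) {
  n <- nrow(D)
  W <- 1 - diag(n)
  denom <- sum(W * D^2)
  if (denom == 0) return(list(X = X * 0, stress = 0))
  stress_of <- function(X) {
    d <- as.matrix(stats::dist(X))
    sqrt(sum(W * (D - d)^2) / denom)
  }
  s_old <- stress_of(X)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(X))
    ratio <- ifelse(d > 1e-12, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s_new <- stress_of(X)
    if (s_old - s_new < eps) break
    s_old <- s_new
  }
  list(X = X, stress = stress_of(X))
}

#' Metric MDS embedding of an encoding distance matrix
#'
#' Metric (stress-minimizing, SMACOF majorization) multidimensional scaling
#' with several random restarts, or classical Torgerson scaling
#' (`kind = "classical"`). Stress is normalized Kruskal stress-1.
#'
#' @param D symmetric distance matrix.
#' @param k embedding dimensionality (default 2).
#' @param seed integer seed controlling the random restarts.
#' @param kind `"metric"` (default) or `"classical"`.
#' @param n_restarts random restarts for the metric flavor.
#' @return object of class `cae_embedding`: list with `points` (n x k,
#'   rownames preserved), `stress`, `k`, `kind`.
#' @export
mds_embed <- function(D, k = 2, seed = 1, kind = c("metric", "classical"),
                      n_restarts = 8) {
  kind <- match.arg(kind)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dimension error: D must be square",
                               call. = FALSE)
  n <- nrow(D)
  if (n < k + 1) {
    stop("insufficient-points error: need at least k + 1 = ", k + 1,
         " points for a ", k, "-dimensional embedding", call. = FALSE)
  }
  if (kind == "classical") {
    X <- stats::cmdscale(D, k = k)
    if (ncol(X) < k) X <- cbind(X, matrix(0, n, k - ncol(X)))
    d <- as.matrix(stats::dist(X))
    denom <- sum(D^2)
    stress <- if (denom == 0) 0 else sqrt(sum((D - d)^2) / denom)
  } else {
    best <- NULL
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
    ## first start from the classical solution, then random restarts
    X0 <- tryCatch({
      Xc <- suppressWarnings(stats::cmdscale(D, k = k))
      if (ncol(Xc) < k) Xc <- cbind(Xc, matrix(0, n, k - ncol(Xc)))
      Xc
    }, error = function(e) matrix(stats::rnorm(n * k), n, k))
    starts <- c(list(X0), replicate(max(0, n_restarts - 1),
      matrix(stats::rnorm(n * k), n, k) * max(D), simplify = FALSE))
    for (X in starts) {
      run <- smacof_run(D, X)
      if (is.null(best) || run$stress < best$stress) best <- run
    }
    X <- best$X
    stress <- best$stress
  }
  rownames(X) <- rownames(D)
  colnames(X) <- paste0("dim", seq_len(k))
  structure(list(points = X, stress = stress, k = k, kind = kind),
            class = "cae_embedding")
}

#' @export
print.cae_embedding <- function(x, ...) {
  cat("<cae_embedding>", nrow(x$points), "points in", x$k,
      "dimensions; stress =", format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' Write / read a distance matrix CSV (figure-id header row and column)
#'
#' @param D distance matrix with dimnames.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_distance_csv <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write an embedding CSV (`figure_id, dim1..dimk`)
#'
#' @param emb a `cae_embedding`.
#' @param path file path.
#' @export
write_embedding_csv <- function(emb, path) {
  stopifnot(inherits(emb, "cae_embedding"))
  df <- data.frame(figure_id = rownames(emb$points), emb$points,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Test linear separability of a binary label in an embedding
#'
#' Runs a pooled-variance two-sample Student t test of the label groups along
#' each embedding axis and reports the axis with the largest |t| together
#' with its two-sided p value (degrees of freedom n - 2).
#'
#' @param emb a `cae_embedding` (or plain n x k coordinate matrix).
#' @param labels logical/binary vector, one per embedded point.
#' @return list with `t`, `p`, `axis`, `df`, and the per-axis statistics in
#'   `by_axis`.
#' @export
separability_test <- function(emb, labels) {
  X <- if (inherits(emb, "cae_embedding")) emb$points else as.matrix(emb)
  labels <- as.logical(labels)
  if (length(labels) != nrow(X)) stop("labels must match embedded points",
                                      call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("undefined-contrast error: both label groups must be present",
         call. = FALSE)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  df <- n1 + n0 - 2
  stats_axis <- apply(X, 2, function(v) {
    x1 <- v[labels]; x0 <- v[!labels]
    sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    if (se == 0) {
      t <- 0
    } else {
      t <- (mean(x1) - mean(x0)) / se
    }
    c(t = t, p = 2 * stats::pt(-abs(t), df))
  })
  t_vals <- stats_axis["t", ]
  p_vals <- stats_axis["p", ]
  p_vals[t_vals == 0] <- 1
  axis <- which.max(abs(t_vals))
  list(t = unname(t_vals[axis]), p = unname(p_vals[axis]),
       axis = unname(axis), df = df,
       by_axis = data.frame(axis = seq_along(t_vals), t = unname(t_vals),
                            p = unname(p_vals)))
}
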
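## Small shared helpers.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## evaluate `expr` under a local seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

## locate a shipped data file (works from the installed package and, for
## development, from a source checkout)
pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tangramcae")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

## derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

lower_tri_vec <- function(m) m[lower.tri(m)]

## length-safe permutation (sample(x) on a length-1 integer permutes 1:x)
shuffle <- function(x) x[sample.int(length(x))]

## mean silhouette width for a binary/label split of a distance matrix
silhouette_mean <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.character(labels)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
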
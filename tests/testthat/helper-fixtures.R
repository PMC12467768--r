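# Shared fixtures and small utilities for the suite.

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# right triangle / square / parallelogram constructors in test coordinates
tri <- function(id, x, y, leg = 1, rot = 0) {
  v <- rbind(c(0, 0), c(leg, 0), c(0, leg))
  if (rot != 0) {
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    v <- v %*% t(R)
  }
  v[, 1] <- v[, 1] + x; v[, 2] <- v[, 2] + y
  piece(id, v)
}

sq <- function(x, y, side = 1) {
  piece("square", rbind(c(x, y), c(x + side, y), c(x + side, y + side),
                        c(x, y + side)))
}

# a labelled pool of random two-piece configurations built from the
# generator's own snapping primitives plus free placements
random_pair_config <- function() {
  ids <- sample(tangramcae:::PIECE_IDS, 2)
  code <- sample(0:5, 1)
  pa <- tangramcae:::child_base(ids[1])
  rot <- matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2, 2)
  pa <- pa %*% t(tangramcae:::rot2(runif(1, 0, 2 * pi)))
  if (code == 0) {
    pb <- tangramcae:::child_base(ids[2]) %*%
      t(tangramcae:::rot2(runif(1, 0, 2 * pi)))
    pb[, 1] <- pb[, 1] + runif(1, 6, 9)
    pb[, 2] <- pb[, 2] + runif(1, -2, 2)
    return(list(a = piece(ids[1], pa), b = piece(ids[2], pb), code = 0L))
  }
  if (code == 1 && !tangramcae:::code1_feasible(ids[1], ids[2])) {
    return(NULL)
  }
  combos <- tangramcae:::enumerate_combos(pa, ids[2], code)
  for (cb in sample(combos)) {
    pb <- tangramcae:::realize_combo(pa, ids[2], code, cb)
    if (is.null(pb)) next
    ok <- tryCatch(
      classify_relationship(piece(ids[1], pa), piece(ids[2], pb)) == code,
      error = function(e) FALSE)
    if (ok) return(list(a = piece(ids[1], pa), b = piece(ids[2], pb),
                        code = as.integer(code)))
  }
  NULL
}

# small stimulus table used across decoding / RSA / behavior tests
make_stim_table <- function(n = 20, seed = 11) {
  withr::with_seed(seed, {
    data.frame(figure_id = sprintf("f%02d", seq_len(n)),
               animacy_binary = rep(c(TRUE, FALSE), length.out = n),
               abstraction = runif(n), lfd = runif(n),
               group_index = rep(1:9, length.out = n))
  })
}

# encodings with one informative cell: label = (cell (1,3) == 3)
make_single_cell_dataset <- function(n = 240, seed = 21) {
  withr::with_seed(seed, {
    encs <- lapply(seq_len(n), function(i) {
      m <- matrix(0L, 7, 7)
      # random sparse background relations
      for (k in sample(21, 4)) {
        pr <- tangramcae:::ut_pairs()[k, ]
        m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- sample(0:5, 1)
      }
      m[1, 3] <- m[3, 1] <- if (i %% 2 == 0) 3L else
        sample(c(0L, 1L, 2L, 4L, 5L), 1)
      cae_matrix(m)
    })
    labels <- vapply(encs, function(m) unclass(m)[1, 3] == 3L, logical(1))
    list(encodings = encs, labels = labels)
  })
}

# encodings with a global existence rule: label = any cell has code 1
make_global_rule_dataset <- function(n = 240, seed = 22, q = 0.0325) {
  withr::with_seed(seed, {
    encs <- lapply(seq_len(n), function(i) {
      m <- matrix(0L, 7, 7)
      pr <- tangramcae:::ut_pairs()
      for (k in seq_len(21)) {
        code <- if (runif(1) < q) 1L else sample(c(0L, 2L, 3L, 4L, 5L), 1)
        m[pr[k, 1], pr[k, 2]] <- m[pr[k, 2], pr[k, 1]] <- code
      }
      cae_matrix(m)
    })
    labels <- vapply(encs, function(m) any(cae_upper(m) == 1L), logical(1))
    list(encodings = encs, labels = labels)
  })
}

# null-calibration run: pure-noise epochs for n_sub subjects, decoded on a
# random binary contrast; returns the subjects x time accuracy matrix
null_decode_run <- function(seed, n_sub = 24, n_trials = 24, n_ch = 8,
                            n_t = 20) {
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, n_sub))
  acc <- matrix(NA_real_, n_sub, n_t)
  for (s in seq_len(n_sub)) {
    withr::with_seed(seeds[s], {
      data <- array(rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t))
      labels <- rep(c(TRUE, FALSE), length.out = n_trials)
      es <- epoch_set(data, seq(0, by = 0.04, length.out = n_t),
                      sprintf("ch%02d", seq_len(n_ch)),
                      data.frame(figure_id = sprintf("f%02d",
                                                     seq_len(n_trials)),
                                 presentation = 1L))
      acc[s, ] <- decode_timecourse(es, labels, cv_folds = 4,
                                    seed = seeds[s])$accuracy
    })
  }
  acc
}
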
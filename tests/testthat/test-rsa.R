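# Model RDMs, time-resolved GLM and stimulus embeddings.

make_model_set <- function(n = 30, seed = 531) {
  withr::with_seed(seed, {
    stim <- make_stim_table(n)
    gf <- gen_figures(sim_figure_spec(seed = seed), n)
    names(gf$encodings) <- stim$figure_id
    tags <- setNames(lapply(seq_len(n), function(i) {
      sample(c("head", "leg", "wing", "roof", "base"), sample(1:3, 1))
    }), stim$figure_id)
    list(stim = stim,
         models = build_model_rdms(stim, gf$encodings, tags),
         encodings = gf$encodings)
  })
}

rdm_series_from <- function(D_by_time, ids, times) {
  arr <- array(0, dim = c(length(ids), length(ids), length(times)))
  for (tt in seq_along(times)) arr[, , tt] <- D_by_time[[tt]]
  structure(list(d = arr, ids = ids, times = times), class = "rdm_series")
}

vec_to_rdm <- function(v, n) {
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- v
  M + t(M)
}

test_that("the six model RDMs have their defining properties", {
  ms <- make_model_set()
  expect_setequal(names(ms$models),
                  c("animacy", "abstraction", "lfd", "object_level",
                    "feature_level", "connections"))
  for (m in ms$models) {
    expect_equal(m$d, t(m$d))
    expect_true(all(diag(m$d) == 0))
  }
  expect_true(all(ms$models$animacy$d %in% c(0, 1)))
  expect_true(all(ms$models$object_level$d %in% c(0, 1)))
  # connections model equals the encoding distance matrix
  D <- cae_distance_matrix(ms$encodings)
  expect_equal(unname(ms$models$connections$d), unname(D))
  # identical stimuli pair -> all model entries zero (diagonal)
  expect_true(all(vapply(ms$models, function(m) all(diag(m$d) == 0),
                         logical(1))))
})

test_that("missing encodings are imputed at the maximum and flagged", {
  ms <- make_model_set(n = 12)
  encs <- ms$encodings[-(1:3)]
  mods <- build_model_rdms(ms$stim, encs, NULL)
  conn <- mods$connections
  expect_true(all(conn$imputed[1:3, 4:12]))
  expect_equal(unique(conn$d[1, 4:12]), max(conn$d))
})

test_that("model-space MDS separates a model from its negation", {
  ms <- make_model_set()
  neg <- ms$models$abstraction
  neg$d <- max(neg$d) - neg$d
  diag(neg$d) <- 0
  neg$name <- "neg_abstraction"
  mm <- model_space_mds(c(ms$models, list(neg)))
  expect_equal(mm$dist["abstraction", "neg_abstraction"], 2,
               tolerance = 1e-10)
  expect_equal(mm$dist["abstraction", "abstraction"], 0, tolerance = 1e-10)
  # orthogonalized random models sit near distance 1
  set.seed(532)
  n <- 30
  rand_models <- lapply(1:4, function(k) {
    v <- rnorm(n * (n - 1) / 2)
    tangramcae:::model_rdm(paste0("rand", k), vec_to_rdm(abs(v), n))
  })
  mmr <- model_space_mds(rand_models)
  off <- mmr$dist[upper.tri(mmr$dist)]
  expect_true(all(abs(off - 1) < 0.35))
})

test_that("exact OLS: a noiseless scaled model recovers its coefficient", {
  ms <- make_model_set(n = 20)
  n <- 20
  Z <- zscore(tangramcae:::lower_tri_vec(ms$models$animacy$d))
  times <- c(0.1, 0.2)
  neural <- list(s1 = rdm_series_from(
    list(vec_to_rdm(2 * Z, n), vec_to_rdm(2 * Z, n)),
    ms$stim$figure_id, times))
  bs <- timewise_glm(neural, ms$models)
  expect_equal(unname(bs$beta["s1", "animacy", 1]), 2, tolerance = 1e-8)
  expect_lt(max(abs(bs$beta["s1", setdiff(bs$models, "animacy"), ])), 0.3)
})

test_that("planted beta time courses are recovered with the right order", {
  ms <- make_model_set(n = 40, seed = 533)
  n <- 40
  times <- seq(0, 1, by = 0.025)
  shapes <- list(connections = c(0.16, 0.4), feature_level = c(0.22, 0.3),
                 lfd = c(0.25, 0.3), abstraction = c(0.2, 0.3),
                 animacy = c(0.45, 0.4), object_level = c(0.5, 0.2))
  Zs <- vapply(ms$models[names(shapes)], function(m) {
    zscore(tangramcae:::lower_tri_vec(m$d))
  }, numeric(n * (n - 1) / 2))
  true_b <- vapply(times, function(t) {
    vapply(shapes, function(s) s[2] * exp(-(t - s[1])^2 / (2 * 0.05^2)),
           numeric(1))
  }, numeric(length(shapes)))
  set.seed(534)
  neural <- lapply(1:12, function(s) {
    rdm_series_from(lapply(seq_along(times), function(tt) {
      vec_to_rdm(as.numeric(Zs %*% true_b[, tt]) +
                   rnorm(nrow(Zs), 0, 0.5), n)
    }), ms$stim$figure_id, times)
  })
  bs <- timewise_glm(neural, ms$models[names(shapes)])
  rmse <- sqrt(mean((bs$mean - true_b)^2))
  expect_lt(rmse, 0.1)
  pk <- beta_peak_latencies(bs)
  expect_lt(pk[["connections"]], pk[["animacy"]])
  # the planted windows are flagged significant
  expect_true(any(bs$mask["connections", times > 0.1 & times < 0.25]))
  expect_true(any(bs$mask["animacy", times > 0.35 & times < 0.55]))
})

test_that("pure-noise RDM series keep the FDR mask empty", {
  ms <- make_model_set(n = 20, seed = 535)
  n <- 20
  times <- seq_len(15)
  set.seed(536)
  n_hit <- 0
  for (run in 1:40) {
    neural <- lapply(1:10, function(s) {
      rdm_series_from(lapply(times, function(tt) {
        vec_to_rdm(abs(rnorm(n * (n - 1) / 2)), n)
      }), ms$stim$figure_id, times)
    })
    bs <- timewise_glm(neural, ms$models)
    if (any(bs$mask)) n_hit <- n_hit + 1
  }
  expect_lte(n_hit, 4)  # <= 10% of null runs at q = 0.05
})

test_that("collinear models trigger the condition-number warning", {
  ms <- make_model_set(n = 15, seed = 537)
  dup <- ms$models$animacy
  dup$name <- "animacy_copy"
  neural <- list(s1 = rdm_series_from(
    list(vec_to_rdm(abs(rnorm(15 * 14 / 2)), 15)),
    ms$stim$figure_id, 0.1))
  expect_warning(timewise_glm(neural, list(ms$models$animacy, dup)),
                 "condition-number")
})

test_that("stimulus embeddings preserve planted cluster structure", {
  set.seed(538)
  n <- 24
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  D <- matrix(1, n, n)
  D[lab, lab] <- 0.5; D[!lab, !lab] <- 0.5
  diag(D) <- 0
  D <- D + matrix(runif(n * n, 0, 0.05), n); D <- (D + t(D)) / 2
  diag(D) <- 0
  for (method in c("mds", "tsne")) {
    em <- stimulus_embedding(D, method, seed = 4)
    sil <- tangramcae:::silhouette_mean(as.matrix(dist(em$coords)), lab)
    expect_gt(sil, 0.4)
    expect_identical(dim(em$coords), c(as.integer(n), 2L))
  }
  # identical rows embed to coincident points under classical MDS
  D0 <- matrix(0, 5, 5)
  em0 <- stimulus_embedding(D0, "mds")
  expect_lt(max(dist(em0$coords)), 1e-8)
  # three-point metric reproduced up to stress tolerance
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  em3 <- stimulus_embedding(D3, "mds")
  expect_equal(as.numeric(dist(em3$coords)), c(3, 4, 5), tolerance = 0.01)
  # t-SNE is deterministic per seed
  e1 <- stimulus_embedding(D, "tsne", seed = 9)
  e2 <- stimulus_embedding(D, "tsne", seed = 9)
  expect_identical(e1$coords, e2$coords)
})
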
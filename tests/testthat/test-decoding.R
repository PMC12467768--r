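# Time-resolved decoding: recovery, calibration, image-level RDMs.

make_decoding_sim <- function(n_subjects = 6, n_images = 16,
                              effect = 1.2, latencies = c(0.45),
                              dims = c("animacy_binary"),
                              topo_seeds = c(42), sfreq = 50,
                              n_channels = 12, seed = 501, ...) {
  stim <- make_stim_table(n_images)
  comps <- mapply(function(d, l, ts) {
    sim_component(d, latency = l, duration = 0.05, effect_size = effect,
                  topography_seed = ts)
  }, dims, latencies, topo_seeds, SIMPLIFY = FALSE)
  spec <- sim_eeg_spec(n_channels = n_channels, sfreq = sfreq,
                       components = comps, spatial_rank = 6, seed = seed,
                       ...)
  list(stim = stim, epochs = gen_epochs_multi(spec, stim, n_subjects))
}

test_that("planted components are recovered at their latencies", {
  sim <- make_decoding_sim(n_subjects = 12, effect = 1.5)
  curves <- lapply(sim$epochs, function(e) {
    decode_timecourse(e, contrast_labels(e, sim$stim, "animacy_binary"),
                      seed = 7)
  })
  gt <- decode_group_test(curves)
  peak_t <- gt$times[which.max(gt$mean)]
  expect_lt(abs(peak_t - 0.45), 0.06)
  # significant cluster overlaps the planted window
  sig_times <- gt$times[gt$mask]
  expect_true(any(sig_times > 0.35 & sig_times < 0.55))
  # pre-stimulus accuracies sit at chance
  pre <- gt$mean[gt$times < 0]
  expect_lt(abs(mean(pre) - 0.5), 0.03)
  # no significant pre-stimulus timepoint
  expect_false(any(gt$mask[gt$times < -0.05]))
})

test_that("group-averaged activation patterns recover the topography", {
  sim <- make_decoding_sim(n_subjects = 12, effect = 1.5)
  curves <- lapply(sim$epochs, function(e) {
    decode_timecourse(e, contrast_labels(e, sim$stim, "animacy_binary"),
                      seed = 7)
  })
  gt <- decode_group_test(curves)
  pk <- which.max(gt$mean)
  mean_pattern <- rowMeans(vapply(curves, function(cv) cv$patterns[, pk],
                                  numeric(12)))
  planted <- tangramcae:::random_topography(12, 42)
  expect_gt(cosine_sim(mean_pattern, planted), 0.8)
})

test_that("label shuffling yields no significant timepoints", {
  sim <- make_decoding_sim(n_subjects = 6, effect = 1.2, seed = 502)
  curves <- lapply(seq_along(sim$epochs), function(s) {
    e <- sim$epochs[[s]]
    lab <- contrast_labels(e, sim$stim, "animacy_binary")
    lab <- withr::with_seed(600 + s, sample(lab))
    decode_timecourse(e, lab, seed = 7)
  })
  gt <- decode_group_test(curves)
  expect_false(any(gt$mask))
})

test_that("covariate control balances non-target tertiles", {
  stim <- make_stim_table(30)
  spec <- sim_eeg_spec(n_channels = 6, sfreq = 20, seed = 503)
  ep <- gen_epochs(spec, stim, trial_schedule(stim$figure_id, 3, seed = 2))
  lab <- contrast_labels(ep, stim, "abstraction", covariates = "lfd",
                         seed = 4)
  cells <- tertile_assign(stim$lfd)[match(ep$meta$figure_id,
                                          stim$figure_id)]
  for (cl in levels(cells)) {
    sel <- !is.na(lab) & cells == cl
    expect_equal(sum(lab[sel]), sum(!lab[sel]))
  }
})

test_that("image-level pairwise decoding produces valid RDM series", {
  stim <- make_stim_table(8)
  spec <- sim_eeg_spec(n_channels = 10, sfreq = 25, tmin = -0.2,
                       tmax = 0.8, baseline = c(-0.2, -0.05),
                       components = list(
                         sim_component("image", latency = 0.3,
                                       duration = 0.06,
                                       effect_size = 2.5)),
                       spatial_rank = 5, seed = 504)
  ep <- gen_epochs(spec, stim, trial_schedule(stim$figure_id, 4, seed = 3))
  rdm <- decode_pairwise_images(ep, seed = 5)
  # symmetry, zero diagonal
  for (tt in c(1, dim(rdm$d)[3])) {
    expect_equal(rdm$d[, , tt], t(rdm$d[, , tt]))
    expect_true(all(diag(rdm$d[, , tt]) == 0))
  }
  # orthogonal planted image patterns: high accuracy at the signal latency
  sig_idx <- which.min(abs(rdm$times - 0.3))
  off <- rdm$d[, , sig_idx][lower.tri(matrix(0, 8, 8))]
  expect_gt(mean(off), 0.8)
  # pre-stimulus pairs hover at chance
  pre_idx <- which(rdm$times < -0.05)
  pre_vals <- apply(rdm$d[, , pre_idx, drop = FALSE], 3, function(m) {
    mean(m[lower.tri(m)])
  })
  expect_lt(abs(mean(pre_vals) - 0.5), 0.05)
})

test_that("images with too few trials are imputed and flagged", {
  stim <- make_stim_table(6)
  spec <- sim_eeg_spec(n_channels = 6, sfreq = 20, tmin = -0.2, tmax = 0.6,
                       baseline = c(-0.2, -0.05), seed = 505)
  sched <- trial_schedule(stim$figure_id, 3, seed = 2)
  ep <- gen_epochs(spec, stim, sched)
  # drop all but one trial of the first image
  drop <- which(ep$meta$figure_id == stim$figure_id[1])[-1]
  keep <- setdiff(seq_len(nrow(ep$meta)), drop)
  ep2 <- epoch_set(ep$data[keep, , , drop = FALSE], ep$times, ep$channels,
                   ep$meta[keep, , drop = FALSE])
  rdm <- decode_pairwise_images(ep2, image_ids = stim$figure_id, seed = 5)
  expect_true(all(rdm$imputed[1, -1]))
  expect_false(any(rdm$imputed[-1, -1]))
  expect_true(all(is.finite(rdm$d)))
})

test_that("lda_shrink separates planted means and tolerates p > n", {
  set.seed(506)
  n <- 30; p <- 40
  mu <- c(rep(2, 5), rep(0, p - 5))
  X <- rbind(matrix(rnorm(n / 2 * p), n / 2) + rep(mu, each = n / 2),
             matrix(rnorm(n / 2 * p), n / 2))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  fit <- lda_shrink(X, y)
  expect_gte(fit$shrinkage, 0)
  expect_lte(fit$shrinkage, 1)
  expect_gt(mean(lda_predict(fit, X) == y), 0.9)
})
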
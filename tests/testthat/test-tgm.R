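# Temporal generalization and cluster-based permutation inference.

make_tgm_sim <- function(n_subjects = 8, latency_shift = 0,
                         components = NULL, seed = 521) {
  stim <- make_stim_table(12)
  if (is.null(components)) {
    components <- list(sim_component("animacy_binary", latency = 0.2,
                                     duration = 0.06, effect_size = 1.5,
                                     topography_seed = 42))
  }
  spec <- sim_eeg_spec(n_channels = 10, sfreq = 40, tmin = -0.1,
                       tmax = 0.7, baseline = c(-0.1, -0.02),
                       components = components, spatial_rank = 5,
                       familiarity_latency_shift = latency_shift,
                       seed = seed)
  list(stim = stim, epochs = gen_epochs_multi(spec, stim, n_subjects))
}

subject_tgms <- function(sim, train = "familiar", test = "unfamiliar") {
  lapply(sim$epochs, function(e) {
    lab <- contrast_labels(e, sim$stim, "animacy_binary")
    fam <- familiarity_split(e$meta)
    temporal_generalization(e, lab, which(fam == train),
                            which(fam == test), seed = 3)
  })
}

test_that("familiarity split drops the transition presentation", {
  meta <- data.frame(presentation = 1:5)
  fam <- familiarity_split(meta)
  expect_identical(as.character(fam),
                   c("unfamiliar", "unfamiliar", NA, "familiar",
                     "familiar"))
  # RT split: fast trials are familiar
  meta2 <- data.frame(presentation = 1:9, rt = seq(0.4, 2, length.out = 9))
  fam2 <- familiarity_split(meta2, method = "rt")
  expect_true(all(fam2[meta2$rt <= 0.8] == "familiar", na.rm = TRUE))
})

test_that("a sustained code generalizes as a significant square block", {
  sim <- make_tgm_sim(components = list(
    sim_component("animacy_binary", latency = 0.35, duration = 0.18,
                  effect_size = 1.5, topography_seed = 42)))
  tgms <- subject_tgms(sim)
  ct <- tgm_cluster_test(tgms, n_perm = 300, seed = 5)
  times <- tgms[[1]]$times
  in_win <- times > 0.2 & times < 0.55
  block <- ct$pos_mask[in_win, in_win]
  expect_gt(mean(block), 0.6)
  # accuracy inside the block is far above chance
  mean_acc <- Reduce(`+`, lapply(tgms, `[[`, "acc")) / length(tgms)
  expect_gt(mean(mean_acc[in_win, in_win]), 0.7)
})

test_that("a planted latency delay in the training split shifts mass above the diagonal", {
  sim <- make_tgm_sim(latency_shift = 0.04)  # +0.12 s familiar vs unfamiliar
  tgms <- subject_tgms(sim, train = "familiar", test = "unfamiliar")
  ct <- tgm_cluster_test(tgms, n_perm = 300, seed = 6)
  dm <- diagonal_mass(ct$pos_mask)
  expect_gt(dm$above, 2 * max(1, dm$below))
})

test_that("a planted pattern inversion produces below-chance generalization", {
  # negative effect sizes are rejected by the constructor; the inversion is
  # planted by pairing the same topography with the inverted label
  expect_error(sim_component("x", 0.5, effect_size = -1), "effect_size")
  stim <- make_stim_table(12)
  stim$anti <- !stim$animacy_binary
  spec <- sim_eeg_spec(n_channels = 10, sfreq = 40, tmin = -0.1,
                       tmax = 0.7, baseline = c(-0.1, -0.02),
                       components = list(
                         sim_component("animacy_binary", latency = 0.15,
                                       duration = 0.05, effect_size = 1.5,
                                       topography_seed = 42),
                         sim_component("anti", latency = 0.5,
                                       duration = 0.05, effect_size = 1.5,
                                       topography_seed = 42)),
                       spatial_rank = 5, seed = 522)
  eps <- gen_epochs_multi(spec, stim, 8)
  tgms <- lapply(eps, function(e) {
    lab <- contrast_labels(e, stim, "animacy_binary")
    idx <- which(!is.na(lab))
    temporal_generalization(e, lab, idx, idx, seed = 3)
  })
  ct <- tgm_cluster_test(tgms, n_perm = 300, seed = 7)
  times <- tgms[[1]]$times
  early <- times > 0.1 & times < 0.2
  late <- times > 0.45 & times < 0.55
  # train early, test late (and vice versa) flips the sign of the code
  expect_gt(mean(ct$neg_mask[early, late]) + mean(ct$neg_mask[late, early]),
            0.3)
  expect_gt(mean(ct$pos_mask[early, early]), 0.3)
})

test_that("self-generalization diagonal matches time-resolved decoding", {
  sim <- make_tgm_sim(n_subjects = 2)
  e <- sim$epochs[[1]]
  lab <- contrast_labels(e, sim$stim, "animacy_binary")
  idx <- which(!is.na(lab))
  tg <- temporal_generalization(e, lab, idx, idx, cv_folds = 5, seed = 3)
  dc <- decode_timecourse(e, lab, cv_folds = 5, seed = 3)
  # same folds, same classifier: the diagonal equals the decoding curve up
  # to fold-weighting noise
  expect_lt(mean(abs(diag(tg$acc) - dc$accuracy)), 0.06)
})

test_that("empty splits and single-class training are rejected", {
  sim <- make_tgm_sim(n_subjects = 1)
  e <- sim$epochs[[1]]
  lab <- contrast_labels(e, sim$stim, "animacy_binary")
  expect_error(temporal_generalization(e, lab, integer(0), seq_len(10)),
               "split error")
  one_class <- which(lab)[1:6]
  expect_error(temporal_generalization(e, lab, one_class, which(!lab)),
               "single class")
})
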
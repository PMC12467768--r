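# Normalized-RT statistics, repetition effects and change-of-mind detection.

make_behavior_sim <- function(n_images = 48, n_subjects = 20, seed = 541,
                              ...) {
  stim <- make_stim_table(n_images)
  stim$local_deviation <- local_deviation(stim$lfd)
  beh <- gen_behavior(sim_behavior_spec(seed = seed, ...), stim,
                      n_subjects = n_subjects)
  list(stim = stim, trials = beh)
}

test_that("normalized RT is a per-subject z of log RT", {
  sim <- make_behavior_sim(n_images = 24, n_subjects = 6)
  tr <- normalize_rt(sim$trials)
  means <- tapply(tr$normalized_rt, tr$subject, mean)
  sds <- tapply(tr$normalized_rt, tr$subject, sd)
  expect_lt(max(abs(means)), 1e-12)
  expect_lt(max(abs(sds - 1)), 1e-12)
  # constant RTs are guarded to zero
  const <- data.frame(subject = "s", rt = rep(1, 20))
  expect_identical(unique(normalize_rt(const)$normalized_rt), 0)
  # a planted log-shift appears in normalized units (base spec without
  # dimension effects, so the two image halves start equal)
  flat <- make_behavior_sim(n_images = 24, n_subjects = 6, seed = 542,
                            abstraction_effect = 0, animacy_effect = 0,
                            lfd_effect = 0, deviation_effect = 0,
                            rep_delta = 0, com_frac = 0)
  tr2 <- flat$trials
  cond <- tr2$figure_id %in% flat$stim$figure_id[1:12]
  tr2$rt[cond] <- tr2$rt[cond] * exp(0.3)
  tr2 <- normalize_rt(tr2)
  gap <- mean(tr2$normalized_rt[cond]) - mean(tr2$normalized_rt[!cond])
  sd_post <- mean(tapply(log(tr2$rt), tr2$subject, sd))
  expect_equal(gap, 0.3 / sd_post, tolerance = 0.15)
})

test_that("dimension tests recover the planted directions", {
  sim <- make_behavior_sim()
  tr <- normalize_rt(exclude_trials(sim$trials))
  dt <- dimension_rt_tests(tr, sim$stim)
  expect_setequal(dt$dimension,
                  c("abstraction", "animacy", "lfd", "local_deviation"))
  expect_true(all(dt$p_fdr < 0.05))
  # abstract images slower; animals, salient features, deviants faster
  expect_gt(dt$direction[dt$dimension == "abstraction"], 0)
  expect_lt(dt$direction[dt$dimension == "animacy"], 0)
  expect_lt(dt$direction[dt$dimension == "lfd"], 0)
  expect_lt(dt$direction[dt$dimension == "local_deviation"], 0)
})

test_that("identical groups give a non-significant Wilcoxon result", {
  sim <- make_behavior_sim(n_images = 24, n_subjects = 8,
                           abstraction_effect = 0, animacy_effect = 0,
                           lfd_effect = 0, deviation_effect = 0,
                           rep_delta = 0, com_frac = 0)
  tr <- normalize_rt(sim$trials)
  dt <- dimension_rt_tests(tr, sim$stim)
  expect_true(all(dt$p_fdr > 0.05))
})

test_that("repetition effects stabilize at the third presentation", {
  sim <- make_behavior_sim(n_subjects = 24)
  tr <- normalize_rt(sim$trials)
  rc <- repetition_curve(tr)
  sig <- rc$adjacent_tests$p_fdr < 0.05
  expect_identical(rc$adjacent_tests$pair, c("1v2", "2v3", "3v4", "4v5"))
  expect_true(all(sig[1:2]))
  expect_false(any(sig[3:4]))
  expect_lt(rc$correlation$r, 0)
  expect_lt(rc$correlation$p, 0.001)
  # curve means decrease then flatten
  expect_gt(rc$curve$mean[1], rc$curve$mean[3])
})

test_that("change-of-mind sequences are classified by the single-transition rule", {
  base <- data.frame(subject = "s01", presentation = 1:5)
  seqs <- list(
    list(resp = c("non-animal", "non-animal", "animal", "animal",
                  "animal"), flag = TRUE, dir = "activation", at = 3L),
    list(resp = rep("animal", 5), flag = FALSE),
    list(resp = c("non-animal", "animal", "non-animal", "animal",
                  "non-animal"), flag = FALSE),
    list(resp = c("animal", "animal", "animal", "animal", "non-animal"),
         flag = TRUE, dir = "suppression", at = 5L))
  trials <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    cbind(base, figure_id = paste0("f", i), response = seqs[[i]]$resp)
  }))
  res <- detect_change_of_mind(trials)
  flagged <- vapply(seqs, `[[`, logical(1), "flag")
  expect_setequal(res$records$figure_id, paste0("f", which(flagged)))
  expect_identical(res$records$direction[res$records$figure_id == "f1"],
                   "activation")
  expect_identical(res$records$transition_index[
    res$records$figure_id == "f1"], 3L)
  expect_identical(res$records$direction[res$records$figure_id == "f4"],
                   "suppression")
})

test_that("the detector has perfect precision and recall on planted data", {
  sim <- make_behavior_sim(n_images = 60, n_subjects = 16,
                           com_frac = 0.115, multi_transition_frac = 0.1)
  res <- detect_change_of_mind(sim$trials)
  planted <- attr(sim$trials, "com_images")
  detected <- unique(res$records$figure_id)
  expect_setequal(detected, planted)        # precision = recall = 1
  expect_equal(res$fraction, length(planted) / 60, tolerance = 0.02)
  # direction bookkeeping agrees with the planted directions
  dirs <- attr(sim$trials, "com_direction")
  got <- unique(res$records[, c("figure_id", "direction")])
  expect_identical(unname(dirs[got$figure_id]), got$direction)
})

test_that("subject-image pairs with one presentation are skipped", {
  trials <- data.frame(subject = "s01", figure_id = c("a", "a", "b"),
                       presentation = c(1, 2, 1),
                       response = c("animal", "non-animal", "animal"))
  res <- detect_change_of_mind(trials)
  expect_identical(res$skipped, 1L)
  expect_identical(res$records$figure_id, "a")
})
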
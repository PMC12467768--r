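# Annotation-derived scores, granularity profiles, LFD and curation.

test_that("animacy score counts animate head nouns", {
  a <- suppressWarnings(annotation_set("x", c("dog", "cat", "bird", "dancer")))
  expect_equal(suppressWarnings(animacy_score(a)), 1)
  b <- suppressWarnings(annotation_set("y", c("house", "bridge")))
  expect_equal(suppressWarnings(animacy_score(b)), 0)
  c6 <- annotation_set("z", c(rep("dog", 6), rep("kite", 4)))
  expect_equal(suppressWarnings(animacy_score(c6)), 0.6)
  # canonicalization: head noun, case, plural
  d <- suppressWarnings(annotation_set("w", c("Two Dogs", "a running horse")))
  expect_equal(suppressWarnings(animacy_score(d)), 1)
})

test_that("abstraction level is normalized label entropy", {
  expect_equal(abstraction_level(annotation_set("a", rep("dog", 10))), 0)
  expect_equal(abstraction_level(
    annotation_set("b", paste0("label", letters[1:10]))), 1)
  # counts (5, 3, 2): H = 1.0297 nats over log(10)
  ab <- abstraction_level(
    annotation_set("c", rep(c("dog", "cat", "hat"), c(5, 3, 2))))
  expect_equal(ab, 0.4472, tolerance = 1e-4)
  # merging two distinct labels never increases entropy
  merged <- abstraction_level(
    annotation_set("d", rep(c("dog", "dog", "hat"), c(5, 3, 2))))
  expect_lte(merged, ab)
  # order invariance
  ab2 <- abstraction_level(
    annotation_set("e", sample(rep(c("dog", "cat", "hat"), c(5, 3, 2)))))
  expect_equal(ab2, ab)
  expect_error(suppressWarnings(abstraction_level(annotation_set("f", "dog"))),
               "insufficient-annotations")
})

test_that("granularity profile finds planted local rules at the local scale", {
  ds <- make_single_cell_dataset(n = 200)
  prof <- granularity_profile(ds$encodings, ds$labels, seed = 5)
  expect_gte(prof$accuracy[["2"]], 0.95)
  expect_true(all(prof$accuracy >= prof$chance - 0.1))
  expect_true(all(prof$accuracy <= 1))
})

test_that("labels independent of encodings decode at chance", {
  ds <- make_single_cell_dataset(n = 160)
  set.seed(9)
  shuffled <- sample(ds$labels)
  prof <- granularity_profile(ds$encodings, shuffled, seed = 5)
  # binomial CI around the majority-class chance level
  ci <- 3 * sqrt(0.25 / 160)
  expect_lt(abs(prof$accuracy[["2"]] - prof$chance), ci + 0.05)
  expect_lt(abs(prof$accuracy[["7"]] - prof$chance), ci + 0.05)
})

test_that("lfd separates local-rule from global-rule datasets", {
  local_ds <- make_single_cell_dataset(n = 240)
  prof_l <- granularity_profile(local_ds$encodings, local_ds$labels,
                                seed = 5)
  expect_gt(lfd(prof_l), 0.8)

  global_ds <- make_global_rule_dataset(n = 400)
  prof_g <- granularity_profile(global_ds$encodings, global_ds$labels,
                                seed = 5)
  expect_gt(prof_g$accuracy[["7"]], prof_g$accuracy[["2"]] + 0.1)
  expect_lt(lfd(prof_g), 0.2)

  # per-figure values stay in [0, 1] and are invariant to class relabeling
  pf <- lfd_per_figure(prof_l)
  expect_true(all(pf >= 0 & pf <= 1))
  prof_flip <- granularity_profile(local_ds$encodings, !local_ds$labels,
                                   seed = 5)
  expect_equal(lfd(prof_flip), lfd(prof_l), tolerance = 0.1)
})

test_that("granularity profile validates its inputs", {
  ds <- make_single_cell_dataset(n = 40)
  expect_error(granularity_profile(ds$encodings, rep(TRUE, 40)),
               "degenerate-target")
  lab <- ds$labels; lab[1:38] <- TRUE; lab[39:40] <- FALSE
  expect_error(granularity_profile(ds$encodings, lab, cv_folds = 5),
               "stratification")
})

test_that("local deviation is the absolute offset from the median", {
  expect_equal(local_deviation(c(0.1, 0.5, 0.9)), c(0.4, 0, 0.4))
  expect_equal(local_deviation(rep(0.3, 5)), rep(0, 5))
  x <- c(0.2, 0.5, 0.8)
  d1 <- local_deviation(x)
  # adding a figure at the median leaves the others unchanged
  d2 <- local_deviation(c(x, 0.5))
  expect_equal(d2[1:3], d1)
  expect_error(local_deviation(c(0.1, 0.2)), "at least 3")
})

test_that("dimension trees recover planted critical connections", {
  ds <- make_single_cell_dataset(n = 200)
  fit <- fit_dimension_tree(ds$encodings, ds$labels, seed = 3)
  expect_identical(names(fit$importance)[1], "c1_3")
  expect_equal(sum(fit$importance), 1)

  # pure-noise target: no importance beyond the permutation null
  set.seed(33)
  noise_lab <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  fit0 <- fit_dimension_tree(ds$encodings, noise_lab, seed = 3)
  null_top <- vapply(1:40, function(i) {
    set.seed(400 + i)
    f <- fit_dimension_tree(ds$encodings, sample(noise_lab), seed = 3)
    max(f$importance)
  }, numeric(1))
  expect_lte(max(fit0$importance), quantile(null_top, 0.95) + 0.15)

  expect_error(fit_dimension_tree(ds$encodings, rep(TRUE, 200)),
               "degenerate-target")
})

test_that("stimulus selection fills tertile cells evenly", {
  set.seed(77)
  n <- 360
  pool <- data.frame(figure_id = sprintf("p%03d", 1:n),
                     animacy_score = runif(n),
                     animacy_binary = runif(n) > 0.5,
                     abstraction = runif(n), lfd = runif(n))
  sel <- select_stimuli(pool, n_target = 90, seed = 5)
  expect_identical(nrow(sel$selected), 90L)
  # marginal tertile distributions near-uniform
  for (col in c("abs_tertile", "lfd_tertile")) {
    counts <- table(sel$selected[[col]])
    expect_lte(diff(range(counts)), 1)
  }
  expect_true(all(sel$selected$group_index %in% 1:9))
  # group ordering is the display ordering
  expect_true(!is.unsorted(sel$selected$group_index))
  # determinism
  sel2 <- select_stimuli(pool, n_target = 90, seed = 5)
  expect_identical(sel$selected$figure_id, sel2$selected$figure_id)

  # pool exactly n_target: everything selected
  small <- pool[1:18, ]
  sel3 <- suppressWarnings(select_stimuli(small, n_target = 18, seed = 1,
                                          exclude_extreme = 0))
  expect_setequal(sel3$selected$figure_id, small$figure_id)
})

test_that("annotations CSV round trips", {
  anns <- gen_annotations(c("f1", "f2"), c(0.9, 0.1), c(0.3, 0.8),
                          seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(anns, path)
  back <- read_annotations_csv(path)
  expect_setequal(names(back), c("f1", "f2"))
  expect_equal(suppressWarnings(animacy_score(back$f1)),
               suppressWarnings(animacy_score(anns$f1)))
  expect_equal(abstraction_level(back$f2), abstraction_level(anns$f2))
})
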
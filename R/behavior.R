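## Normalized-RT analyses across representation dimensions and repetitions,
## and change-of-mind detection.

#' Exclude invalid trials
#'
#' Removes trials with excessively fast (< `fast` s) or slow (> `slow` s)
#' responses, multiple key presses, or premature responses; every removed
#' row is logged with its reason.
#'
#' @param trials behavioral trial table with `rt` and (optionally)
#'   `n_keypresses`, `premature` columns.
#' @param fast,slow RT bounds in seconds.
#' @return the filtered table, with the removal log in attribute
#'   `"exclusions"`.
#' @export
exclude_trials <- function(trials, fast = 0.2, slow = 5) {
  stopifnot("rt" %in% names(trials))
  nk <- trials$n_keypresses %||% rep(1L, nrow(trials))
  pm <- trials$premature %||% rep(FALSE, nrow(trials))
  reason <- rep(NA_character_, nrow(trials))
  reason[trials$rt < fast] <- "too_fast"
  reason[trials$rt > slow] <- "too_slow"
  reason[nk > 1] <- "multiple_keypresses"
  reason[pm] <- "premature"
  bad <- !is.na(reason)
  log <- cbind(trials[bad, intersect(c("subject", "trial", "figure_id",
                                       "rt"), names(trials)),
                      drop = FALSE],
               reason = reason[bad])
  out <- trials[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- log
  out
}

#' Normalize reaction times within subject
#'
#' Adds a `normalized_rt` column: the within-subject z score of log RT
#' (mean 0, SD 1 per subject; zero when a subject's RTs are constant).
#'
#' @param trials trial table with `subject` and `rt` columns.
#' @param method `"zlog"` (default) or `"z"` (plain z of raw RT).
#' @return the table with `normalized_rt` added.
#' @export
normalize_rt <- function(trials, method = c("zlog", "z")) {
  method <- match.arg(method)
  stopifnot(all(c("subject", "rt") %in% names(trials)))
  counts <- table(trials$subject)
  if (any(counts < 10)) {
    warning("subjects with fewer than 10 trials: ",
            paste(names(counts)[counts < 10], collapse = ", "),
            call. = FALSE)
  }
  x <- if (method == "zlog") log(trials$rt) else trials$rt
  trials$normalized_rt <- stats::ave(x, trials$subject, FUN = zscore)
  trials
}

subject_group_means <- function(trials, keep) {
  agg <- stats::aggregate(normalized_rt ~ subject,
                          data = trials[keep, , drop = FALSE], FUN = mean)
  stats::setNames(agg$normalized_rt, agg$subject)
}

#' Wilcoxon tests of normalized RT across representation dimensions
#'
#' Tests subject-level mean normalized RT between dimension groups:
#' abstraction (high vs low tertile), animacy (animal vs non-animal
#' stimuli), local feature density and local deviation (high vs low
#' tertile). The animacy contrast uses the rank-sum test on subject means;
#' the within-subject contrasts use the signed-rank test on paired subject
#' means. P values are BH-FDR corrected across the four tests.
#'
#' @param trials normalized trial table (see [normalize_rt()]).
#' @param stim_table stimulus records with `figure_id`, `animacy_binary`,
#'   `abstraction`, `lfd` and optionally `local_deviation`.
#' @return data.frame with `dimension`, `W`, `p`, `p_fdr`,
#'   `direction` (mean high/animal minus low/non-animal, in normalized RT
#'   units).
#' @export
dimension_rt_tests <- function(trials, stim_table) {
  stopifnot("normalized_rt" %in% names(trials))
  idx <- match(trials$figure_id, stim_table$figure_id)
  dev <- stim_table$local_deviation %||% local_deviation(stim_table$lfd)
  dims <- list(
    abstraction = tertile_assign(stim_table$abstraction)[idx],
    animacy = factor(ifelse(stim_table$animacy_binary[idx], "high", "low"),
                     levels = c("low", "medium", "high")),
    lfd = tertile_assign(stim_table$lfd)[idx],
    local_deviation = tertile_assign(dev)[idx])
  rows <- lapply(names(dims), function(d) {
    g <- dims[[d]]
    hi <- subject_group_means(trials, !is.na(g) & g == "high")
    lo <- subject_group_means(trials, !is.na(g) & g == "low")
    if (!length(hi) || !length(lo)) {
      stop("dimension ", d, ": a contrast group is empty", call. = FALSE)
    }
    if (d == "animacy") {
      wt <- stats::wilcox.test(hi, lo, exact = length(hi) <= 25)
    } else {
      common <- intersect(names(hi), names(lo))
      wt <- stats::wilcox.test(hi[common], lo[common], paired = TRUE,
                               exact = length(common) <= 25)
    }
    data.frame(dimension = d, W = unname(wt$statistic), p = wt$p.value,
               direction = mean(hi) - mean(lo))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("dimension", "W", "p", "p_fdr", "direction")]
}

#' Repetition effects on normalized RT
#'
#' Per-presentation subject-mean normalized RT with a 95% CI, signed-rank
#' tests of adjacent presentations (BH-FDR corrected), and the trial-level
#' Pearson correlation between presentation index and normalized RT.
#'
#' @param trials normalized trial table with a `presentation` column.
#' @return list with `curve` (presentation, mean, se, lo, hi),
#'   `adjacent_tests` (pair, V, p, p_fdr) and `correlation` (r, p).
#' @export
repetition_curve <- function(trials) {
  stopifnot(all(c("normalized_rt", "presentation", "subject") %in%
                  names(trials)))
  pres <- sort(unique(trials$presentation))
  if (length(pres) < 2) stop("need at least 2 presentations", call. = FALSE)
  sm <- stats::aggregate(normalized_rt ~ subject + presentation,
                         data = trials, FUN = mean)
  curve <- do.call(rbind, lapply(pres, function(p) {
    v <- sm$normalized_rt[sm$presentation == p]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(presentation = p, mean = mean(v), se = se,
               lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
  }))
  tests <- do.call(rbind, lapply(seq_len(length(pres) - 1), function(k) {
    a <- sm[sm$presentation == pres[k], ]
    b <- sm[sm$presentation == pres[k + 1], ]
    common <- intersect(a$subject, b$subject)
    wt <- stats::wilcox.test(a$normalized_rt[match(common, a$subject)],
                             b$normalized_rt[match(common, b$subject)],
                             paired = TRUE, exact = length(common) <= 25)
    data.frame(pair = paste0(pres[k], "v", pres[k + 1]),
               V = unname(wt$statistic), p = wt$p.value)
  }))
  tests$p_fdr <- stats::p.adjust(tests$p, method = "BH")
  ct <- stats::cor.test(trials$presentation, trials$normalized_rt)
  list(curve = curve, adjacent_tests = tests,
       correlation = list(r = unname(ct$estimate), p = ct$p.value))
}

#' Detect change-of-mind response patterns
#'
#' A subject-image pair is flagged when its ordered response sequence over
#' the presentations contains exactly one transition; the direction is
#' `activation` (non-animal to animal) or `suppression` (animal to
#' non-animal). The image-level expected count is the mean over subjects of
#' the per-subject flagged-image count (fractional counts are meaningful),
#' and the fraction divides by the number of images.
#'
#' @param trials trial table with `subject`, `figure_id`, `presentation`,
#'   `response` (`"animal"`/`"non-animal"`).
#' @param n_images denominator for the fraction (default: the number of
#'   distinct images in the table).
#' @return list with `records` (subject, figure_id, direction,
#'   transition_index), `expected_count`, `fraction`, `n_images`,
#'   `skipped` (subject-image pairs without >= 2 presentations).
#' @export
detect_change_of_mind <- function(trials, n_images = NULL) {
  stopifnot(all(c("subject", "figure_id", "presentation", "response") %in%
                  names(trials)))
  if (is.null(n_images)) n_images <- length(unique(trials$figure_id))
  subjects <- unique(trials$subject)
  records <- list()
  skipped <- 0L
  per_subject_count <- stats::setNames(numeric(length(subjects)), subjects)
  for (s in subjects) {
    ts <- trials[trials$subject == s, ]
    for (im in unique(ts$figure_id)) {
      ti <- ts[ts$figure_id == im, ]
      ti <- ti[order(ti$presentation), ]
      if (nrow(ti) < 2) { skipped <- skipped + 1L; next }
      r <- ti$response == "animal"
      trans <- which(diff(r) != 0)
      if (length(trans) == 1) {
        dir <- if (r[trans + 1]) "activation" else "suppression"
        records[[length(records) + 1]] <- data.frame(
          subject = s, figure_id = im, direction = dir,
          transition_index = ti$presentation[trans + 1])
        per_subject_count[s] <- per_subject_count[s] + 1
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(subject = character(0), figure_id = character(0),
               direction = character(0), transition_index = integer(0))
  expected <- mean(per_subject_count)
  list(records = records, expected_count = expected,
       fraction = expected / n_images, n_images = n_images,
       per_subject_count = per_subject_count, skipped = skipped)
}
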
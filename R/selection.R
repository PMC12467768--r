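## Stimulus records, tertile partitioning and stimulus-set curation.

#' Rank-based tertile assignment
#'
#' Splits values into low/medium/high thirds by rank so the bins are
#' near-equal (sizes differ by at most 1); ties go to the lower bin.
#'
#' @param x numeric vector.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
tertile_assign <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  factor(ifelse(r <= cut1, "low", ifelse(r <= cut2, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Compute representation-dimension scores for a figure set
#'
#' Computes per-figure animacy (animate-lexicon fraction of global labels),
#' abstraction (normalized label entropy), local feature density (per-figure
#' discriminability share from a [granularity_profile()] with the binary
#' animacy task as target) and the local deviation index.
#'
#' @param encodings named list of `cae_matrix` objects.
#' @param annotations named list of `annotation_set` objects (same ids).
#' @param seed integer seed for the granularity cross-validation.
#' @param lexicon animate word list.
#' @return data.frame of stimulus records: `figure_id`, `animacy_score`,
#'   `animacy_binary`, `abstraction`, `lfd`, `local_deviation`.
#' @export
compute_dimensions <- function(encodings, annotations, seed = 1,
                               lexicon = animate_lexicon()) {
  ids <- names(encodings)
  stopifnot(!is.null(ids), setequal(ids, names(annotations)))
  annotations <- annotations[ids]
  animacy <- vapply(annotations, animacy_score, numeric(1), lexicon = lexicon)
  abstraction <- vapply(annotations, abstraction_level, numeric(1))
  animacy_binary <- animacy >= 0.5
  lfd_vals <- rep(0.5, length(ids))
  if (length(unique(animacy_binary)) == 2 &&
      min(table(animacy_binary)) >= 5) {
    prof <- granularity_profile(encodings, animacy_binary, seed = seed)
    lfd_vals <- lfd_per_figure(prof)
  } else {
    warning("animacy task is degenerate; lfd set to 0.5 for all figures",
            call. = FALSE)
  }
  data.frame(figure_id = ids, animacy_score = unname(animacy),
             animacy_binary = unname(animacy_binary),
             abstraction = unname(abstraction), lfd = lfd_vals,
             local_deviation = local_deviation(lfd_vals),
             row.names = NULL)
}

#' Curate a balanced stimulus set
#'
#' Greedy stratified selection that fills the 18 cells of
#' animacy-binary x abstraction-tertile x LFD-tertile as evenly as
#' possible, after first excluding the most extreme LFD values. The
#' selected set is re-tertiled and arranged into the nine groups
#' (abstraction tertile x LFD tertile) used by RDM displays.
#'
#' @param records data.frame of stimulus records (see
#'   [compute_dimensions()]); needs `figure_id`, `animacy_binary`,
#'   `abstraction`, `lfd`.
#' @param n_target number of stimuli to select.
#' @param seed integer seed (order of within-cell draws).
#' @param exclude_extreme fraction of the pool trimmed from each LFD tail
#'   before filling (skipped when the trimmed pool would fall below
#'   `n_target`).
#' @return list with `selected` (records of the chosen figures plus tertile
#'   columns and `group_index` 1..9, in nine-group display order) and
#'   `cell_counts` (the 18-cell fill table).
#' @export
select_stimuli <- function(records, n_target = 85, seed = 1,
                           exclude_extreme = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("figure_id", "animacy_binary", "abstraction", "lfd") %in%
                  names(records)))
  if (nrow(records) < n_target) {
    stop("pool (", nrow(records), ") smaller than n_target (", n_target, ")",
         call. = FALSE)
  }
  pool <- records
  ## trim extreme LFD values first
  if (exclude_extreme > 0) {
    q <- stats::quantile(pool$lfd, c(exclude_extreme, 1 - exclude_extreme),
                         names = FALSE, type = 1)
    keep <- pool$lfd >= q[1] & pool$lfd <= q[2]
    if (sum(keep) >= n_target) pool <- pool[keep, , drop = FALSE]
  }
  pool$abs_tertile <- tertile_assign(pool$abstraction)
  pool$lfd_tertile <- tertile_assign(pool$lfd)
  cell <- interaction(pool$animacy_binary, pool$abs_tertile,
                      pool$lfd_tertile, drop = FALSE)
  cell_members <- with_seed(seed, lapply(split(seq_len(nrow(pool)), cell),
                                         shuffle))
  picked <- integer(0)
  ## round-robin over cells until the target is reached
  while (length(picked) < n_target) {
    advanced <- FALSE
    for (nm in names(cell_members)) {
      if (length(picked) >= n_target) break
      if (length(cell_members[[nm]])) {
        picked <- c(picked, cell_members[[nm]][1])
        cell_members[[nm]] <- cell_members[[nm]][-1]
        advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  sel <- pool[sort(picked), , drop = FALSE]
  counts <- table(sel$animacy_binary, sel$abs_tertile, sel$lfd_tertile,
                  dnn = c("animacy", "abstraction", "lfd"))
  spread <- diff(range(counts))
  if (spread > 1) {
    warning("partial-fill: stratification cells differ by ", spread,
            " (pool imbalance); see cell_counts", call. = FALSE)
  }
  ## re-tertile on the selected set and build the nine-group ordering
  sel$animacy_tertile <- tertile_assign(sel$animacy_score %||% sel$lfd * 0 +
                                          as.numeric(sel$animacy_binary))
  sel$abs_tertile <- tertile_assign(sel$abstraction)
  sel$lfd_tertile <- tertile_assign(sel$lfd)
  sel$group_index <- (as.integer(sel$abs_tertile) - 1L) * 3L +
    as.integer(sel$lfd_tertile)
  sel <- sel[order(sel$group_index, sel$figure_id), , drop = FALSE]
  rownames(sel) <- NULL
  list(selected = sel, cell_counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a stimulus table CSV
#'
#' @param records stimulus record data.frame.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_stimulus_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- utils::read.csv(path)
  for (col in intersect(c("abs_tertile", "lfd_tertile", "animacy_tertile"),
                        names(df))) {
    df[[col]] <- factor(df[[col]], levels = c("low", "medium", "high"))
  }
  df
}
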
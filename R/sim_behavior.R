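## Synthetic behavioral trials with planted dimension, repetition and
## change-of-mind effects.

#' Specification for synthetic behavior
#'
#' Reaction times are lognormal: `RT = exp(mu + effects + sigma * eps)`.
#' Additive log-unit effects are planted for abstraction (slower when
#' abstract), animacy (animals faster), local feature density (salient
#' local features faster) and the local deviation index (dominant local or
#' global information faster). The repetition effect decays from the first
#' presentation and stabilizes at the third. Responses follow the animacy
#' truth with an error rate that grows with abstraction and are persistent
#' across presentations within a subject-image pair, except for designated
#' change-of-mind images, which flip exactly once.
#'
#' @param mu,sigma lognormal location (log-seconds) and scale.
#' @param abstraction_effect,animacy_effect,lfd_effect,deviation_effect
#'   log-unit RT effects of the (z-scored or +/-1) dimension values.
#' @param rep_delta log-unit RT decrement per presentation before
#'   stabilization at presentation 3.
#' @param base_error response error probability at zero abstraction.
#' @param error_abstraction_slope added error probability per unit
#'   abstraction.
#' @param com_frac fraction of images exhibiting a change of mind.
#' @param com_activation_frac fraction of change-of-mind images in the
#'   activation direction (non-animal -> animal).
#' @param multi_transition_frac fraction of images given unstable
#'   multi-transition response sequences (distractors for the detector).
#' @param seed integer seed.
#' @return object of class `sim_behavior_spec`.
#' @export
sim_behavior_spec <- function(mu = log(0.9), sigma = 0.25,
                              abstraction_effect = 0.2,
                              animacy_effect = -0.1,
                              lfd_effect = -0.05,
                              deviation_effect = -0.1,
                              rep_delta = 0.1,
                              base_error = 0.03,
                              error_abstraction_slope = 0.1,
                              com_frac = 0.115,
                              com_activation_frac = 0.5,
                              multi_transition_frac = 0,
                              seed = 1) {
  stopifnot(sigma >= 0, com_frac >= 0, com_frac <= 1)
  structure(as.list(environment()), class = "sim_behavior_spec")
}

#' Generate behavioral trials
#'
#' @param spec a [sim_behavior_spec()].
#' @param stim_table stimulus records (`figure_id`, `animacy_binary`,
#'   `abstraction`, `lfd`, optionally `local_deviation`).
#' @param n_subjects number of subjects.
#' @param n_presentations presentation cycles.
#' @return data.frame of trials (`subject`, `trial`, `figure_id`,
#'   `presentation`, `response`, `rt`, `n_keypresses`, `premature`) with
#'   attributes `com_images` (planted change-of-mind ids), `com_direction`,
#'   and `multi_transition_images`.
#' @export
gen_behavior <- function(spec, stim_table, n_subjects = 24,
                         n_presentations = 5) {
  stopifnot(inherits(spec, "sim_behavior_spec"),
            all(c("figure_id", "animacy_binary", "abstraction", "lfd") %in%
                  names(stim_table)))
  ids <- stim_table$figure_id
  n_img <- length(ids)
  dev <- stim_table$local_deviation %||% local_deviation(stim_table$lfd)

  with_seed(spec$seed, {
    n_com <- round(spec$com_frac * n_img)
    com_images <- if (n_com > 0) sample(ids, n_com) else character(0)
    com_dir <- stats::setNames(
      ifelse(stats::runif(n_com) < spec$com_activation_frac,
             "activation", "suppression"), com_images)
    ## per-image transition points, shared across subjects
    com_trans <- stats::setNames(
      as.list(sample(2:n_presentations, max(n_com, 1),
                     replace = TRUE)[seq_len(n_com)]), com_images)
    n_multi <- round(spec$multi_transition_frac * n_img)
    multi_images <- if (n_multi > 0) {
      sample(setdiff(ids, com_images), n_multi)
    } else character(0)

    z_abs <- zscore(stim_table$abstraction)
    z_lfd <- zscore(stim_table$lfd)
    z_dev <- zscore(dev)
    sgn_anim <- ifelse(stim_table$animacy_binary, 1, -1)

    seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    rows <- lapply(seq_len(n_subjects), function(s) {
      set.seed(seeds[s])
      sched <- do.call(rbind, lapply(seq_len(n_presentations), function(p) {
        data.frame(figure_id = sample(ids), presentation = p)
      }))
      sched$trial <- seq_len(nrow(sched))
      idx <- match(sched$figure_id, ids)

      ## persistent per-image response state for this subject
      p_err <- pmin(0.5, spec$base_error +
                      spec$error_abstraction_slope * stim_table$abstraction)
      state <- stim_table$animacy_binary
      err <- stats::runif(n_img) < p_err
      state[err] <- !state[err]
      resp <- logical(nrow(sched))
      for (r in seq_len(nrow(sched))) {
        im <- sched$figure_id[r]; k <- idx[r]; p <- sched$presentation[r]
        if (im %in% com_images) {
          tr_at <- com_trans[[im]]
          before <- com_dir[[im]] == "suppression"  # animal first
          resp[r] <- if (p < tr_at) before else !before
        } else if (im %in% multi_images) {
          resp[r] <- (p %% 2) == 1  # alternating, >1 transition
        } else {
          resp[r] <- state[k]
        }
      }

      rep_term <- spec$rep_delta * pmax(0, 3 - sched$presentation)
      log_rt <- spec$mu +
        spec$abstraction_effect * z_abs[idx] +
        spec$animacy_effect * sgn_anim[idx] +
        spec$lfd_effect * z_lfd[idx] +
        spec$deviation_effect * z_dev[idx] +
        rep_term +
        spec$sigma * stats::rnorm(nrow(sched))
      data.frame(subject = sprintf("s%02d", s), trial = sched$trial,
                 figure_id = sched$figure_id,
                 presentation = sched$presentation,
                 response = ifelse(resp, "animal", "non-animal"),
                 rt = exp(log_rt), n_keypresses = 1L, premature = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "com_images") <- com_images
    attr(out, "com_direction") <- com_dir
    attr(out, "multi_transition_images") <- multi_images
    out
  })
}
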
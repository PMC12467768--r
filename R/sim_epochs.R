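## Synthetic evoked-response epochs with planted spatiotemporal components.
##
## Noise model: rank-limited spatially mixed AR(1) sources plus white
## sensor noise, scaled to a target baseline RMS. Each planted component is
## a Gaussian temporal envelope times a fixed random channel topography
## times a per-trial condition value; familiarity (presentation index) can
## shift its latency and scale its gain.

#' Construct an epoch set
#'
#' @param data numeric array, trials x channels x time.
#' @param times numeric vector of sample times in seconds (strictly
#'   increasing), stimulus-locked.
#' @param channels channel names.
#' @param meta data.frame of per-trial metadata (one row per trial;
#'   typically `subject`, `figure_id`, `presentation`, plus behavioral
#'   columns).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channels, meta) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == nrow(meta),
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times),
            all(diff(times) > 0))
  structure(list(data = data, times = times, channels = channels,
                 meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[1], "trials x", d[2], "channels x", d[3],
      sprintf("samples (%.3f..%.3f s)\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Planted spatiotemporal component
#'
#' @param dimension metadata column (or `"image"`) whose per-trial value
#'   scales the component: logical columns map to +/-1, numeric columns are
#'   z-scored; `"image"` plants one random topography per stimulus.
#' @param latency envelope peak time in seconds.
#' @param latency_sd across-trial latency jitter SD in seconds.
#' @param duration Gaussian envelope SD in seconds.
#' @param effect_size component amplitude as a multiple of the baseline
#'   noise RMS (>= 0).
#' @param topography_seed seed fixing the random channel pattern.
#' @return a `sim_component` list.
#' @export
sim_component <- function(dimension, latency, latency_sd = 0,
                          duration = 0.05, effect_size = 1,
                          topography_seed = 1) {
  stopifnot(effect_size >= 0, duration > 0)
  structure(list(dimension = dimension, latency = latency,
                 latency_sd = latency_sd, duration = duration,
                 effect_size = effect_size,
                 topography_seed = topography_seed),
            class = "sim_component")
}

#' Specification for synthetic epochs
#'
#' Defaults mirror a 61-channel, 500 Hz recording segmented from -0.5 to
#' 1.0 s around stimulus onset with a -0.4..-0.1 s baseline.
#'
#' @param n_channels number of channels.
#' @param sfreq sampling rate in Hz.
#' @param tmin,tmax epoch window in seconds.
#' @param baseline length-2 baseline window in seconds (inside the epoch).
#' @param components list of [sim_component()] objects.
#' @param ar_coef AR(1) coefficient of the noise sources.
#' @param spatial_rank number of mixed noise sources.
#' @param noise_rms target baseline RMS (arbitrary units standing in for
#'   microvolts).
#' @param familiarity_latency_shift seconds of added component latency per
#'   presentation step beyond the first.
#' @param familiarity_gain multiplicative component gain per presentation
#'   step beyond the first.
#' @param artifact_frac fraction of epochs receiving a +/-100-unit
#'   excursion (exercises amplitude rejection).
#' @param seed integer seed.
#' @return object of class `sim_eeg_spec`.
#' @export
sim_eeg_spec <- function(n_channels = 61, sfreq = 500, tmin = -0.5,
                         tmax = 1.0, baseline = c(-0.4, -0.1),
                         components = list(), ar_coef = 0.97,
                         spatial_rank = 10, noise_rms = 10,
                         familiarity_latency_shift = 0,
                         familiarity_gain = 1, artifact_frac = 0,
                         seed = 1) {
  stopifnot(tmin < tmax, baseline[1] >= tmin, baseline[2] <= tmax,
            baseline[1] < baseline[2], noise_rms > 0,
            artifact_frac >= 0, artifact_frac <= 1)
  for (cmp in components) {
    stopifnot(inherits(cmp, "sim_component"))
    if (cmp$latency < tmin || cmp$latency > tmax) {
      stop("spec error: component latency ", cmp$latency,
           " outside the epoch window", call. = FALSE)
    }
  }
  structure(list(n_channels = n_channels, sfreq = sfreq, tmin = tmin,
                 tmax = tmax, baseline = baseline, components = components,
                 ar_coef = ar_coef, spatial_rank = spatial_rank,
                 noise_rms = noise_rms,
                 familiarity_latency_shift = familiarity_latency_shift,
                 familiarity_gain = familiarity_gain,
                 artifact_frac = artifact_frac, seed = seed),
            class = "sim_eeg_spec")
}

#' Trial schedule with randomized presentation cycles
#'
#' All stimuli are shown once, in randomized order, before the next
#' repetition cycle begins.
#'
#' @param figure_ids stimulus ids.
#' @param n_presentations repetition cycles (default 5).
#' @param seed integer seed.
#' @return data.frame with `trial`, `figure_id`, `presentation`.
#' @export
trial_schedule <- function(figure_ids, n_presentations = 5, seed = 1) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_presentations), function(p) {
      data.frame(figure_id = sample(figure_ids), presentation = p)
    })
    out <- do.call(rbind, rows)
    out <- cbind(trial = seq_len(nrow(out)), out)
    out
  })
}

## unit-norm random topography
random_topography <- function(n_channels, seed) {
  with_seed(seed, {
    v <- stats::rnorm(n_channels)
    v / sqrt(sum(v^2))
  })
}

## per-trial condition values for one component
component_values <- function(cmp, meta, stim_table) {
  if (identical(cmp$dimension, "image")) return(NULL)  # handled separately
  col <- stim_table[[cmp$dimension]]
  if (is.null(col)) {
    stop("spec error: stimulus table lacks column '", cmp$dimension, "'",
         call. = FALSE)
  }
  v <- col[match(meta$figure_id, stim_table$figure_id)]
  if (is.logical(v)) ifelse(v, 1, -1) else zscore(v)
}

#' Generate one subject's epochs
#'
#' @param spec a [sim_eeg_spec()].
#' @param stim_table stimulus record data.frame (needs `figure_id` plus any
#'   column named by a component dimension).
#' @param schedule trial schedule from [trial_schedule()].
#' @param subject subject id stored in the metadata.
#' @param seed integer seed for this subject's noise (defaults to the spec
#'   seed).
#' @return an `epoch_set`, baseline-corrected, with planted components.
#' @export
gen_epochs <- function(spec, stim_table, schedule, subject = "s01",
                       seed = NULL) {
  stopifnot(inherits(spec, "sim_eeg_spec"))
  if (is.null(seed)) seed <- spec$seed
  stopifnot(all(schedule$figure_id %in% stim_table$figure_id))
  times <- seq(spec$tmin, spec$tmax, by = 1 / spec$sfreq)
  n_t <- length(times)
  n_trials <- nrow(schedule)
  n_ch <- spec$n_channels
  channels <- sprintf("ch%02d", seq_len(n_ch))

  ## fixed topographies (shared across subjects via their own seeds)
  topos <- lapply(spec$components, function(cmp) {
    random_topography(n_ch, cmp$topography_seed)
  })
  image_ids <- unique(stim_table$figure_id)
  image_topos <- NULL
  if (any(vapply(spec$components, function(c) identical(c$dimension,
                                                        "image"),
                 logical(1)))) {
    image_topos <- vapply(seq_along(image_ids), function(k) {
      random_topography(n_ch, 70000 + k)
    }, numeric(n_ch))
    colnames(image_topos) <- image_ids
  }

  with_seed(seed, {
    ## rank-limited spatially mixed AR(1) noise + white sensor noise
    mixing <- matrix(stats::rnorm(n_ch * spec$spatial_rank), n_ch)
    data <- array(0, dim = c(n_trials, n_ch, n_t))
    for (tr in seq_len(n_trials)) {
      src <- matrix(stats::rnorm(spec$spatial_rank * n_t),
                    spec$spatial_rank)
      src <- t(apply(src, 1, function(x) {
        as.numeric(stats::filter(x, spec$ar_coef, method = "recursive"))
      }))
      data[tr, , ] <- mixing %*% src +
        0.2 * matrix(stats::rnorm(n_ch * n_t), n_ch)
    }
    base_idx <- which(times >= spec$baseline[1] & times <= spec$baseline[2])
    rms <- sqrt(mean(data[, , base_idx]^2))
    data <- data * (spec$noise_rms / rms)

    ## planted components
    for (k in seq_along(spec$components)) {
      cmp <- spec$components[[k]]
      vals <- component_values(cmp, schedule, stim_table)
      amp <- cmp$effect_size * spec$noise_rms
      for (tr in seq_len(n_trials)) {
        pres <- schedule$presentation[tr]
        lat <- cmp$latency + spec$familiarity_latency_shift * (pres - 1) +
          stats::rnorm(1, 0, cmp$latency_sd)
        gain <- spec$familiarity_gain^(pres - 1)
        env <- exp(-(times - lat)^2 / (2 * cmp$duration^2))
        topo <- if (identical(cmp$dimension, "image")) {
          image_topos[, schedule$figure_id[tr]]
        } else topos[[k]]
        val <- if (identical(cmp$dimension, "image")) 1 else vals[tr]
        data[tr, , ] <- data[tr, , ] +
          (amp * gain * val) * tcrossprod(topo, env)
      }
    }

    ## optional artifact injection
    if (spec$artifact_frac > 0) {
      n_art <- round(spec$artifact_frac * n_trials)
      if (n_art > 0) {
        art_tr <- sample(n_trials, n_art)
        ## excursions land after the baseline window so that baseline
        ## subtraction cannot mask them
        eligible <- which(times > spec$baseline[2] + 0.05)
        eligible <- eligible[eligible <= n_t - 10]
        for (tr in art_tr) {
          ## dipolar excursion: +100/-100 on a channel pair, so the
          ## average reference leaves the amplitude intact
          ch <- sample(n_ch, 2)
          at <- eligible[sample.int(length(eligible), 1)]
          data[tr, ch[1], at:(at + 9)] <- 100
          data[tr, ch[2], at:(at + 9)] <- -100
        }
        attr(data, "artifact_trials") <- sort(art_tr)
      }
    }

    ## baseline correction (per trial and channel)
    for (tr in seq_len(n_trials)) {
      bm <- rowMeans(matrix(data[tr, , base_idx], nrow = n_ch))
      data[tr, , ] <- data[tr, , ] - bm
    }

    meta <- cbind(subject = subject, schedule)
    es <- epoch_set(data, times, channels, meta)
    attr(es, "artifact_trials") <- attr(data, "artifact_trials")
    es
  })
}

#' Generate a multi-subject epoch list
#'
#' @param spec a [sim_eeg_spec()].
#' @param stim_table stimulus records.
#' @param n_subjects number of subjects.
#' @param n_presentations presentation cycles per subject.
#' @return named list of `epoch_set`, one per subject (independent noise and
#'   schedules; shared component topographies).
#' @export
gen_epochs_multi <- function(spec, stim_table, n_subjects = 24,
                             n_presentations = 5) {
  seeds <- derive_seeds(spec$seed, 2 * n_subjects)
  out <- lapply(seq_len(n_subjects), function(s) {
    sched <- trial_schedule(stim_table$figure_id, n_presentations,
                            seed = seeds[2 * s - 1])
    gen_epochs(spec, stim_table, sched,
               subject = sprintf("s%02d", s), seed = seeds[2 * s])
  })
  names(out) <- sprintf("s%02d", seq_len(n_subjects))
  out
}

#' Write / read an epoch set (array file + JSON sidecar)
#'
#' The voltage array is stored as an RDS file and the metadata (times,
#' channels, per-trial table) as a JSON sidecar next to it.
#'
#' @param epochs an `epoch_set`.
#' @param path path of the array file (`.rds`); the sidecar gets the same
#'   path with `.json` appended.
#' @return `path` (write) or an `epoch_set` (read).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs$data, path)
  jsonlite::write_json(
    list(times = epochs$times, channels = epochs$channels,
         meta = epochs$meta),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  epoch_set(readRDS(path), side$times, side$channels,
            as.data.frame(side$meta))
}
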
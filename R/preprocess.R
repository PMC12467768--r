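## Epoch preprocessing: average reference, zero-phase band-pass, baseline
## correction, amplitude rejection.

#' Preprocess epochs
#'
#' Applies, in order: average reference (per sample), zero-phase
#' Butterworth band-pass (forward-backward filtering), baseline subtraction
#' (mean over the baseline window), and rejection of epochs whose absolute
#' amplitude exceeds the threshold on any retained channel. The kept-trial
#' log is attached as attribute `"rejected"`.
#'
#' @param epochs an `epoch_set` covering the requested windows.
#' @param l_freq,h_freq band-pass corners in Hz (defaults 0.1 and 40).
#' @param baseline length-2 window in seconds for baseline subtraction.
#' @param reject absolute amplitude threshold (same units as the data,
#'   default 80); `Inf` disables rejection.
#' @param filter_order Butterworth order (applied twice, forward and
#'   backward).
#' @return the preprocessed `epoch_set`; rejected trial indices (relative
#'   to the input) in attribute `"rejected"`.
#' @export
preprocess <- function(epochs, l_freq = 0.1, h_freq = 40,
                       baseline = c(-0.4, -0.1), reject = 80,
                       filter_order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  data <- epochs$data
  times <- epochs$times
  n_trials <- dim(data)[1]; n_ch <- dim(data)[2]; n_t <- dim(data)[3]
  sfreq <- 1 / mean(diff(times))

  ## average reference
  for (tr in seq_len(n_trials)) {
    data[tr, , ] <- sweep(data[tr, , , drop = TRUE], 2,
                          colMeans(data[tr, , , drop = TRUE]))
  }

  ## zero-phase band-pass; fall back to low-pass when the high-pass corner
  ## is too close to DC for the epoch length
  nyq <- sfreq / 2
  h <- min(h_freq, 0.99 * nyq)
  use_bp <- l_freq > 0 && l_freq / nyq > 1e-4
  flt <- if (use_bp) {
    signal::butter(filter_order, c(l_freq, h) / nyq, type = "pass")
  } else {
    signal::butter(filter_order, h / nyq, type = "low")
  }
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      data[tr, ch, ] <- signal::filtfilt(flt, data[tr, ch, ])
    }
  }

  ## baseline correction
  base_idx <- which(times >= baseline[1] & times <= baseline[2])
  if (!length(base_idx)) stop("baseline window outside the epoch",
                              call. = FALSE)
  for (tr in seq_len(n_trials)) {
    bm <- rowMeans(matrix(data[tr, , base_idx], nrow = n_ch))
    data[tr, , ] <- data[tr, , ] - bm
  }

  ## amplitude rejection
  peak <- apply(abs(data), 1, max)
  keep <- peak <= reject
  if (!any(keep)) stop("empty-output error: all trials rejected",
                       call. = FALSE)
  out <- epoch_set(data[keep, , , drop = FALSE], times, epochs$channels,
                   epochs$meta[keep, , drop = FALSE])
  attr(out, "rejected") <- which(!keep)
  out
}

#' Select a time window / decimate an epoch set
#'
#' @param epochs an `epoch_set`.
#' @param tmin,tmax window bounds in seconds (NULL keeps the current bound).
#' @param decim keep every `decim`-th sample.
#' @return the cropped `epoch_set`.
#' @export
crop_epochs <- function(epochs, tmin = NULL, tmax = NULL, decim = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  t <- epochs$times
  keep <- rep(TRUE, length(t))
  if (!is.null(tmin)) keep <- keep & t >= tmin
  if (!is.null(tmax)) keep <- keep & t <= tmax
  idx <- which(keep)
  idx <- idx[seq(1, length(idx), by = decim)]
  epoch_set(epochs$data[, , idx, drop = FALSE], t[idx], epochs$channels,
            epochs$meta)
}
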
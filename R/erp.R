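#' Construct an epoch set
#'
#' Container for epoched multichannel EEG: a 3-d voltage array
#' (epochs x channels x samples, microvolts) with its time axis and condition
#' metadata. In the paradigm-faithful configuration epochs span 600 ms, from
#' 200 ms before sound onset (`t0_offset_ms = -200`) to 400 ms after.
#'
#' @param data Numeric array, epochs x channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param t0_offset_ms Time of the first sample relative to sound onset (ms).
#' @param channel_labels Unique channel labels, one per channel.
#' @param production Condition: `"MA"`, `"MO"` or `"AV"`.
#' @param soa SOA level in seconds.
#' @param participant_id Participant label.
#' @param meta Optional provenance list (ground-truth amplitudes, seeds,
#'   event markers such as the keypress at -100 ms in MA/MO epochs).
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0_offset_ms, channel_labels,
                      production = c("MA", "MO", "AV"), soa = 0.8,
                      participant_id = "P01", meta = list()) {
  production <- match.arg(production)
  stopifnot(length(dim(data)) == 3, fs > 0)
  if (length(channel_labels) != dim(data)[2]) {
    stop("channel_labels length must equal the channel dimension")
  }
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (any(!is.finite(data))) stop("voltages must be finite")
  structure(
    list(data = data, fs = fs, t0_offset_ms = t0_offset_ms,
         channel_labels = as.character(channel_labels),
         production = production, soa = soa,
         participant_id = as.character(participant_id), meta = meta),
    class = "epoch_set"
  )
}

#' @exportS3Method base::print
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s %s SOA %.1f: %d epochs x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              x$participant_id, x$production, x$soa, d[1], d[2], d[3], x$fs,
              x$t0_offset_ms))
  invisible(x)
}

#' Time axis of an epoch set or waveform (ms)
#' @param x An `epoch_set` or `erp_waveform`.
#' @return Numeric vector of sample times in ms relative to sound onset.
#' @export
epoch_times_ms <- function(x) {
  n_samp <- if (inherits(x, "epoch_set")) dim(x$data)[3] else ncol(x$data)
  x$t0_offset_ms + (seq_len(n_samp) - 1) / x$fs * 1000
}

#' Zero-phase band-pass and notch filtering of continuous EEG
#'
#' Band-pass filters each channel from `band[1]` to `band[2]` Hz with a
#' non-causal (forward-backward, zero-phase) Butterworth filter whose one-pass
#' asymptotic roll-off is 12 dB/octave per edge, then applies a zero-phase
#' Butterworth notch around `notch` Hz to remove mains artifacts. The
#' high-pass and low-pass edges are applied as separate cascaded second-order
#' sections for numerical stability at the very low high-pass corner.
#'
#' @param signal Numeric matrix, channels x samples (a vector is treated as
#'   one channel).
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param band High-pass and low-pass corner frequencies in Hz.
#' @param notch Notch centre frequency in Hz (width 2 Hz each side), or `NULL`
#'   to skip.
#' @return Filtered matrix of the same shape.
#' @export
filter_continuous <- function(signal, fs, band = c(0.1, 30), notch = 50) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (fs <= 2 * band[2]) stop("sampling rate too low for the requested band")
  nyq <- fs / 2
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(2, band[2] / nyq, type = "low")
  filters <- list(hp, lp)
  if (!is.null(notch)) {
    if (notch >= nyq) stop("notch frequency above Nyquist")
    filters <- c(filters, list(
      signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")))
  }
  out <- signal
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (f in filters) x <- signal::filtfilt(f, x)
    out[ch, ] <- x
  }
  out
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts, per sample, the mean of the named reference channels (e.g. the
#' mastoids) from every channel.
#'
#' @param signal Channels x samples matrix.
#' @param channel_labels Labels for the rows of `signal`.
#' @param reference_labels Labels of the reference channels; must all be
#'   present.
#' @return Re-referenced matrix of the same shape.
#' @export
rereference <- function(signal, channel_labels, reference_labels) {
  missing_ref <- setdiff(reference_labels, channel_labels)
  if (length(missing_ref) > 0) {
    stop("reference channels not found: ", paste(missing_ref, collapse = ", "))
  }
  ref_rows <- match(reference_labels, channel_labels)
  ref <- colMeans(signal[ref_rows, , drop = FALSE])
  sweep(signal, 2, ref)
}

#' Extract epochs around events
#'
#' Cuts fixed-length epochs from a continuous recording: for each event time,
#' samples covering the half-open window `[window_ms[1], window_ms[2])` ms
#' relative to the event, `round(span * fs)` samples in total. Events whose
#' window would run outside the recording are dropped and counted.
#'
#' @param signal Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param event_times_s Event (sound onset) times in seconds from recording
#'   start.
#' @param window_ms Epoch window in ms relative to the event
#'   (default `c(-200, 400)`).
#' @param channel_labels Channel labels.
#' @param ... Metadata forwarded to [epoch_set()] (`production`, `soa`,
#'   `participant_id`, `meta`).
#' @return An [epoch_set()]; `meta$n_dropped_edge` counts dropped events.
#' @export
extract_epochs <- function(signal, fs, event_times_s, window_ms = c(-200, 400),
                           channel_labels = paste0("ch", seq_len(nrow(signal))),
                           ...) {
  stopifnot(window_ms[1] < 0, window_ms[2] > 0)
  n_total <- ncol(signal)
  n_samp <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  starts <- round(event_times_s * fs + window_ms[1] / 1000 * fs) + 1L
  ok <- starts >= 1L & (starts + n_samp - 1L) <= n_total
  dropped <- sum(!ok)
  starts <- starts[ok]
  if (length(starts) == 0) stop("no events with a full epoch inside the recording")
  data <- array(NA_real_, dim = c(length(starts), nrow(signal), n_samp))
  for (e in seq_along(starts)) {
    data[e, , ] <- signal[, starts[e]:(starts[e] + n_samp - 1L), drop = FALSE]
  }
  args <- list(...)
  meta <- c(args$meta, list(n_dropped_edge = dropped))
  args$meta <- NULL
  do.call(epoch_set, c(list(data = data, fs = fs, t0_offset_ms = window_ms[1],
                            channel_labels = channel_labels, meta = meta), args))
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline window
#' (default the 200 ms preceding sound onset), so the baseline mean is zero
#' afterwards.
#'
#' @param epochs An [epoch_set()].
#' @param window_ms Baseline window `[start, end)` in ms (default
#'   `c(-200, 0)`).
#' @return Baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window_ms = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  t_ms <- epoch_times_ms(epochs)
  sel <- t_ms >= window_ms[1] & t_ms < window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - array(base, dim = dim(epochs$data))
  out
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Removes every epoch in which any channel's peak-to-peak range (max minus
#' min) STRICTLY exceeds the threshold; an epoch at exactly the threshold is
#' retained.
#'
#' @param epochs An [epoch_set()].
#' @param threshold_uv Peak-to-peak threshold in microvolts (default 200).
#' @return The surviving [epoch_set()] with `meta$n_rejected` recording the
#'   count; an error (with per-epoch ranges) if every epoch is rejected.
#' @export
reject_epochs <- function(epochs, threshold_uv = 200) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  rng <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  worst <- apply(rng, 1, max)
  keep <- worst <= threshold_uv
  if (!any(keep)) {
    stop("all ", length(keep), " epochs exceed the ", threshold_uv,
         " uV peak-to-peak threshold (worst ranges: ",
         paste(signif(utils::head(sort(worst), 3), 4), collapse = ", "), " ...)")
  }
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$meta$n_rejected <- sum(!keep)
  if (!is.null(out$meta$epoch_index)) out$meta$epoch_index <- out$meta$epoch_index[keep]
  out
}

#' Drop the first k epochs
#'
#' Removes the first `k` epochs in acquisition order, matching the removal of
#' initial keypress intervals that may contain timing transients (13 epochs
#' against 525 recorded leaves 512 analyzable).
#'
#' @param epochs An [epoch_set()].
#' @param k Number of initial epochs to drop (default 13).
#' @return The remaining [epoch_set()].
#' @export
drop_initial <- function(epochs, k = 13) {
  stopifnot(inherits(epochs, "epoch_set"), k >= 0)
  n <- dim(epochs$data)[1]
  if (n <= k) stop("cannot drop ", k, " epochs from a set of ", n)
  if (k == 0) return(epochs)
  out <- epochs
  out$data <- epochs$data[-seq_len(k), , , drop = FALSE]
  if (!is.null(out$meta$epoch_index)) out$meta$epoch_index <- out$meta$epoch_index[-seq_len(k)]
  out
}

#' Average epochs into an ERP waveform
#'
#' @param epochs An [epoch_set()] with at least one epoch.
#' @return An `erp_waveform`: channels x samples matrix `data` plus the time
#'   axis / labels / condition metadata of the epoch set.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] < 1) stop("no epochs to average")
  structure(
    list(data = apply(epochs$data, c(2, 3), mean),
         fs = epochs$fs, t0_offset_ms = epochs$t0_offset_ms,
         channel_labels = epochs$channel_labels,
         production = epochs$production, soa = epochs$soa,
         participant_id = epochs$participant_id,
         n_epochs = dim(epochs$data)[1]),
    class = "erp_waveform"
  )
}

#' Motor-correct an ERP
#'
#' Subtracts the motor-only (MO) ERP from the motor-auditory (MA) ERP,
#' pointwise, to remove motor activity and leave the auditory response: the
#' corrected waveform is labelled `"C-MA"`.
#'
#' @param ma_erp,mo_erp `erp_waveform`s with identical shape, channel labels,
#'   sampling and SOA.
#' @return The difference `erp_waveform` (MA - MO).
#' @export
motor_correct <- function(ma_erp, mo_erp) {
  stopifnot(inherits(ma_erp, "erp_waveform"), inherits(mo_erp, "erp_waveform"))
  if (!identical(dim(ma_erp$data), dim(mo_erp$data)) ||
      !identical(ma_erp$channel_labels, mo_erp$channel_labels) ||
      ma_erp$fs != mo_erp$fs || ma_erp$t0_offset_ms != mo_erp$t0_offset_ms ||
      ma_erp$soa != mo_erp$soa) {
    stop("MA and MO waveforms must share shape, channels, sampling and SOA")
  }
  out <- ma_erp
  out$data <- ma_erp$data - mo_erp$data
  out$production <- "C-MA"
  out
}

#' Place a component window with the collapsed localizer
#'
#' Averages the supplied condition ERPs with equal weight (the "collapsed"
#' waveform), pools it over the electrode set (pool-first), finds the
#' component extremum inside the search range (minimum for N1, maximum for
#' P2; ties broken to the earliest latency on the sampled grid), and centres
#' a window of `width_ms` on it. Placing the window on the collapsed waveform
#' avoids biasing the subsequent per-condition amplitude comparison.
#'
#' @param all_condition_erps List of `erp_waveform`s (all conditions).
#' @param component `"N1"` (negative, ~90 ms) or `"P2"` (positive, ~160 ms).
#' @param search_range_ms Latency range searched (defaults: N1 `c(50, 150)`,
#'   P2 `c(120, 220)`).
#' @param pool Electrode labels to pool (defaults: N1 Fz/FCz/Cz, P2
#'   FCz/Cz/CPz).
#' @param width_ms Window width (default 30 ms).
#' @return A `component_window` list: `name`, `center_ms`, `width_ms`,
#'   `start_ms`, `end_ms`, `electrode_pool`. Warns if the extremum lies on the
#'   search-range boundary (possible truncation).
#' @export
collapsed_localizer <- function(all_condition_erps, component = c("N1", "P2"),
                                search_range_ms = NULL, pool = NULL,
                                width_ms = 30) {
  component <- match.arg(component)
  if (is.null(search_range_ms)) {
    search_range_ms <- if (component == "N1") c(50, 150) else c(120, 220)
  }
  if (is.null(pool)) {
    pool <- if (component == "N1") c("Fz", "FCz", "Cz") else c("FCz", "Cz", "CPz")
  }
  stopifnot(length(all_condition_erps) >= 1)
  w1 <- all_condition_erps[[1]]
  collapsed <- Reduce(`+`, lapply(all_condition_erps, `[[`, "data")) /
    length(all_condition_erps)
  rows <- match(pool, w1$channel_labels)
  if (anyNA(rows)) {
    stop("pool channels not found: ",
         paste(pool[is.na(rows)], collapse = ", "))
  }
  pooled <- colMeans(collapsed[rows, , drop = FALSE])
  t_ms <- epoch_times_ms(w1)
  sel <- which(t_ms >= search_range_ms[1] & t_ms <= search_range_ms[2])
  if (length(sel) == 0) stop("search range contains no samples")
  seg <- pooled[sel]
  pick <- if (component == "N1") which.min(seg) else which.max(seg)
  center <- t_ms[sel[pick]]
  if (pick == 1L || pick == length(seg)) {
    warning("component extremum lies on the search-range boundary; ",
            "window may be truncated")
  }
  structure(list(name = component, center_ms = center, width_ms = width_ms,
                 start_ms = center - width_ms / 2, end_ms = center + width_ms / 2,
                 electrode_pool = pool),
            class = "component_window")
}

#' @exportS3Method base::print
print.component_window <- function(x, ...) {
  cat(sprintf("<component_window> %s: %.2f-%.2f ms (center %.2f), pool %s\n",
              x$name, x$start_ms, x$end_ms, x$center_ms,
              paste(x$electrode_pool, collapse = "/")))
  invisible(x)
}

#' Mean amplitude of a component window
#'
#' Average voltage over the pooled electrodes and over the samples in the
#' half-open window `[start_ms, end_ms)` on the sampling grid (averaging over
#' pool first then time; the order is irrelevant on a fixed grid).
#'
#' @param erp An `erp_waveform`.
#' @param window A `component_window` (from [collapsed_localizer()] or built
#'   directly).
#' @return A one-row data.frame: `participant`, `production`, `soa`,
#'   `component`, `mean_amplitude_uv`.
#' @export
mean_amplitude <- function(erp, window) {
  stopifnot(inherits(erp, "erp_waveform"), inherits(window, "component_window"))
  rows <- match(window$electrode_pool, erp$channel_labels)
  if (anyNA(rows)) {
    stop("pool channels not found: ",
         paste(window$electrode_pool[is.na(rows)], collapse = ", "))
  }
  t_ms <- epoch_times_ms(erp)
  sel <- t_ms >= window$start_ms & t_ms < window$end_ms
  if (!any(sel)) stop("window contains no samples")
  amp <- mean(colMeans(erp$data[rows, sel, drop = FALSE]))
  data.frame(participant = erp$participant_id, production = erp$production,
             soa = erp$soa, component = window$name, mean_amplitude_uv = amp,
             stringsAsFactors = FALSE)
}
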
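#' 1/f-like noise
#'
#' Spectral-synthesis noise with power spectrum proportional to
#' `f^(-exponent)`, scaled to a target RMS. Used as the background activity of
#' simulated EEG epochs (scalp EEG is well approximated by 1/f-like spectra).
#'
#' @param n Number of samples.
#' @param exponent Spectral exponent (1 = pink noise; 0 = white).
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n` with zero mean.
#' @export
one_over_f_noise <- function(n, exponent = 1, rms = 1) {
  stopifnot(n >= 4, exponent >= 0, rms >= 0)
  if (rms == 0) return(numeric(n))
  # draw in current RNG stream: callers control the seed
  half <- n %/% 2
  freqs <- seq_len(half)
  mag <- freqs^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[1 + freqs] <- mag * exp(1i * phase)
  if (n %% 2 == 0) spec[1 + half] <- Re(spec[1 + half])
  spec[n + 1 - seq_len(half - if (n %% 2 == 0) 1 else 0)] <-
    Conj(spec[1 + seq_len(half - if (n %% 2 == 0) 1 else 0)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

#' Specification for simulated ERP epochs
#'
#' Describes the simulated recording: epoch geometry, ERP components
#' (Gaussian-in-time bumps with a per-channel topography), per-condition
#' amplitude offsets, and 1/f background noise. The default specification
#' mirrors the self-stimulation paradigm: an auditory N1 (negative, peaking
#' ~90 ms) and P2 (positive, ~160 ms) present whenever a sound is heard
#' (MA and AV conditions), and a slow motor potential around the keypress
#' (made at -100 ms) present whenever a keypress is made (MA and MO), so that
#' the MA - MO subtraction isolates the auditory response.
#'
#' Because components are Gaussian bumps, the mean amplitude over a 30 ms
#' window centred on the peak is slightly below the peak amplitude; for the
#' default component widths it lies within 5% of it (windowed means are
#' shape-insensitive at the window centre).
#'
#' @param n_epochs_per_cell Epochs per production x SOA cell (default 525,
#'   matching one block of keypresses).
#' @param channels Ordered channel labels.
#' @param fs Sampling rate in Hz (default 1024).
#' @param epoch_window_ms Epoch span relative to sound onset (default
#'   `c(-200, 400)`; start must be negative, end positive).
#' @param components List of component definitions, each a list with `name`,
#'   `latency_ms`, `width_ms` (full width at half maximum), `amplitude_uv`
#'   (signed: negative for N1), `topography` (named weights, one per channel),
#'   `present_in` (productions containing the component).
#' @param condition_effects Data.frame with columns `component`, `production`,
#'   `soa`, `offset_uv`: additive amplitude offsets per cell (e.g. a -1 uV P2
#'   offset in MA yields 1 uV of P2 attenuation in C-MA relative to AV).
#' @param noise List with `exponent` (spectral slope, default 1) and `rms_uv`
#'   (default 2.5).
#' @param seed Integer seed.
#' @return An `erp_sim_spec` list, validated.
#' @export
erp_sim_spec <- function(n_epochs_per_cell = 525,
                         channels = c("Fz", "FCz", "Cz", "CPz", "Pz"),
                         fs = 1024,
                         epoch_window_ms = c(-200, 400),
                         components = default_components(channels),
                         condition_effects = NULL,
                         noise = list(exponent = 1, rms_uv = 2.5),
                         seed = 1) {
  stopifnot(n_epochs_per_cell >= 1, fs > 0,
            epoch_window_ms[1] < 0, epoch_window_ms[2] > 0)
  if (is.null(condition_effects)) {
    condition_effects <- data.frame(component = character(0),
                                    production = character(0),
                                    soa = numeric(0), offset_uv = numeric(0))
  }
  for (comp in components) {
    stopifnot(!is.null(comp$name), !is.null(comp$latency_ms),
              !is.null(comp$amplitude_uv), !is.null(comp$topography))
    if (comp$latency_ms < epoch_window_ms[1] || comp$latency_ms > epoch_window_ms[2]) {
      stop("component ", comp$name, " peaks outside the epoch window")
    }
    if (!all(names(comp$topography) %in% channels) ||
        any(!is.finite(unlist(comp$topography)))) {
      stop("component ", comp$name, ": topography must give finite weights ",
           "for channels in the montage")
    }
  }
  structure(list(n_epochs_per_cell = n_epochs_per_cell, channels = channels,
                 fs = fs, epoch_window_ms = epoch_window_ms,
                 components = components, condition_effects = condition_effects,
                 noise = noise, seed = seed),
            class = "erp_sim_spec")
}

#' Default simulated ERP components
#'
#' @param channels Montage labels (weights default to 0 for channels beyond
#'   the named ones).
#' @return List of component definitions for [erp_sim_spec()]: auditory N1
#'   (-3 uV at 90 ms) and P2 (+4 uV at 160 ms) in the sound-bearing MA and AV
#'   conditions, and a +2 uV slow motor potential near the keypress (-80 ms)
#'   in the keypress-bearing MA and MO conditions.
#' @export
default_components <- function(channels = c("Fz", "FCz", "Cz", "CPz", "Pz")) {
  topo <- function(...) {
    w <- c(...)
    out <- stats::setNames(rep(0, length(channels)), channels)
    out[intersect(names(w), channels)] <- w[intersect(names(w), channels)]
    out
  }
  list(
    list(name = "N1", latency_ms = 90, width_ms = 60, amplitude_uv = -3,
         topography = topo(Fz = 0.9, FCz = 1, Cz = 0.9, CPz = 0.7, Pz = 0.5),
         present_in = c("MA", "AV")),
    list(name = "P2", latency_ms = 160, width_ms = 80, amplitude_uv = 4,
         topography = topo(Fz = 0.6, FCz = 0.9, Cz = 1, CPz = 0.9, Pz = 0.7),
         present_in = c("MA", "AV")),
    list(name = "motor", latency_ms = -80, width_ms = 150, amplitude_uv = 2,
         topography = topo(Fz = 0.4, FCz = 0.6, Cz = 1, CPz = 0.8, Pz = 0.5),
         present_in = c("MA", "MO"))
  )
}

#' Simulate ERP epochs for every condition cell
#'
#' Generates, for one participant, an [epoch_set()] per production x SOA cell:
#' each epoch is the sum over applicable components of a Gaussian-in-time bump
#' scaled by (base amplitude + condition offset) and the channel topography,
#' plus independent 1/f noise per channel. Cell metadata carries the
#' ground-truth effective component amplitudes; MA and MO cells carry the
#' keypress event marker at -100 ms.
#'
#' @param spec An [erp_sim_spec()].
#' @param productions Conditions to simulate (default MA, MO, AV).
#' @param soas SOA levels (default 0.8, 1.6, 3.2 s).
#' @param participant_id Participant label.
#' @return Named list of [epoch_set()]s, names `"<production>_<soa>"`.
#' @export
simulate_epochs <- function(spec, productions = c("MA", "MO", "AV"),
                            soas = c(0.8, 1.6, 3.2), participant_id = "P01") {
  stopifnot(inherits(spec, "erp_sim_spec"))
  n_samp <- round(diff(spec$epoch_window_ms) / 1000 * spec$fs)
  t_ms <- spec$epoch_window_ms[1] + (seq_len(n_samp) - 1) / spec$fs * 1000
  n_ch <- length(spec$channels)
  eff <- spec$condition_effects
  with_local_seed(spec$seed, {
    out <- list()
    for (prod in productions) for (soa in soas) {
      signal_cs <- matrix(0, nrow = n_ch, ncol = n_samp)
      truth <- list()
      for (comp in spec$components) {
        if (!(prod %in% comp$present_in)) next
        off <- eff$offset_uv[eff$component == comp$name &
                               eff$production == prod & eff$soa == soa]
        amp <- comp$amplitude_uv + if (length(off) == 1) off else 0
        sdv <- comp$width_ms / (2 * sqrt(2 * log(2)))
        bump <- exp(-0.5 * ((t_ms - comp$latency_ms) / sdv)^2)
        w <- comp$topography[spec$channels]
        w[is.na(w)] <- 0
        signal_cs <- signal_cs + amp * outer(as.numeric(w), bump)
        truth[[comp$name]] <- amp
      }
      data <- array(0, dim = c(spec$n_epochs_per_cell, n_ch, n_samp))
      for (e in seq_len(spec$n_epochs_per_cell)) {
        noise <- t(vapply(seq_len(n_ch), function(ch) {
          one_over_f_noise(n_samp, spec$noise$exponent, spec$noise$rms_uv)
        }, numeric(n_samp)))
        data[e, , ] <- signal_cs + noise
      }
      meta <- list(ground_truth_amplitudes_uv = truth, seed = spec$seed)
      if (prod %in% c("MA", "MO")) meta$keypress_ms <- -100
      out[[paste0(prod, "_", soa)]] <-
        epoch_set(data, fs = spec$fs, t0_offset_ms = spec$epoch_window_ms[1],
                  channel_labels = spec$channels, production = prod, soa = soa,
                  participant_id = participant_id, meta = meta)
    }
    out
  })
}

#' Write / read an epoch set as plain text
#'
#' Serialises an [epoch_set()] to a pair of files: `<path>.csv` holding the
#' voltage array as a wide matrix (one row per epoch x channel, one column per
#' sample) and `<path>.json` holding the metadata sidecar (sampling rate,
#' epoch start offset, channel labels, condition, participant). Plain-text
#' formats keep the container auditable and diff-able.
#'
#' @param epochs An [epoch_set()].
#' @param path Base path (without extension).
#' @return `write_epoch_set()` returns `path` invisibly; `read_epoch_set()`
#'   returns the reconstructed [epoch_set()].
#' @export
write_epoch_set <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  utils::write.table(flat, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs_hz = epochs$fs, t0_ms = epochs$t0_offset_ms,
               channels = epochs$channel_labels, production = epochs$production,
               soa = epochs$soa, participant = epochs$participant_id,
               n_epochs = d[1], n_channels = d[2], n_samples = d[3])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  data <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                       meta$n_epochs)), c(3, 2, 1))
  epoch_set(data, fs = meta$fs_hz, t0_offset_ms = meta$t0_ms,
            channel_labels = meta$channels, production = meta$production,
            soa = meta$soa, participant_id = meta$participant)
}
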
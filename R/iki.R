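#' Construct an inter-keypress-interval series
#'
#' Container for one block's ordered inter-keypress intervals (IKIs), labelled
#' with participant, production condition (MA: motor-auditory, MO: motor-only)
#' and SOA level. The interval order is meaningful — it is the substrate of the
#' fractal analysis — and is never sorted.
#'
#' @param intervals Numeric vector of strictly positive durations in seconds.
#' @param participant_id Opaque participant label.
#' @param production `"MA"` or `"MO"`.
#' @param soa Stimulus onset asynchrony in seconds: 0.8, 1.6 or 3.2.
#' @param meta Optional list of provenance (seed, generator parameters).
#' @return An object of class `iki_series`.
#' @export
iki_series <- function(intervals, participant_id = "P01", production = c("MA", "MO"),
                       soa = c(0.8, 1.6, 3.2), meta = list()) {
  production <- match.arg(production)
  soa <- match.arg(as.character(soa[1L]), c("0.8", "1.6", "3.2"))
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L) stop("`intervals` must be non-empty")
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("all intervals must be finite and strictly positive")
  }
  structure(
    list(intervals = intervals, participant_id = as.character(participant_id),
         production = production, soa = as.numeric(soa), meta = meta),
    class = "iki_series"
  )
}

#' @exportS3Method base::print
print.iki_series <- function(x, ...) {
  cat(sprintf("<iki_series> participant %s, %s, SOA %.1f s: %d intervals (mean %.3f s, SD %.3f s)\n",
              x$participant_id, x$production, x$soa, length(x$intervals),
              mean(x$intervals), stats::sd(x$intervals)))
  invisible(x)
}

#' @exportS3Method base::length
length.iki_series <- function(x) length(x$intervals)

#' Simulate an inter-keypress-interval series with known fractal structure
#'
#' Generates an IKI series as affine-scaled fractional Gaussian noise with
#' Hurst parameter `target_alpha`, so that the DFA scaling exponent of the
#' series is `target_alpha` in expectation. This emulates the keypress timing
#' behaviour of the self-stimulation paradigm, where participants press once
#' every SOA seconds and the interval series exhibits persistent fluctuations.
#'
#' @param target_alpha Target scaling exponent, strictly inside (0, 1).
#'   Exponents >= 1 correspond to nonstationary (fBm-type) series and are not
#'   supported as generation targets.
#' @param mean_iki Target mean interval in seconds (> 0).
#' @param sd_iki Target interval standard deviation in seconds (>= 0). Zero
#'   yields a constant series.
#' @param n Series length (>= 16); 512 in the paradigm-faithful configuration.
#' @param seed Integer seed.
#' @param participant_id,production,soa Labels forwarded to [iki_series()].
#' @return An [iki_series()] whose `meta` records the generator parameters and
#'   the number of values clipped to the positive floor (1 ms). For typical
#'   keypress parameters (e.g. mean 0.85 s, SD 0.16 s) the clipping count is 0.
#' @export
simulate_iki_series <- function(target_alpha, mean_iki, sd_iki, n, seed,
                                participant_id = "P01", production = "MA",
                                soa = 0.8) {
  stopifnot(mean_iki > 0, sd_iki >= 0, n >= 16)
  if (!(target_alpha > 0 && target_alpha < 1)) {
    stop("`target_alpha` must lie strictly inside (0, 1); exponents >= 1 ",
         "(fBm-type nonstationary series) are not supported as generation targets")
  }
  if (sd_iki == 0) {
    x <- rep(0, n)
  } else {
    # standardise the realised draw so each block hits its nominal mean and
    # SD exactly; DFA is unaffected (it centres the series, and alpha is
    # scale-invariant)
    x <- simulate_fgn(target_alpha, n, seed)
    x <- (x - mean(x)) / stats::sd(x)
  }
  intervals <- mean_iki + sd_iki * x
  floor_s <- 1e-3
  clipped <- sum(intervals < floor_s)
  intervals[intervals < floor_s] <- floor_s
  iki_series(intervals, participant_id = participant_id, production = production,
             soa = soa,
             meta = list(target_alpha = target_alpha, mean_iki = mean_iki,
                         sd_iki = sd_iki, seed = seed, n_clipped = clipped))
}

#' Write / read IKI series as delimited text
#'
#' Long-format CSV with mandatory header `participant,production,soa,index,iki_s`,
#' UTF-8, `.` decimal separator.
#'
#' @param series A single `iki_series` or a list of them.
#' @param path File path.
#' @return `write_iki_csv()` returns `path` invisibly; `read_iki_csv()` returns
#'   a list of `iki_series` (one per participant x production x SOA block, in
#'   file order).
#' @export
write_iki_csv <- function(series, path) {
  if (inherits(series, "iki_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(participant = s$participant_id, production = s$production,
               soa = s$soa, index = seq_along(s$intervals), iki_s = s$intervals)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_iki_csv
#' @export
read_iki_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("participant", "production", "soa", "index", "iki_s")
  if (!all(need %in% names(df))) {
    stop("IKI csv must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(df$participant, df$production, df$soa, drop = TRUE)
  lapply(split(df, key)[unique(as.character(key))], function(d) {
    d <- d[order(d$index), ]
    iki_series(d$iki_s, participant_id = d$participant[1L],
               production = d$production[1L], soa = d$soa[1L])
  })
}
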
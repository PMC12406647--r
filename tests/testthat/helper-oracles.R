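# Independent oracles used across the suite. These deliberately use explicit
# loops and textbook arithmetic, sharing no code with the package internals.

# Naive DFA: per-window loops, lm() for detrending and the log-log fit.
naive_dfa <- function(x, window_sizes = generate_window_sizes(length(x))) {
  profile <- cumsum(x - mean(x))
  fn <- numeric(length(window_sizes))
  for (i in seq_along(window_sizes)) {
    n <- window_sizes[i]
    n_win <- floor(length(x) / n)
    msr <- numeric(n_win)
    for (w in seq_len(n_win)) {
      seg <- profile[((w - 1) * n + 1):(w * n)]
      fit <- stats::lm(seg ~ seq_len(n))
      msr[w] <- mean(stats::residuals(fit)^2)
    }
    fn[i] <- sqrt(mean(msr))
  }
  slope <- stats::coef(stats::lm(log(fn) ~ log(window_sizes)))[[2]]
  list(fluctuations = fn, alpha = slope)
}

# Balanced within-subject 2x3 ANOVA through stats::aov error strata.
aov_oracle <- function(data) {
  d <- data
  d$participant <- factor(d$participant)
  d$fa <- factor(d$production)
  d$fb <- factor(d$soa)
  fit <- stats::aov(value ~ fa * fb + Error(participant / (fa * fb)), data = d)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    idx <- trimws(rownames(tab)) == term
    list(ss = tab[idx, "Sum Sq"], df = tab[idx, "Df"],
         F = tab[idx, "F value"], p = tab[idx, "Pr(>F)"],
         ss_err = tab[trimws(rownames(tab)) == "Residuals", "Sum Sq"])
  }
  list(A = grab("Error: participant:fa", "fa"),
       B = grab("Error: participant:fb", "fb"),
       AB = grab("Error: participant:fa:fb", "fa:fb"))
}

# A balanced set of simulated IKI series covering participants x MA/MO x SOA.
make_design_series <- function(n_participants, alpha_ma = c(0.7, 0.7, 0.7),
                               alpha_mo = alpha_ma, n = 512, seed = 1,
                               mean_scale = TRUE) {
  soas <- c(0.8, 1.6, 3.2)
  out <- list()
  for (p in seq_len(n_participants)) {
    for (prod in c("MA", "MO")) {
      targets <- if (prod == "MA") alpha_ma else alpha_mo
      for (si in seq_along(soas)) {
        sd_iki <- if (mean_scale) 0.18 * soas[si] else 0.16
        m_iki <- if (mean_scale) soas[si] * 1.05 else 0.85
        s <- simulate_iki_series(
          targets[si], m_iki, sd_iki, n,
          seed = seed * 100000 + p * 100 + si * 10 + (prod == "MO"),
          participant_id = sprintf("P%02d", p), production = prod,
          soa = soas[si])
        out[[paste(p, prod, soas[si], sep = "_")]] <- s
      }
    }
  }
  out
}

# Flat epoch set with every voltage equal to `value` (or per-channel values).
constant_epochs <- function(value, n_epochs = 4, channels = c("Fz", "Cz"),
                            fs = 1000, window = c(-200, 400), ...) {
  n_samp <- round(diff(window) / 1000 * fs)
  data <- array(0, dim = c(n_epochs, length(channels), n_samp))
  for (ch in seq_along(channels)) {
    data[, ch, ] <- if (length(value) > 1) value[ch] else value
  }
  epoch_set(data, fs = fs, t0_offset_ms = window[1], channel_labels = channels, ...)
}
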
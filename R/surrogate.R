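#' Shuffle an IKI series
#'
#' Returns the series with its intervals in a uniformly random permuted order.
#' The multiset of values — and hence the mean and SD — is preserved exactly;
#' only the sequential order (the basis of the fractal analysis) is destroyed.
#' Labels and metadata are unchanged.
#'
#' @param series An [iki_series()].
#' @param seed Integer seed.
#' @return A shuffled [iki_series()].
#' @export
shuffle_series <- function(series, seed) {
  stopifnot(inherits(series, "iki_series"))
  perm <- with_local_seed(seed, sample.int(length(series$intervals)))
  out <- series
  out$intervals <- series$intervals[perm]
  out
}

#' Equivalent p from a surrogate distribution
#'
#' Fraction of surrogate statistics at least as large as the observed one,
#' `count(surrogate >= observed) / n_surrogates`. Ties count against the
#' observed effect; the (k+1)/(n+1) permutation convention is deliberately not
#' used, so 1 exceedance out of 500 gives p = 0.002 and 19 out of 500 gives
#' p = 0.038.
#'
#' @param observed Observed statistic.
#' @param surrogate Numeric vector of surrogate statistics.
#' @return Equivalent p in \[0, 1\].
#' @export
equivalent_p <- function(observed, surrogate) {
  stopifnot(is.finite(observed), length(surrogate) >= 1, all(is.finite(surrogate)))
  sum(surrogate >= observed) / length(surrogate)
}

#' Shuffle-surrogate control for the alpha-exponent ANOVA
#'
#' Tests whether the Production and SOA main effects on DFA alpha exponents
#' are genuine sequence-order effects rather than artifacts of per-cell
#' interval means and SDs. The observed F statistics come from the 2 x 3
#' within-subject ANOVA on the alpha exponents of the supplied series. On
#' each of `n_shuffles` iterations every series is independently permuted
#' (which preserves its mean and SD exactly), DFA is recomputed, and the same
#' ANOVA is run, yielding surrogate F distributions for both main effects.
#' The equivalent p per effect is the fraction of surrogate F values at least
#' as large as the observed F. The surrogate loop compares uncorrected F
#' values (no sphericity correction is needed since F, not p, is ranked).
#'
#' @param all_series List of [iki_series()] forming a complete balanced design:
#'   every participant must have all 6 production x SOA cells.
#' @param n_shuffles Number of surrogate iterations (500 in the
#'   paradigm-faithful configuration).
#' @param seed Master seed; per-iteration, per-series streams are derived from
#'   it, so runs are reproducible.
#' @return A `surrogate_test` list: `observed_f` (named: production, soa),
#'   `surrogate_f` (n_shuffles x 2 matrix), `equivalent_p` (named),
#'   `n_shuffles`, `seed`, and `alphas` (the observed alpha table).
#' @export
surrogate_anova_test <- function(all_series, n_shuffles = 500, seed = 1) {
  stopifnot(length(all_series) >= 6, n_shuffles >= 1)
  info <- data.frame(
    participant = vapply(all_series, function(s) s$participant_id, ""),
    production = vapply(all_series, function(s) s$production, ""),
    soa = vapply(all_series, function(s) s$soa, 0)
  )
  participants <- sort(unique(info$participant))
  prods <- c("MA", "MO")
  soas <- sort(unique(info$soa))
  if (length(soas) != 3) stop("expected 3 SOA levels, got ", length(soas))
  cell_of <- function(prod, soa) which(info$production == prod & info$soa == soa)
  # index matrix: participants x 6 cells (production-major ordering)
  idx <- matrix(NA_integer_, nrow = length(participants), ncol = 6)
  col <- 0
  for (prod in prods) for (soa in soas) {
    col <- col + 1
    for (r in seq_along(participants)) {
      j <- which(info$participant == participants[r] & info$production == prod &
                   info$soa == soa)
      if (length(j) != 1) {
        stop("incomplete design: participant ", participants[r],
             " must have exactly one ", prod, " series at SOA ", soa)
      }
      idx[r, col] <- j
    }
  }
  lens <- vapply(all_series, function(s) length(s$intervals), 0L)
  if (length(unique(lens)) != 1) stop("all series must have equal length")
  n_samp <- lens[1]
  plan <- dfa_plan(n_samp, generate_window_sizes(n_samp))
  vals <- lapply(all_series, function(s) s$intervals)

  n_cells <- length(idx)
  value_mat <- vapply(vals[as.vector(idx)], identity, numeric(n_samp))
  observed_alpha <- matrix(dfa_alpha_multi(value_mat, plan), nrow = nrow(idx))
  observed_f <- rm_anova_f(observed_alpha, a = 2, b = 3)

  surrogate_f <- matrix(NA_real_, nrow = n_shuffles, ncol = 2,
                        dimnames = list(NULL, c("production", "soa")))
  shuffled <- value_mat
  for (it in seq_len(n_shuffles)) {
    for (cell in seq_len(n_cells)) {
      s_seed <- derive_seed(seed, (it - 1L) * n_cells + cell)
      perm <- with_local_seed(s_seed, sample.int(n_samp))
      shuffled[, cell] <- value_mat[perm, cell]
    }
    shuf_alpha <- matrix(dfa_alpha_multi(shuffled, plan), nrow = nrow(idx))
    surrogate_f[it, ] <- rm_anova_f(shuf_alpha, a = 2, b = 3)
  }
  eq_p <- c(production = equivalent_p(observed_f[["A"]], surrogate_f[, "production"]),
            soa = equivalent_p(observed_f[["B"]], surrogate_f[, "soa"]))
  structure(list(
    observed_f = c(production = observed_f[["A"]], soa = observed_f[["B"]]),
    surrogate_f = surrogate_f,
    equivalent_p = eq_p,
    n_shuffles = n_shuffles,
    seed = seed,
    alphas = data.frame(
      participant = rep(participants, times = 6),
      production = rep(rep(prods, each = 3), each = length(participants)),
      soa = rep(rep(soas, times = 2), each = length(participants)),
      alpha = as.vector(observed_alpha)
    )
  ), class = "surrogate_test")
}

#' @exportS3Method base::print
print.surrogate_test <- function(x, ...) {
  cat(sprintf("<surrogate_test> %d shuffles (seed %d)\n", x$n_shuffles, x$seed))
  for (nm in names(x$observed_f)) {
    cat(sprintf("  %-11s observed F = %7.3f, equivalent p = %.4f\n",
                nm, x$observed_f[[nm]], x$equivalent_p[[nm]]))
  }
  invisible(x)
}
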
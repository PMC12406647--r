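#' Theoretical autocovariance of fractional Gaussian noise
#'
#' Autocovariance gamma(k) = 0.5 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) of a
#' unit-variance fGn process with Hurst parameter `H`.
#'
#' @param hurst Hurst parameter in (0, 1).
#' @param lags Integer vector of lags (>= 0).
#' @return Numeric vector of autocovariances, one per lag.
#' @export
fgn_autocovariance <- function(hurst, lags) {
  stopifnot(is.numeric(hurst), length(hurst) == 1L)
  if (!(hurst > 0 && hurst < 1)) {
    stop("`hurst` must lie strictly inside (0, 1), got ", hurst)
  }
  k <- as.numeric(lags)
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Simulate fractional Gaussian noise by exact circulant embedding
#'
#' Draws a length-`n` realisation of unit-variance fractional Gaussian noise
#' (fGn) with Hurst parameter `hurst` using the Davies--Harte circulant
#' embedding of the theoretical autocovariance. The construction is exact: the
#' simulated process has the fGn autocovariance in expectation at every lag,
#' which makes it a trustworthy ground truth for validating detrended
#' fluctuation analysis (for fGn the DFA scaling exponent equals `H`).
#'
#' @param hurst Hurst parameter, strictly inside (0, 1). `H = 0.5` gives white
#'   noise; `H > 0.5` persistent (positively autocorrelated) noise; `H < 0.5`
#'   anti-persistent noise.
#' @param n Number of samples (>= 16).
#' @param seed Integer seed; the same `(hurst, n, seed)` always returns a
#'   bit-identical sequence.
#' @return Numeric vector of length `n` with (theoretical) zero mean and unit
#'   variance.
#' @details The circulant embedding of size `2n` must be non-negative
#'   definite; for fGn this holds for all `H` in (0, 1), but the eigenvalues
#'   are checked and an error is raised (never a silent truncation) if
#'   numerical round-off produces a materially negative eigenvalue.
#' @examples
#' x <- simulate_fgn(0.7, 512, seed = 1)
#' @export
simulate_fgn <- function(hurst, n, seed) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 16)
  n <- as.integer(n)
  if (!(hurst > 0 && hurst < 1)) {
    stop("`hurst` must lie strictly inside (0, 1), got ", hurst)
  }
  g <- fgn_autocovariance(hurst, 0:n)
  # first row of the 2n x 2n circulant matrix
  circ <- c(g, g[seq(n, 2L)])
  ev <- Re(stats::fft(circ))
  tol <- 1e-8 * max(abs(ev))
  if (any(ev < -tol)) {
    stop("circulant embedding is not non-negative definite (min eigenvalue ",
         format(min(ev)), "); cannot simulate exactly at H = ", hurst,
         ", n = ", n)
  }
  ev[ev < 0] <- 0
  m <- 2L * n
  z <- with_local_seed(seed, {
    u <- stats::rnorm(m)
    v <- stats::rnorm(m)
    list(u = u, v = v)
  })
  w <- complex(length.out = m)
  w[1L] <- sqrt(ev[1L] / m) * z$u[1L]
  w[n + 1L] <- sqrt(ev[n + 1L] / m) * z$u[n + 1L]
  idx <- seq(2L, n)
  w[idx] <- sqrt(ev[idx] / (2 * m)) * complex(real = z$u[idx], imaginary = z$v[idx])
  w[m + 2L - idx] <- Conj(w[idx])
  Re(stats::fft(w))[seq_len(n)]
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library-level simulation never perturbs
# user-level randomness.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation (Lehmer step), kept inside 32-bit range so
# one master seed can spawn independent per-series / per-iteration streams.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + index) %% 2147483647)
}
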
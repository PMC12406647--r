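#' Greenhouse--Geisser epsilon
#'
#' Sphericity-correction factor computed from the covariance matrix of the k
#' within-subject condition scores: with E the covariance projected onto an
#' orthonormal contrast basis (orthogonal to the unit vector),
#' epsilon = tr(E)^2 / ((k - 1) * tr(E^2)), bounded to [1/(k-1), 1]. Under
#' perfect sphericity (e.g. compound symmetry) epsilon = 1; the lower bound is
#' attained when all contrast variance lies in a single direction.
#'
#' @param sigma k x k covariance matrix of the condition scores (k >= 2).
#' @return Epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(sigma) {
  sigma <- as.matrix(sigma)
  k <- nrow(sigma)
  stopifnot(k >= 2, ncol(sigma) == k)
  if (any(!is.finite(sigma))) stop("covariance matrix contains non-finite values")
  if (k == 2) return(1)
  e <- contrast_project(sigma)
  tr <- sum(diag(e))
  tr2 <- sum(e * e)
  if (tr2 <= 0) stop("degenerate covariance: zero contrast variance")
  min(1, max(1 / (k - 1), tr^2 / ((k - 1) * tr2)))
}

# Project a condition covariance onto an orthonormal basis of contrasts
# (rows orthogonal to the unit vector): E = C' Sigma C with C k x (k-1).
contrast_project <- function(sigma) {
  k <- nrow(sigma)
  cm <- stats::contr.helmert(k)
  cm <- sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  t(cm) %*% sigma %*% cm
}

#' Mauchly's test of sphericity from condition scores
#'
#' Tests whether the covariance of the orthonormal contrasts of k repeated
#' measures is proportional to the identity (sphericity). W is the ratio of
#' the determinant of the contrast covariance to the (k-1)-th power of its
#' average eigenvalue; the chi-square approximation follows Mauchly's
#' correction factor.
#'
#' @param scores n x k matrix: one row per subject, one column per condition.
#' @return List with `W`, `chisq`, `df`, `p_value`, and `n` (subjects).
#' @export
mauchly_sphericity <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  stopifnot(n >= 3, k >= 2)
  if (k == 2) {
    # a single contrast is trivially spherical
    return(list(W = 1, chisq = 0, df = 0L, p_value = 1, n = n))
  }
  e <- contrast_project(stats::cov(scores))
  p <- k - 1
  w <- det(e) / (sum(diag(e)) / p)^p
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chisq <- -(n - 1) * d * log(w)
  df <- as.integer(p * (p + 1) / 2 - 1)
  list(W = w, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE), n = n)
}

# Fast F statistics for the balanced two-way within-subject design, operating
# on a subjects x (a*b) matrix with cells ordered A-major (all B levels of A1,
# then of A2, ...). Returns only what the surrogate loop needs.
rm_anova_f <- function(m, a, b) {
  n <- nrow(m)
  arr <- array(t(m), dim = c(b, a, n))  # [j, i, s]
  g <- mean(arr)
  mean_a <- apply(arr, 2, mean)
  mean_b <- apply(arr, 1, mean)
  mean_s <- apply(arr, 3, mean)
  mean_as <- apply(arr, c(2, 3), mean)  # a x n
  mean_bs <- apply(arr, c(1, 3), mean)  # b x n
  ss_a <- n * b * sum((mean_a - g)^2)
  ss_b <- n * a * sum((mean_b - g)^2)
  ss_as <- b * sum((mean_as - outer(mean_a, rep(1, n)) -
                      outer(rep(1, a), mean_s) + g)^2)
  ss_bs <- a * sum((mean_bs - outer(mean_b, rep(1, n)) -
                      outer(rep(1, b), mean_s) + g)^2)
  f_a <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1)))
  c(A = f_a, B = f_b)
}

#' Two-way repeated-measures ANOVA (2 x 3 within-subject design)
#'
#' Classical univariate decomposition for a fully within-subject factorial
#' design: each effect (factor A, factor B, A x B) is tested against its own
#' subject-by-effect interaction stratum. For every within factor with more
#' than two levels, Mauchly's sphericity test and the Greenhouse--Geisser
#' epsilon are computed on the per-subject scores of that effect (condition
#' means for a main effect; level differences of the 2-level factor for the
#' interaction); both the uncorrected and the GG-corrected p are always
#' reported, and `p_headline` applies the correction only when Mauchly's test
#' is significant at 0.05.
#'
#' @param data Long data.frame with columns `participant`, `factor_a`,
#'   `factor_b`, `value`; a complete balanced design (every participant in
#'   every cell exactly once, >= 3 participants).
#' @param factor_a,factor_b,participant,value Column names (defaults
#'   `"production"`, `"soa"`, `"participant"`, `"value"`).
#' @return An `rm_anova` object: a list with one entry per effect (`A`, `B`,
#'   `AB`) carrying `ss_effect`, `ss_error`, `df`, `df_error`, `F`, `p`,
#'   `gg_epsilon`, `p_gg`, `p_headline`, `partial_eta_sq`, `mauchly`.
#' @export
rm_anova_2x3 <- function(data, factor_a = "production", factor_b = "soa",
                         participant = "participant", value = "value") {
  need <- c(participant, factor_a, factor_b, value)
  if (!all(need %in% names(data))) {
    stop("`data` must contain columns: ", paste(need, collapse = ", "))
  }
  subj <- factor(data[[participant]])
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  y <- as.numeric(data[[value]])
  n <- nlevels(subj); a <- nlevels(fa); b <- nlevels(fb)
  if (n < 3) stop("need >= 3 participants")
  counts <- table(subj, fa, fb)
  if (any(counts != 1L)) {
    stop("design must be complete and balanced: every participant exactly once per cell")
  }
  arr <- array(NA_real_, dim = c(b, a, n))
  arr[cbind(as.integer(fb), as.integer(fa), as.integer(subj))] <- y

  g <- mean(arr)
  mean_a <- apply(arr, 2, mean); mean_b <- apply(arr, 1, mean)
  mean_s <- apply(arr, 3, mean)
  mean_ab <- apply(arr, c(1, 2), mean)       # b x a
  mean_as <- apply(arr, c(2, 3), mean)       # a x n
  mean_bs <- apply(arr, c(1, 3), mean)       # b x n

  ss <- function(x) sum(x^2)
  ss_a <- n * b * ss(mean_a - g)
  ss_b <- n * a * ss(mean_b - g)
  ss_ab <- n * ss(sweep(sweep(mean_ab, 2, mean_a), 1, mean_b) + g)
  ss_as <- b * ss(mean_as - outer(mean_a, rep(1, n)) - outer(rep(1, a), mean_s) + g)
  ss_bs <- a * ss(mean_bs - outer(mean_b, rep(1, n)) - outer(rep(1, b), mean_s) + g)
  resid <- arr
  for (s in seq_len(n)) {
    resid[, , s] <- arr[, , s] - mean_ab - outer(mean_bs[, s], rep(1, a)) -
      outer(rep(1, b), mean_as[, s]) + outer(mean_b, rep(1, a)) +
      outer(rep(1, b), mean_a) + mean_s[s] - g
  }
  ss_abs <- ss(resid)
  ss_subj <- a * b * ss(mean_s - g)
  ss_total <- ss(arr - g)

  effect <- function(ss_e, ss_err, df1, df2, scores) {
    f <- (ss_e / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    k <- ncol(scores)
    contrast_var <- sum(contrast_project(stats::cov(scores))^2)
    if (k > 2 && contrast_var <= 1e-12 * max(1, sum(stats::cov(scores)^2))) {
      # zero contrast variance (e.g. a purely additive model): sphericity is
      # vacuous, no correction applies
      mau <- list(W = 1, chisq = 0, df = 0L, p_value = 1, n = nrow(scores))
      eps <- 1; p_gg <- p; p_head <- p
    } else if (k > 2) {
      mau <- mauchly_sphericity(scores)
      eps <- gg_epsilon(stats::cov(scores))
      p_gg <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
      p_head <- if (mau$p_value < 0.05) p_gg else p
    } else {
      mau <- list(W = 1, chisq = 0, df = 0L, p_value = 1, n = nrow(scores))
      eps <- 1; p_gg <- p; p_head <- p
    }
    list(ss_effect = ss_e, ss_error = ss_err, df = df1, df_error = df2,
         F = f, p = p, gg_epsilon = eps, df_gg = c(eps * df1, eps * df2),
         p_gg = p_gg, p_headline = p_head,
         partial_eta_sq = ss_e / (ss_e + ss_err), mauchly = mau)
  }

  # per-subject effect scores for sphericity assessment
  scores_a <- t(mean_as)                     # n x a
  scores_b <- t(mean_bs)                     # n x b
  if (a == 2) {
    scores_ab <- t(apply(arr, c(1, 3), function(v) v[1] - v[2]))  # n x b
  } else {
    scores_ab <- t(mean_bs)  # fallback; interaction sphericity on B contrasts
  }

  out <- list(
    A = effect(ss_a, ss_as, a - 1, (a - 1) * (n - 1), scores_a),
    B = effect(ss_b, ss_bs, b - 1, (b - 1) * (n - 1), scores_b),
    AB = effect(ss_ab, ss_abs, (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1), scores_ab),
    strata = list(ss_subject = ss_subj, ss_total = ss_total,
                  ss_all = c(subject = ss_subj, A = ss_a, AS = ss_as, B = ss_b,
                             BS = ss_bs, AB = ss_ab, ABS = ss_abs)),
    design = list(n = n, a = a, b = b,
                  factor_a = factor_a, factor_b = factor_b,
                  levels_a = levels(fa), levels_b = levels(fb))
  )
  class(out) <- "rm_anova"
  out
}

#' @exportS3Method base::print
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d participants, %s (%d) x %s (%d)\n",
              x$design$n, x$design$factor_a, x$design$a,
              x$design$factor_b, x$design$b))
  for (nm in c("A", "B", "AB")) {
    e <- x[[nm]]
    label <- switch(nm, A = x$design$factor_a, B = x$design$factor_b,
                    AB = paste0(x$design$factor_a, ":", x$design$factor_b))
    cat(sprintf("  %-18s F(%.2f, %.2f) = %6.2f, p = %.4f (GG p = %.4f, eps = %.3f), pes = %.3f\n",
                label, e$df, e$df_error, e$F, e$p, e$p_gg, e$gg_epsilon,
                e$partial_eta_sq))
  }
  invisible(x)
}

#' Paired-samples t contrast with Cohen's d
#'
#' Two-sided paired t test; Cohen's d for paired data is the mean difference
#' divided by the standard deviation of the differences (so d = t / sqrt(n)).
#'
#' @param x,y Numeric vectors of equal length (>= 2), paired by position.
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`, `sd_diff`, `n`.
#' @export
paired_contrast <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- as.numeric(x) - as.numeric(y)
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero difference variance: paired t undefined")
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE),
       d = mean(d) / sdd, mean_diff = mean(d), sd_diff = sdd, n = n)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("all p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Intraclass correlation from variance components
#'
#' @param var_intercept Random-intercept (between-group) variance, >= 0.
#' @param var_residual Residual (within-group) variance, >= 0.
#' @return `var_intercept / (var_intercept + var_residual)`.
#' @export
icc <- function(var_intercept, var_residual) {
  stopifnot(var_intercept >= 0, var_residual >= 0)
  if (var_intercept + var_residual == 0) {
    stop("both variance components are zero: ICC undefined")
  }
  var_intercept / (var_intercept + var_residual)
}

#' BIC-based Bayes-factor approximation
#'
#' BF10 = exp((BIC_null - BIC_full) / 2), comparing a model containing the
#' term of interest (`bic_alt`) with the model omitting it (`bic_null`). Both
#' BICs must come from maximum-likelihood fits for the comparison to be valid.
#'
#' @param bic_null BIC of the reduced model.
#' @param bic_alt BIC of the full model.
#' @return BF10 (> 1 favours the full model).
#' @export
bic_bayes_factor <- function(bic_null, bic_alt) {
  stopifnot(is.finite(bic_null), is.finite(bic_alt))
  exp((bic_null - bic_alt) / 2)
}

#' Gaussian random-intercept linear mixed model
#'
#' Fits `response ~ fixed covariates + (1 | group)` by maximum likelihood
#' (not REML, so BICs are comparable across models with different fixed
#' effects). Fixed-effect inference uses Wald normal-approximation confidence
#' intervals and p values.
#'
#' @param response Numeric outcome vector.
#' @param fixed Data.frame (or named list) of fixed covariates; an intercept
#'   is always included. May be `NULL` / empty for an intercept-only model.
#' @param group Grouping labels (one random intercept per unique label).
#' @return An `lmm_fit` list: `fixed` (data.frame with `term`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `z`, `p`), `var_intercept`, `sd_intercept`,
#'   `var_residual`, `icc`, `log_lik`, `bic`, `n_obs`, `n_groups`,
#'   `boundary` (TRUE when the intercept variance is estimated at 0), and the
#'   underlying `lme4` model in `model`.
#' @export
fit_random_intercept_lmm <- function(response, fixed = NULL, group) {
  y <- as.numeric(response)
  g <- factor(group)
  if (length(unique(g)) < 2) stop("need >= 2 groups for a random intercept")
  if (anyNA(y)) stop("missing values in response")
  df <- data.frame(.y = y, .g = g)
  terms <- character(0)
  if (!is.null(fixed) && length(fixed) > 0) {
    fixed <- as.data.frame(fixed)
    if (anyNA(fixed)) stop("missing values in fixed covariates")
    stopifnot(nrow(fixed) == length(y))
    terms <- names(fixed)
    df <- cbind(df, fixed)
  }
  rhs <- paste(c("1", terms, "(1 | .g)"), collapse = " + ")
  fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = df,
                    REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u <- vc$vcov[vc$grp == ".g"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  zc <- stats::qnorm(0.975)
  fixed_tab <- data.frame(
    term = rownames(co), estimate = est, se = se,
    ci_lower = est - zc * se, ci_upper = est + zc * se,
    z = est / se, p = 2 * stats::pnorm(-abs(est / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    fixed = fixed_tab,
    var_intercept = var_u, sd_intercept = sqrt(var_u),
    var_residual = var_e,
    icc = icc(var_u, var_e),
    log_lik = as.numeric(stats::logLik(fit)),
    bic = stats::BIC(fit),
    n_obs = length(y), n_groups = nlevels(g),
    boundary = var_u <= .Machine$double.eps * var_e,
    model = fit
  ), class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> ML, %d obs, %d groups; var(intercept) = %.3f (SD %.3f), var(resid) = %.3f, ICC = %.3f, BIC = %.2f%s\n",
              x$n_obs, x$n_groups, x$var_intercept, x$sd_intercept,
              x$var_residual, x$icc, x$bic,
              if (x$boundary) " [boundary: intercept variance ~ 0]" else ""))
  print(x$fixed, digits = 4)
  invisible(x)
}
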
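#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the end-to-end analysis. Defaults are
#' paradigm-faithful where the study design fixes them (SOA levels, 525
#' keypresses per block, discard of the first 12 intervals / 13 epochs, the
#' DFA ladder, the 200 uV rejection threshold) and reduced-scale for routine
#' desk runs (8 participants, 64 epochs per cell, 100 shuffles);
#' `paper_scale = TRUE` restores 21 participants, 525 epochs per cell and 500
#' shuffles. Generator targets mirror the observed behaviour of the paradigm:
#' mean intervals near the instructed SOA with SD growing with SOA, and alpha
#' exponents increasing with SOA (0.8 / 1.6 / 3.2 s cell targets averaging
#' 0.68 / 0.75 / 0.82) and slightly higher with sound feedback (MA) than
#' without (MO).
#'
#' @param seed Master seed; every random stage derives its stream from it.
#' @param paper_scale Use full study dimensions instead of reduced ones.
#' @param n_participants,n_epochs_per_cell,n_shuffles Scale overrides.
#' @param n_keypresses Keypresses per block (yielding `n_keypresses - 1`
#'   intervals).
#' @param discard_ikis Initial intervals discarded as timing transients.
#' @param drop_epochs Initial epochs dropped to match the interval discard.
#' @param soas SOA levels in seconds.
#' @param alpha_targets Named list `MA` / `MO` of per-SOA target exponents.
#' @param alpha_subject_sd Between-participant SD of the target exponent.
#' @param iki_means,iki_sds Named lists `MA` / `MO` of per-SOA interval means
#'   and SDs (seconds).
#' @param rejection_threshold_uv Peak-to-peak artifact threshold.
#' @param dfa_base,dfa_factor DFA ladder parameters.
#' @param erp_effects Condition-effect table for [erp_sim_spec()]; the default
#'   injects a 1 uV P2 attenuation and a 1 uV N1 enhancement in MA at the two
#'   longer SOAs (effects absent at SOA 0.8), mirroring the SOA-graded pattern
#'   with a 1 uV effect magnitude.
#' @param noise_rms_uv Epoch background-noise RMS.
#' @return A `run_config` list (also echoing any override downstream).
#' @export
run_config <- function(seed = 1, paper_scale = FALSE,
                       n_participants = if (paper_scale) 21 else 8,
                       n_epochs_per_cell = if (paper_scale) 525 else 64,
                       n_shuffles = if (paper_scale) 500 else 100,
                       n_keypresses = 525, discard_ikis = 12, drop_epochs = 13,
                       soas = c(0.8, 1.6, 3.2),
                       alpha_targets = list(MA = c(0.70, 0.77, 0.84),
                                            MO = c(0.66, 0.73, 0.80)),
                       alpha_subject_sd = 0.05,
                       iki_means = list(MA = c(0.85, 1.71, 3.18),
                                        MO = c(0.75, 1.45, 3.06)),
                       iki_sds = list(MA = c(0.16, 0.28, 0.48),
                                      MO = c(0.14, 0.25, 0.67)),
                       rejection_threshold_uv = 200,
                       dfa_base = 4, dfa_factor = 1.2,
                       erp_effects = default_erp_effects(soas),
                       noise_rms_uv = 2.5) {
  stopifnot(n_participants >= 3, n_keypresses - 1 - discard_ikis >= 40,
            n_epochs_per_cell > drop_epochs)
  structure(as.list(environment()), class = "run_config")
}

#' Default simulated condition effects
#'
#' @param soas SOA levels.
#' @return Condition-effect data.frame for [erp_sim_spec()]: -1 uV offsets on
#'   the MA N1 and P2 at the two longest SOA levels.
#' @export
default_erp_effects <- function(soas = c(0.8, 1.6, 3.2)) {
  long <- soas[-1]
  data.frame(
    component = rep(c("N1", "P2"), each = length(long)),
    production = "MA",
    soa = rep(long, 2),
    offset_uv = -1
  )
}

#' Run the full behavioural--electrophysiological pipeline
#'
#' Executes every stage on synthetic data generated from `config`:
#' \enumerate{
#'   \item Keypress simulation: per participant x production (MA, MO) x SOA,
#'     a block of `n_keypresses` yields `n_keypresses - 1` intervals; the
#'     first `discard_ikis` are discarded as transients.
#'   \item DFA: alpha exponent and persistence classification per cell, then
#'     the 2 x 3 within-subject ANOVA on the exponents.
#'   \item Shuffle-surrogate control: equivalent p for both main effects.
#'   \item ERP chain: simulated epochs per cell are baseline-corrected,
#'     artifact-rejected (peak-to-peak), stripped of the first `drop_epochs`
#'     epochs, and averaged; MA - MO gives the motor-corrected C-MA waveform;
#'     component windows come from the collapsed localizer on the grand
#'     average of all analysed conditions; windowed mean amplitudes are
#'     measured per participant x condition x SOA.
#'   \item Statistics: 2 (C-MA, AV) x 3 (SOA) ANOVA per component; paired
#'     AV-vs-C-MA contrasts per SOA and difference-wave contrasts between SOA
#'     levels, each family BH-adjusted; random-intercept mixed models
#'     predicting the C-MA amplitude from the MA alpha exponent, the AV
#'     amplitude and the MA mean interval; BIC-approximated Bayes factor for
#'     the alpha term.
#' }
#'
#' @param config A [run_config()].
#' @return A structured report (class `pipeline_report`): `schema_version`,
#'   `config` echo, `alphas`, `alpha_anova`, `surrogate`, `windows`,
#'   `component_measures`, `component_anovas`, `contrasts`,
#'   `difference_contrasts`, `lmm`, `bayes_factor_alpha`, `bookkeeping`.
#'   Re-running with an identical config reproduces every number exactly.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  participants <- sprintf("P%02d", seq_len(cf$n_participants))
  prods <- c("MA", "MO")

  ## ---- stage 1: keypress series -------------------------------------------
  series <- list()
  n_iki_raw <- cf$n_keypresses - 1
  for (pi in seq_along(participants)) {
    for (prod in prods) for (si in seq_along(cf$soas)) {
      sseed <- derive_seed(cf$seed, pi * 1000 + (prod == "MO") * 100 + si)
      jitter <- with_local_seed(derive_seed(sseed, 7),
                                stats::rnorm(1, 0, cf$alpha_subject_sd))
      target <- min(0.95, max(0.05, cf$alpha_targets[[prod]][si] + jitter))
      s <- simulate_iki_series(target, cf$iki_means[[prod]][si],
                               cf$iki_sds[[prod]][si], n_iki_raw, sseed,
                               participant_id = participants[pi],
                               production = prod, soa = cf$soas[si])
      s$intervals <- s$intervals[-seq_len(cf$discard_ikis)]
      s$meta$n_discarded <- cf$discard_ikis
      series[[paste(participants[pi], prod, cf$soas[si], sep = "_")]] <- s
    }
  }
  n_analyzed <- n_iki_raw - cf$discard_ikis

  ## ---- stage 2: DFA + ANOVA on exponents ----------------------------------
  alphas <- dfa_table(series)
  alpha_anova <- rm_anova_2x3(alphas, factor_a = "production", factor_b = "soa",
                              value = "alpha")

  ## ---- stage 3: surrogate control -----------------------------------------
  surrogate <- surrogate_anova_test(series, n_shuffles = cf$n_shuffles,
                                    seed = derive_seed(cf$seed, 31))

  ## ---- stage 4: ERP chain -------------------------------------------------
  erps <- list()   # erps[[participant]][[cell]]
  for (pi in seq_along(participants)) {
    spec <- erp_sim_spec(n_epochs_per_cell = cf$n_epochs_per_cell,
                         condition_effects = cf$erp_effects,
                         noise = list(exponent = 1, rms_uv = cf$noise_rms_uv),
                         seed = derive_seed(cf$seed, 500 + pi))
    cells <- simulate_epochs(spec, participant_id = participants[pi],
                             soas = cf$soas)
    proc <- lapply(cells, function(ep) {
      ep <- baseline_correct(ep)
      ep <- reject_epochs(ep, cf$rejection_threshold_uv)
      ep <- drop_initial(ep, cf$drop_epochs)
      average_erp(ep)
    })
    pe <- list()
    for (soa in cf$soas) {
      key <- function(p) paste0(p, "_", soa)
      pe[[key("AV")]] <- proc[[key("AV")]]
      pe[[key("C-MA")]] <- motor_correct(proc[[key("MA")]], proc[[key("MO")]])
    }
    erps[[participants[pi]]] <- pe
  }

  # grand averages of the analysed conditions, collapsed for the localizer
  cell_names <- names(erps[[1]])
  grand <- lapply(cell_names, function(nm) {
    w <- erps[[1]][[nm]]
    w$data <- Reduce(`+`, lapply(erps, function(pe) pe[[nm]]$data)) / length(erps)
    w$participant_id <- "grand"
    w
  })
  windows <- list(N1 = collapsed_localizer(grand, "N1"),
                  P2 = collapsed_localizer(grand, "P2"))

  measures <- do.call(rbind, lapply(erps, function(pe) {
    do.call(rbind, lapply(pe, function(w) {
      rbind(mean_amplitude(w, windows$N1), mean_amplitude(w, windows$P2))
    }))
  }))
  rownames(measures) <- NULL

  ## ---- stage 5: statistics ------------------------------------------------
  component_anovas <- list()
  contrasts <- list()
  diff_contrasts <- list()
  lmm <- list()
  bf_alpha <- list()

  alpha_ma <- alphas[alphas$production == "MA", ]
  iki_ma <- do.call(rbind, lapply(series, function(s) {
    data.frame(participant = s$participant_id, production = s$production,
               soa = s$soa, mean_iki = mean(s$intervals))
  }))
  iki_ma <- iki_ma[iki_ma$production == "MA", ]

  for (comp in c("N1", "P2")) {
    m <- measures[measures$component == comp, ]
    component_anovas[[comp]] <- rm_anova_2x3(
      m, factor_a = "production", factor_b = "soa", value = "mean_amplitude_uv")

    wide <- function(prod) {
      x <- m[m$production == prod, ]
      stats::reshape(x[, c("participant", "soa", "mean_amplitude_uv")],
                     idvar = "participant", timevar = "soa",
                     direction = "wide")
    }
    av <- wide("AV"); cma <- wide("C-MA")
    av <- av[order(av$participant), ]; cma <- cma[order(cma$participant), ]

    # AV vs C-MA at each SOA level (one BH family per component)
    fam <- lapply(seq_along(cf$soas), function(si) {
      cr <- paired_contrast(av[[si + 1]], cma[[si + 1]])
      data.frame(component = comp, contrast = sprintf("AV-%g vs C-MA-%g",
                                                      cf$soas[si], cf$soas[si]),
                 t = cr$t, df = cr$df, p = cr$p, d = cr$d)
    })
    fam <- do.call(rbind, fam)
    fam$p_adj <- bh_adjust(fam$p)
    contrasts[[comp]] <- fam

    # difference waves (C-MA minus AV) compared between SOA levels
    dmat <- as.matrix(cma[, -1]) - as.matrix(av[, -1])
    pairs <- utils::combn(seq_along(cf$soas), 2)
    dfam <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      cr <- paired_contrast(dmat[, i2], dmat[, i1])
      data.frame(component = comp,
                 contrast = sprintf("diff %g vs %g", cf$soas[i2], cf$soas[i1]),
                 t = cr$t, df = cr$df, p = cr$p, d = cr$d)
    })
    dfam <- do.call(rbind, dfam)
    dfam$p_adj <- bh_adjust(dfam$p)
    diff_contrasts[[comp]] <- dfam

    # random-intercept LMM: C-MA ~ 1 + alpha-MA + AV + MA-IKI + (1 | participant)
    key <- function(d, nm) paste(d$participant, d$soa)
    mm <- m[m$production == "C-MA", ]
    ord <- key(mm, NULL)
    fixed <- data.frame(
      alpha_ma = alpha_ma$alpha[match(ord, key(alpha_ma, NULL))],
      av_amp = m$mean_amplitude_uv[m$production == "AV"][
        match(ord, key(m[m$production == "AV", ], NULL))],
      iki_ma = iki_ma$mean_iki[match(ord, key(iki_ma, NULL))]
    )
    full <- fit_random_intercept_lmm(mm$mean_amplitude_uv, fixed, mm$participant)
    null <- fit_random_intercept_lmm(mm$mean_amplitude_uv,
                                     fixed[, c("av_amp", "iki_ma")],
                                     mm$participant)
    lmm[[comp]] <- list(full = full, without_alpha = null)
    bf_alpha[[comp]] <- bic_bayes_factor(null$bic, full$bic)
  }

  structure(list(
    schema_version = "1.0",
    config = unclass(cf),
    bookkeeping = list(
      keypresses_per_block = cf$n_keypresses,
      raw_ikis = n_iki_raw,
      discarded_ikis = cf$discard_ikis,
      analyzed_ikis = n_analyzed,
      epochs_simulated = cf$n_epochs_per_cell,
      epochs_dropped_initial = cf$drop_epochs
    ),
    alphas = alphas,
    alpha_anova = alpha_anova,
    surrogate = surrogate,
    windows = windows,
    component_measures = measures,
    component_anovas = component_anovas,
    contrasts = contrasts,
    difference_contrasts = diff_contrasts,
    lmm = lmm,
    bayes_factor_alpha = bf_alpha
  ), class = "pipeline_report")
}

#' Validate a pipeline report against its schema
#'
#' Checks the presence and basic shape of every section of a
#' [run_full()] report for the report's declared `schema_version`.
#'
#' @param report A `pipeline_report`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!identical(report$schema_version, "1.0")) {
    stop("unknown schema version: ", report$schema_version)
  }
  need <- c("config", "bookkeeping", "alphas", "alpha_anova", "surrogate",
            "windows", "component_measures", "component_anovas", "contrasts",
            "difference_contrasts", "lmm", "bayes_factor_alpha")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0) stop("report missing sections: ",
                                paste(missing, collapse = ", "))
  stopifnot(
    is.data.frame(report$alphas),
    all(c("participant", "production", "soa", "alpha", "classification") %in%
          names(report$alphas)),
    inherits(report$alpha_anova, "rm_anova"),
    inherits(report$surrogate, "surrogate_test"),
    all(c("N1", "P2") %in% names(report$windows)),
    is.data.frame(report$component_measures),
    all(c("N1", "P2") %in% names(report$lmm)),
    all(vapply(report$bayes_factor_alpha, is.numeric, TRUE))
  )
  invisible(TRUE)
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> schema %s: %d participants, %d shuffles, %d epochs/cell\n",
              x$schema_version, x$config$n_participants, x$config$n_shuffles,
              x$config$n_epochs_per_cell))
  cat(sprintf("  alpha ANOVA: production F = %.2f (p = %.4f), soa F = %.2f (p = %.4f)\n",
              x$alpha_anova$A$F, x$alpha_anova$A$p_headline,
              x$alpha_anova$B$F, x$alpha_anova$B$p_headline))
  cat(sprintf("  surrogate equivalent p: production %.3f, soa %.3f\n",
              x$surrogate$equivalent_p[["production"]],
              x$surrogate$equivalent_p[["soa"]]))
  cat(sprintf("  windows: N1 %.1f-%.1f ms, P2 %.1f-%.1f ms\n",
              x$windows$N1$start_ms, x$windows$N1$end_ms,
              x$windows$P2$start_ms, x$windows$P2$end_ms))
  cat(sprintf("  BF10 (alpha term): N1 %.3f, P2 %.3f\n",
              x$bayes_factor_alpha$N1, x$bayes_factor_alpha$P2))
  invisible(x)
}
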
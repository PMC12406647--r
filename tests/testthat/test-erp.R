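test_that("band-pass filter honours its passband, notch and DC contracts", {
  fs <- 512
  t <- seq(0, 10, by = 1 / fs)
  inner <- function(x) x[(2 * fs):(8 * fs)]   # discard edge transients
  amp <- function(x) (max(inner(x)) - min(inner(x))) / 2

  in_band <- filter_continuous(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(amp(in_band) - 1), 0.05)

  mains <- filter_continuous(sin(2 * pi * 50 * t), fs)
  expect_lt(amp(mains), 0.10)

  # the 0.1 Hz high-pass removes a 100 uV DC offset to below 1% once edge
  # transients are discarded (the corner's time constant is seconds long)
  dc <- filter_continuous(rep(100, length(t)), fs)
  expect_lt(abs(mean(inner(dc))), 1)

  expect_error(filter_continuous(sin(t), fs = 50), "too low")
})

test_that("re-referencing subtracts the mean of the reference channels per sample", {
  sig <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(10, 10, 10))
  labs <- c("a", "b", "c")
  # references identically zero: unchanged
  sig0 <- rbind(sig, z = c(0, 0, 0))
  expect_equal(rereference(sig0, c(labs, "z"), "z"), sig0)
  # all channels equal: all zero
  eq <- matrix(5, 3, 4)
  expect_true(all(rereference(eq, labs, labs) == 0))
  # two references: (a + b) / 2 subtracted, hand computed
  out <- rereference(sig, labs, c("a", "b"))
  expect_equal(out[3, ], c(10, 10, 10) - c(2, 2, 2))
  expect_error(rereference(sig, labs, "Cz"), "not found")
})

test_that("epoch extraction cuts round(span * fs) samples and drops edge events", {
  fs <- 1000
  sig <- matrix(rnorm(2 * 5000), nrow = 2)
  ep <- extract_epochs(sig, fs, event_times_s = c(0.05, 1, 2, 4.9),
                       production = "AV", soa = 0.8)
  # 600 ms at 1000 Hz = 600 samples; events at 0.05 s and 4.9 s lack a full window
  expect_identical(dim(ep$data), c(2L, 2L, 600L))
  expect_identical(ep$meta$n_dropped_edge, 2L)
  expect_identical(ep$t0_offset_ms, -200)
  # content check: epoch 1 should be the samples around t = 1 s
  expect_equal(ep$data[1, 1, ], sig[1, 801:1400])
  expect_error(extract_epochs(sig, fs, event_times_s = 0.01), "no events")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- constant_epochs(7, production = "AV", soa = 0.8)
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))
  # linear ramp: output is the ramp shifted by its baseline-window mean
  fs <- 1000
  ramp <- seq_len(600)
  ep$data[1, 1, ] <- ramp
  bc <- baseline_correct(ep)
  t_ms <- epoch_times_ms(ep)
  shift <- mean(ramp[t_ms >= -200 & t_ms < 0])
  expect_equal(bc$data[1, 1, ], ramp - shift)
  expect_lt(abs(mean(bc$data[1, 1, t_ms >= -200 & t_ms < 0])), 1e-10)
})

test_that("peak-to-peak rejection uses a strict threshold", {
  ep <- constant_epochs(0, n_epochs = 3)
  ep$data[1, 1, 1:2] <- c(-125, 125)    # range 250: rejected
  ep$data[2, 2, 1:2] <- c(-100, 100)    # range exactly 200: retained
  out <- reject_epochs(ep, 200)
  expect_identical(dim(out$data)[1], 2L)
  expect_identical(out$meta$n_rejected, 1L)
  clean <- constant_epochs(0, n_epochs = 4)
  clean$data[] <- stats::runif(length(clean$data), -5, 5)
  expect_identical(reject_epochs(clean, 200)$meta$n_rejected, 0L)
  bad <- constant_epochs(0, n_epochs = 2)
  bad$data[, , 1] <- 500
  expect_error(reject_epochs(bad, 200), "all 2 epochs")
})

test_that("initial-epoch removal follows acquisition order", {
  ep <- constant_epochs(0, n_epochs = 525)
  ep$data[, 1, 1] <- seq_len(525)
  out <- drop_initial(ep, 13)
  expect_identical(dim(out$data)[1], 512L)
  expect_identical(out$data[1, 1, 1], 14)
  expect_identical(drop_initial(ep, 0)$data, ep$data)
  small <- constant_epochs(0, n_epochs = 10)
  expect_error(drop_initial(small, 13), "cannot drop")
})

test_that("averaging and motor correction are pointwise arithmetic", {
  ep <- constant_epochs(0, n_epochs = 2, production = "MA", soa = 0.8)
  v <- rnorm(600)
  ep$data[1, 1, ] <- v
  ep$data[2, 1, ] <- -v
  avg <- average_erp(ep)
  expect_true(all(abs(avg$data[1, ]) < 1e-12))

  ma <- average_erp(constant_epochs(3, production = "MA", soa = 1.6))
  mo <- average_erp(constant_epochs(1, production = "MO", soa = 1.6))
  cma <- motor_correct(ma, mo)
  expect_true(all(cma$data == 2))
  expect_identical(cma$production, "C-MA")
  zero <- mo; zero$data[] <- 0
  expect_equal(motor_correct(ma, zero)$data, ma$data)
  mo_other <- average_erp(constant_epochs(1, production = "MO", soa = 3.2))
  expect_error(motor_correct(ma, mo_other), "share")
})

test_that("the collapsed localizer centres windows on the pooled extremum", {
  fs <- 1000
  mk <- function(center, amp, soa = 0.8, prod = "AV") {
    ep <- constant_epochs(0, n_epochs = 1, channels = c("Fz", "FCz", "Cz"),
                          fs = fs, production = prod, soa = soa)
    t_ms <- epoch_times_ms(ep)
    for (ch in 1:3) ep$data[1, ch, ] <- amp * exp(-0.5 * ((t_ms - center) / 15)^2)
    average_erp(ep)
  }
  # single negative bump at 90 ms -> window [75, 105]
  w <- collapsed_localizer(list(mk(90, -4)), "N1", pool = c("Fz", "FCz", "Cz"))
  expect_equal(w$center_ms, 90)
  expect_equal(c(w$start_ms, w$end_ms), c(75, 105))

  # two equal bumps at 80 and 100 ms: the collapsed peak is found by dense
  # evaluation of the summed waveform over the sampled grid
  e1 <- mk(80, -4); e2 <- mk(100, -4)
  t_ms <- epoch_times_ms(e1)
  dense <- (e1$data[1, ] + e2$data[1, ]) / 2
  expected <- t_ms[t_ms >= 50 & t_ms <= 150][
    which.min(dense[t_ms >= 50 & t_ms <= 150])]
  w2 <- collapsed_localizer(list(e1, e2), "N1", pool = c("Fz", "FCz", "Cz"))
  expect_equal(w2$center_ms, expected)
  expect_gt(w2$center_ms, 80)
  expect_lt(w2$center_ms, 100)

  # extremum on the search boundary warns about truncation
  expect_warning(collapsed_localizer(list(mk(150, -4)), "N1",
                                     pool = c("Fz", "FCz", "Cz")),
                 "boundary")
})

test_that("windowed mean amplitude pools electrodes then averages samples", {
  erp <- average_erp(constant_epochs(5, channels = c("FCz", "Cz"),
                                     production = "AV", soa = 0.8))
  win <- structure(list(name = "P2", center_ms = 160, width_ms = 30,
                        start_ms = 145, end_ms = 175,
                        electrode_pool = c("FCz", "Cz")),
                   class = "component_window")
  expect_identical(mean_amplitude(erp, win)$mean_amplitude_uv, 5)
  erp2 <- average_erp(constant_epochs(c(2, 4), channels = c("FCz", "Cz"),
                                      production = "AV", soa = 0.8))
  expect_identical(mean_amplitude(erp2, win)$mean_amplitude_uv, 3)
})

test_that("windowed means are stable under sampling-rate refinement", {
  mk <- function(fs) {
    ep <- constant_epochs(0, n_epochs = 1, channels = "Cz", fs = fs,
                          production = "AV", soa = 0.8)
    t_ms <- epoch_times_ms(ep)
    ep$data[1, 1, ] <- 4 * exp(-0.5 * ((t_ms - 160) / 34)^2)
    average_erp(ep)
  }
  win <- structure(list(name = "P2", center_ms = 160, width_ms = 30,
                        start_ms = 145, end_ms = 175, electrode_pool = "Cz"),
                   class = "component_window")
  a512 <- mean_amplitude(mk(512), win)$mean_amplitude_uv
  a1024 <- mean_amplitude(mk(1024), win)$mean_amplitude_uv
  expect_equal(a512, a1024, tolerance = 0.01)
})

test_that("the pipeline recovers an injected P2 attenuation end to end", {
  # -1 uV P2 offset in MA: the AV minus C-MA difference should estimate 1 uV
  eff <- data.frame(component = "P2", production = "MA",
                    soa = rep(c(0.8, 1.6, 3.2), 1), offset_uv = -1)
  n_epochs <- 48
  diffs <- vapply(1:4, function(p) {
    spec <- erp_sim_spec(n_epochs_per_cell = n_epochs, condition_effects = eff,
                         noise = list(exponent = 1, rms_uv = 2), seed = 700 + p)
    cells <- simulate_epochs(spec, soas = 0.8, participant_id = paste0("P", p))
    proc <- lapply(cells, function(ep) {
      average_erp(drop_initial(reject_epochs(baseline_correct(ep), 200), 13))
    })
    cma <- motor_correct(proc[["MA_0.8"]], proc[["MO_0.8"]])
    win <- collapsed_localizer(list(proc[["AV_0.8"]], cma), "P2")
    mean_amplitude(proc[["AV_0.8"]], win)$mean_amplitude_uv -
      mean_amplitude(cma, win)$mean_amplitude_uv
  }, 0)
  # Monte-Carlo tolerance: averaged-ERP noise shrinks as 1/sqrt(n_epochs)
  expect_equal(mean(diffs), 1, tolerance = 0.4)
})
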
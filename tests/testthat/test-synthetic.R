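# synthetic-data generator: ground truth, raw recordings, artifacts

test_that("a constant noise-free trajectory yields constant ABG and no hypoxemia", {
  cfg <- tiny_config()
  tr <- generate_truth(cfg)
  expect_equal(tr$abg$fsao2, rep(50, nrow(tr$abg)))
  expect_true(all(!tr$labels, na.rm = TRUE))
  expect_true(all(tr$fsao2 == 50))
})

test_that("ABG draws fall at the 2.5/5/10 min marks of every 10-min step", {
  cfg <- sim_config(n_steps = 2, step_duration = 600, fsao2_start = 50,
                    fsao2_end = 30, abg_noise_sd = 0)
  tr <- generate_truth(cfg)
  expect_equal(tr$abg$t, c(150, 300, 600, 750, 900, 1200))
})

test_that("ground truth is reproducible under a fixed seed only", {
  cfg <- tiny_config(fhr_step_sd = 0.5, seed = 11)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  t3 <- generate_truth(tiny_config(fhr_step_sd = 0.5, seed = 12))
  expect_false(identical(t1$fhr, t3$fhr))
})

test_that("heart-rate walks stay within the configured ranges", {
  cfg <- sim_config(n_steps = 1, step_duration = 900, fhr_step_sd = 3,
                    mhr_step_sd = 2, seed = 4)
  tr <- generate_truth(cfg)
  expect_true(all(tr$fhr >= cfg$fhr_range[1] & tr$fhr <= cfg$fhr_range[2]))
  expect_true(all(tr$mhr >= cfg$mhr_range[1] & tr$mhr <= cfg$mhr_range[2]))
  expect_true(mean(diff(tr$fsao2)) <= 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(mod_freqs = c("740" = 690, "850" = 690)), "distinct")
  expect_error(sim_config(mod_freqs = c("740" = 690, "850" = 4500)), "Nyquist")
  expect_error(sim_config(fetal_fraction = c(0.3, 0.2, 0.1, 0.05, 0.02)),
               "non-decreasing")
  expect_error(sim_config(gains = rep(-1, 5)), "positive")
  expect_error(sim_config(n_steps = 0), "step")
})

test_that("simulated recordings are deterministic and structured as configured", {
  cfg <- tiny_config(noise_sd = 1e-4, seed = 21)
  tr <- generate_truth(cfg)
  r1 <- synthesize_recording(cfg, tr)
  r2 <- synthesize_recording(cfg, tr)
  expect_identical(r1, r2)
  expect_length(r1$signals, 2)
  expect_length(r1$signals[[1]], cfg$round_duration * cfg$fs_raw)
  # DC received power strictly decreases with distance
  expect_lt(mean(r1$signals[[2]]), mean(r1$signals[[1]]))
})

test_that("simulated fetal AC/DC sits two to four orders below DC and grows with distance", {
  cfg <- sim_config(n_steps = 1, step_duration = 60, fsao2_start = 60,
                    fsao2_end = 60, noise_sd = 0, abg_noise_sd = 0)
  s_frac <- 0.6
  ratios <- sapply(seq_along(cfg$distances), function(d)
    sapply(c(740, 850), function(w) expected_fetal_acdc(cfg, s_frac, d, w)))
  expect_true(all(ratios >= 1e-4 & ratios <= 1e-2))
  expect_true(all(diff(ratios[1, ]) > 0) && all(diff(ratios[2, ]) > 0))
  # lowest saturation end of the default trajectory stays in band too
  r15 <- sapply(seq_along(cfg$distances), function(d)
    sapply(c(740, 850), function(w) expected_fetal_acdc(cfg, 0.15, d, w)))
  expect_true(all(r15 >= 1e-4 & r15 <= 1e-2))
})

test_that("artifact injection is confined to its windows", {
  cfg <- tiny_config(seed = 31)
  tr <- generate_truth(cfg)
  rec <- synthesize_recording(cfg, tr)
  expect_identical(inject_artifacts(rec, NULL), rec)
  spec <- data.frame(t_start = 20, t_end = 30, type = "step", amplitude = 0.5)
  out <- inject_artifacts(rec, spec)
  fs <- rec$fs_raw
  expect_identical(out$signals[[1]][1:(20 * fs)], rec$signals[[1]][1:(20 * fs)])
  expect_identical(out$signals[[1]][(30 * fs + 1):(60 * fs)],
                   rec$signals[[1]][(30 * fs + 1):(60 * fs)])
  inside <- (20 * fs + 2):(30 * fs - 1)
  expect_equal(out$signals[[1]][inside], rec$signals[[1]][inside] + 0.5)
})

test_that("a baseline step shifts the lower envelope by its amplitude", {
  # envelope oracle on a piecewise-constant signal with cardiac ripple
  fs <- 80
  tt <- (0:(fs * 60 - 1)) / fs
  a <- 0.2
  x <- 1 + 0.01 * sin(2 * pi * 2 * tt) + a * (tt >= 30)
  dc <- extract_dc(x, fs)
  before <- mean(dc[(10 * fs):(20 * fs)])
  after <- mean(dc[(40 * fs):(50 * fs)])
  expect_equal(after - before, a, tolerance = 0.02)
})

test_that("a raw-signal baseline step is rejected by synchronous detection", {
  # an unmodulated (ambient-like) shift carries no LED-frequency content,
  # so the demodulated envelopes are unchanged up to filter leakage
  cfg <- tiny_config(seed = 33)
  tr <- generate_truth(cfg)
  rec <- synthesize_recording(cfg, tr)
  out <- inject_artifacts(rec, data.frame(t_start = 20, t_end = 50,
                                          type = "step", amplitude = 0.2))
  ppg0 <- demodulate_recording(rec)
  ppg1 <- demodulate_recording(out)
  mid <- (30 * 80):(45 * 80)
  expect_equal(ppg1$power[[1]][["740"]][mid], ppg0$power[[1]][["740"]][mid],
               tolerance = 1e-3)
})

test_that("a burst artifact elevates broadband spectral energy in its window", {
  cfg <- tiny_config(seed = 35)
  tr <- generate_truth(cfg)
  rec <- synthesize_recording(cfg, tr)
  out <- inject_artifacts(rec, data.frame(t_start = 20, t_end = 30,
                                          type = "burst", amplitude = 0.05),
                          seed = 5)
  fs <- rec$fs_raw
  in_win <- out$signals[[1]][(22 * fs):(28 * fs)] - rec$signals[[1]][(22 * fs):(28 * fs)]
  out_win <- out$signals[[1]][(40 * fs):(46 * fs)] - rec$signals[[1]][(40 * fs):(46 * fs)]
  expect_gt(stats::sd(in_win), 0.04)
  expect_equal(stats::sd(out_win), 0)
  expect_warning(
    inject_artifacts(rec, data.frame(t_start = c(10, 15), t_end = c(20, 25),
                                     type = "burst", amplitude = 0.01)),
    "overlapping")
})

test_that("a demodulated channel shows the expected spectral lines", {
  cfg <- tiny_config(fhr_step_sd = 0, mhr_step_sd = 0, seed = 41,
                     step_duration = 120)
  tr <- generate_truth(cfg)
  rec <- synthesize_recording(cfg, tr)
  ppg <- demodulate_recording(rec)
  x <- mid_region(ppg$power[[2]][["850"]], 0.1)
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x * signal::hanning(n)))[1:(n / 2)]
  fr <- (seq_len(n / 2) - 1) * 80 / n
  line_power <- function(f0) max(sp[abs(fr - f0) < 0.06])
  floor_power <- stats::median(sp[fr > 0.1 & fr < 5])
  expected_lines <- c(cfg$mrr, 2 * cfg$mrr, mean(cfg$mhr_range) / 60,
                      mean(cfg$fhr_range) / 60)
  for (f0 in expected_lines) expect_gt(line_power(f0), 20 * floor_power)
})
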
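test_that("generated trials peak at the requested stimulus frequency", {
  cfg <- generator_config(snr_db = 60, transient = FALSE, seed = 2)
  for (k in c(1L, 7L, 12L)) {
    tr <- generate_trial(cfg, k)
    spec <- Mod(stats::fft(tr[3, ]))[2:(cfg$n_samples / 2)]
    f_axis <- (1:(cfg$n_samples / 2 - 1)) * cfg$sample_rate / cfg$n_samples
    f_peak <- f_axis[which.max(spec)]
    expect_lt(abs(f_peak - cfg$grid$frequencies[k]),
              cfg$sample_rate / cfg$n_samples + 1e-9)
  }
  expect_error(generate_trial(cfg, 13L), "\\[1, 12\\]")
})

test_that("harmonic amplitude ratios carry into spectral power", {
  cfg <- generator_config(harmonic_amplitudes = c(1, 0.5), snr_db = Inf,
                          transient = FALSE, mixing = "identity",
                          phase_mode = "fixed", seed = 2)
  tr <- generate_trial(cfg, 4L)   # 10.75 Hz: both harmonics on-bin for 4 s
  spec <- Mod(stats::fft(tr[1, ]))^2
  bin <- function(f) round(f * cfg$n_samples / cfg$sample_rate) + 1L
  f0 <- cfg$grid$frequencies[4]
  ratio <- spec[bin(2 * f0)] / spec[bin(f0)]
  expect_equal(ratio, 0.25, tolerance = 1e-6)
})

test_that("trial generation is deterministic given the seed", {
  cfg <- generator_config(seed = 9)
  expect_identical(generate_trial(cfg, 5L, seed = 42),
                   generate_trial(cfg, 5L, seed = 42))
  expect_false(identical(generate_trial(cfg, 5L, seed = 42),
                         generate_trial(cfg, 5L, seed = 43)))
})

test_that("datasets have the protocol's trial layout and seeded randomization", {
  cfg <- generator_config(grid = small_grid(), n_blocks = 2, seed = 4,
                          trial_duration = 1)
  ep <- generate_dataset(cfg)
  expect_equal(n_trials(ep), 6L)
  expect_equal(sort(ep$labels[ep$block_ids == 1]), 1:3)
  expect_equal(sort(ep$labels[ep$block_ids == 2]), 1:3)
  # one trial per stimulus when n_blocks = 1
  ep1 <- generate_dataset(generator_config(grid = small_grid(), n_blocks = 1,
                                           trial_duration = 1, seed = 4))
  expect_equal(sort(ep1$labels), 1:3)
  # different seeds: different data, identical label multiset
  ep_b <- generate_dataset(generator_config(grid = small_grid(), n_blocks = 2,
                                            trial_duration = 1, seed = 5))
  expect_false(identical(ep$data, ep_b$data))
  expect_equal(sort(ep$labels), sort(ep_b$labels))
})

test_that("noise-free steady state is exactly periodic after the transient", {
  # frequencies whose period is an integer number of samples at 256 Hz
  cfg <- generator_config(grid = stimulus_grid(c(8, 12.8)), snr_db = Inf,
                          transient = TRUE, mixing = "identity",
                          phase_mode = "fixed", seed = 6)
  for (k in 1:2) {
    tr <- generate_trial(cfg, k)
    L <- as.integer(cfg$sample_rate / cfg$grid$frequencies[k])  # 32, 20
    post <- (cfg$transient_duration * cfg$sample_rate + 1):cfg$n_samples
    x <- tr[2, post]
    expect_lt(max(abs(x[seq_len(length(x) - L)] - x[(L + 1):length(x)])), 1e-9)
  }
  # and for a default-grid stimulus the samples match the analytic waveform
  cfg2 <- generator_config(snr_db = Inf, transient = FALSE,
                           mixing = "identity", phase_mode = "fixed", seed = 6)
  tr2 <- generate_trial(cfg2, 7L)
  f <- cfg2$grid$frequencies[7]
  t <- seq_len(cfg2$n_samples) / cfg2$sample_rate
  expected <- Reduce(`+`, lapply(1:3, function(h)
    cfg2$harmonic_amplitudes[h] * sin(2 * pi * h * f * t)))
  expect_equal(tr2[1, ], expected, tolerance = 1e-12)
})

test_that("measured narrowband SNR matches the configured level within 1 dB", {
  for (target in c(-10, 0, 20)) {
    # 4 s trials put every grid frequency and harmonic exactly on an FFT bin
    # (0.25 Hz resolution), so the narrowband measurement is leakage-free
    cfg <- generator_config(grid = small_grid(), snr_db = target,
                            transient = FALSE, mixing = "identity",
                            seed = 20 + target)
    measured <- numeric(50)
    for (i in 1:50) {
      tr <- generate_trial(cfg, 2L, seed = 1000 + i)
      spec <- Mod(stats::fft(tr[1, ]))^2
      n <- cfg$n_samples
      f_axis <- (0:(n - 1)) * cfg$sample_rate / n
      f_axis <- pmin(f_axis, cfg$sample_rate - f_axis)
      f0 <- cfg$grid$frequencies[2]
      harm <- unlist(lapply(seq_along(cfg$harmonic_amplitudes), function(h)
        which(abs(f_axis - h * f0) <= 0.1 + 1e-9)))
      p_sig <- sum(spec[harm])
      p_noise <- sum(spec[-c(1L, harm)])
      measured[i] <- p_sig / p_noise
    }
    snr_db_hat <- 10 * log10(mean(measured))
    expect_lt(abs(snr_db_hat - target), 1)
  }
})

test_that("the transient stage alters only its own window", {
  base <- generator_config(snr_db = Inf, transient = FALSE,
                           mixing = "identity", phase_mode = "fixed", seed = 8)
  with_tr <- generator_config(snr_db = Inf, transient = TRUE,
                              mixing = "identity", phase_mode = "fixed", seed = 8)
  a <- generate_trial(base, 3L, seed = 99)
  b <- generate_trial(with_tr, 3L, seed = 99)
  cut <- ceiling(with_tr$transient_duration * with_tr$sample_rate)
  expect_false(isTRUE(all.equal(a[1, 1:cut], b[1, 1:cut])))
  expect_equal(a[, (cut + 1):ncol(a)], b[, (cut + 1):ncol(b)], tolerance = 1e-12)
})

test_that("config validation rejects impossible setups", {
  expect_error(generator_config(trial_duration = 1.001), "integer number")
  expect_error(generator_config(harmonic_amplitudes = numeric(0)), "non-empty")
  expect_error(generator_config(harmonic_amplitudes = c(1, -1)), "non-negative")
  expect_error(generator_config(transient_duration = 5), "shorter")
  expect_error(generator_config(mixing = matrix(1, 2, 2)), "n_channels")
})
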
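#' Synthetic SSVEP generator configuration
#'
#' Describes the statistical structure of generated recordings: steady-state
#' sinusoids at the stimulus fundamental and harmonics, an initial transient
#' N75/P100/N135 wave complex, 1/f-type background noise at a target SNR, and
#' cross-channel mixing. Defaults reproduce the study conditions the package
#' is evaluated under: 12 stimuli (9.25-14.75 Hz), 15 blocks, 4 s trials at
#' 256 Hz over 8 occipital/parietal channels.
#'
#' @param grid a [stimulus_grid()].
#' @param sample_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds; `trial_duration * sample_rate`
#'   must be integral.
#' @param n_blocks number of acquisition blocks (one trial per stimulus each).
#' @param n_channels number of EEG channels.
#' @param harmonic_amplitudes relative amplitude of harmonic h = 1..Nh of the
#'   steady-state response; length sets the number of harmonics generated.
#' @param snr_db steady-state power over background-noise power, in dB.
#' @param phase_mode `"random"` draws a uniform phase per trial (models
#'   response-latency variability and feeds the phase-effect analyses);
#'   `"fixed"` locks every trial to phase 0 at flicker onset, the idealized
#'   stimulus-locked condition template detectors assume.
#' @param transient logical: prepend the transient VEP stage (three
#'   raised-cosine lobes at 75/100/135 ms with signs -, +, -)?
#' @param transient_duration seconds occupied by the transient stage.
#' @param transient_amplitudes signed N75/P100/N135 lobe amplitudes, relative
#'   to the fundamental's amplitude.
#' @param mixing `"crosstalk"` (identity plus small seeded random cross-talk)
#'   or `"identity"`, or an explicit `n_channels x n_channels` matrix.
#' @param noise_exponent spectral slope of the background noise
#'   (power ~ 1/f^exponent, bandlimited 1-100 Hz).
#' @param seed integer seed controlling all randomness of the generator.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(grid = stimulus_grid(), sample_rate = 256,
                             trial_duration = 4, n_blocks = 15, n_channels = 8,
                             harmonic_amplitudes = c(1, 0.5, 0.25),
                             snr_db = 0,
                             phase_mode = c("random", "fixed"),
                             transient = TRUE, transient_duration = 0.2,
                             transient_amplitudes = c(-1, 2, -1),
                             mixing = "crosstalk", noise_exponent = 1,
                             seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  if (!is_stimulus_grid(grid)) stop("`grid` must be a stimulus_grid", call. = FALSE)
  n_samples <- trial_duration * sample_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("trial_duration * sample_rate must be an integer number of samples",
         call. = FALSE)
  }
  if (length(harmonic_amplitudes) < 1L || any(harmonic_amplitudes < 0)) {
    stop("`harmonic_amplitudes` must be non-empty and non-negative", call. = FALSE)
  }
  if (transient && transient_duration >= trial_duration) {
    stop("transient duration must be shorter than the trial", call. = FALSE)
  }
  if (is.matrix(mixing)) {
    if (!all(dim(mixing) == n_channels)) {
      stop("`mixing` matrix must be n_channels x n_channels", call. = FALSE)
    }
  } else if (!mixing %in% c("identity", "crosstalk")) {
    stop('`mixing` must be "identity", "crosstalk" or a matrix', call. = FALSE)
  }
  structure(
    list(grid = grid, sample_rate = sample_rate,
         trial_duration = trial_duration, n_samples = as.integer(round(n_samples)),
         n_blocks = as.integer(n_blocks), n_channels = as.integer(n_channels),
         harmonic_amplitudes = harmonic_amplitudes, snr_db = snr_db,
         phase_mode = phase_mode, transient = isTRUE(transient),
         transient_duration = transient_duration,
         transient_amplitudes = transient_amplitudes,
         mixing = mixing, noise_exponent = noise_exponent,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Resolve the channel-mixing matrix for a config (deterministic in cfg$seed).
mixing_matrix <- function(cfg) {
  if (is.matrix(cfg$mixing)) return(cfg$mixing)
  if (identical(cfg$mixing, "identity")) return(diag(cfg$n_channels))
  # identity + small seeded cross-talk; 0.1 keeps the condition number well
  # below 10 for 8 channels
  rng <- local({ set.seed(cfg$seed + 777L); matrix(stats::rnorm(cfg$n_channels^2),
                                                   cfg$n_channels) })
  diag(cfg$n_channels) + 0.1 * rng
}

# Noise-free steady-state source waveform for stimulus k at phase phi.
steady_state_source <- function(cfg, stimulus_index, phase) {
  f <- cfg$grid$frequencies[stimulus_index]
  t <- seq_len(cfg$n_samples) / cfg$sample_rate
  s <- numeric(cfg$n_samples)
  for (h in seq_along(cfg$harmonic_amplitudes)) {
    s <- s + cfg$harmonic_amplitudes[h] * sin(2 * pi * h * f * t + h * phase)
  }
  s
}

# Transient N75/P100/N135 complex: raised-cosine lobes (60 ms wide) centered
# at 75/100/135 ms, zero outside the transient window.
transient_waveform <- function(cfg) {
  w <- numeric(cfg$n_samples)
  if (!cfg$transient) return(w)
  t <- (seq_len(cfg$n_samples) - 1) / cfg$sample_rate
  centers <- c(0.075, 0.100, 0.135)
  width <- 0.060
  for (j in seq_along(centers)) {
    lobe <- abs(t - centers[j]) < width / 2
    w[lobe] <- w[lobe] + cfg$transient_amplitudes[j] *
      0.5 * (1 + cos(2 * pi * (t[lobe] - centers[j]) / width))
  }
  w[t >= cfg$transient_duration] <- 0
  w
}

# One realization of bandlimited (1-100 Hz) 1/f^a Gaussian noise, unit power.
colored_noise <- function(n, sample_rate, exponent) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0, seq_len(n - 1)) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)   # two-sided magnitude
  gain <- ifelse(freqs >= 1 & freqs <= 100, 1 / freqs^(exponent / 2), 0)
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  p <- mean(x^2)
  if (p <= 0) stop("degenerate noise band", call. = FALSE)
  x / sqrt(p)
}

#' Generate one synthetic SSVEP trial
#'
#' Builds `mixing %*% (steady state + transient)` per channel and adds
#' independent colored noise scaled so each channel attains the configured
#' steady-state-to-noise ratio. Deterministic given `seed`.
#'
#' @param cfg a [generator_config()].
#' @param stimulus_index stimulus to simulate, in `1..grid$K`.
#' @param seed integer seed for this trial's randomness (phase and noise);
#'   defaults to a value derived from `cfg$seed` and the stimulus.
#' @return numeric matrix `[channel, sample]` in microvolts.
#' @export
generate_trial <- function(cfg, stimulus_index,
                           seed = cfg$seed + 131L * stimulus_index) {
  if (stimulus_index < 1L || stimulus_index > cfg$grid$K) {
    stop(sprintf("stimulus_index must be in [1, %d]", cfg$grid$K), call. = FALSE)
  }
  set.seed(seed %% .Machine$integer.max)
  phase <- if (cfg$phase_mode == "random") stats::runif(1, 0, 2 * pi) else 0
  src <- steady_state_source(cfg, stimulus_index, phase) + transient_waveform(cfg)
  M <- mixing_matrix(cfg)
  # every source channel carries the response; mixing yields per-channel gains
  clean <- M %*% matrix(rep(src, each = cfg$n_channels), nrow = cfg$n_channels)
  ss_only <- M %*% matrix(rep(steady_state_source(cfg, stimulus_index, phase),
                              each = cfg$n_channels), nrow = cfg$n_channels)
  out <- clean
  snr_lin <- 10^(cfg$snr_db / 10)
  for (ch in seq_len(cfg$n_channels)) {
    p_sig <- mean(ss_only[ch, ]^2)
    noise <- colored_noise(cfg$n_samples, cfg$sample_rate, cfg$noise_exponent)
    out[ch, ] <- out[ch, ] + noise * sqrt(p_sig / snr_lin)
  }
  unname(out)
}

#' Generate a full synthetic SSVEP dataset
#'
#' One trial per stimulus per block, with the presentation order randomized
#' within each block (seeded), mirroring the cued random-target protocol.
#'
#' @param cfg a [generator_config()].
#' @return an [epoch_array()] with `n_blocks * K` trials.
#' @export
generate_dataset <- function(cfg) {
  K <- cfg$grid$K
  nt <- cfg$n_blocks * K
  dat <- array(NA_real_, dim = c(nt, cfg$n_channels, cfg$n_samples))
  labels <- integer(nt)
  blocks <- integer(nt)
  i <- 1L
  for (b in seq_len(cfg$n_blocks)) {
    set.seed((cfg$seed + 7919L * b) %% .Machine$integer.max)
    order_k <- sample.int(K)
    for (k in order_k) {
      trial_seed <- (cfg$seed + 7919L * b + 131L * k) %% .Machine$integer.max
      dat[i, , ] <- generate_trial(cfg, k, seed = trial_seed)
      labels[i] <- k
      blocks[i] <- b
      i <- i + 1L
    }
  }
  epoch_array(dat, sample_rate = cfg$sample_rate, grid = cfg$grid,
              labels = labels, block_ids = blocks,
              channel_names = if (cfg$n_channels == 8L) SSVEP_CHANNELS else
                paste0("ch", seq_len(cfg$n_channels)))
}
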
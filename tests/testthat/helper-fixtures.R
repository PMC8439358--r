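# Small generator configurations used across tests. Sizes are kept modest so
# the full suite runs quickly; the statistical conditions (grid, rates,
# harmonics) are the package defaults.

small_grid <- function() stimulus_grid(c(9.25, 10.25, 11.75))

# Clean, stimulus-locked epochs for detector round-trips.
clean_epochs <- function(n_blocks = 2, snr_db = 10, grid = stimulus_grid(),
                         seed = 3, phase_mode = "fixed", ...) {
  cfg <- generator_config(grid = grid, n_blocks = n_blocks, snr_db = snr_db,
                          phase_mode = phase_mode, seed = seed, ...)
  generate_dataset(cfg)
}

# Biweight midcorrelation recomputed from its definition with the location
# and scale statistics supplied from outside (used as the finite-difference
# oracle for the frozen-statistic gradient).
bicor_given_stats <- function(x, y, med_x, mad_x) {
  norm_dev <- function(v, med, mad) {
    u <- (v - med) / (9 * mad)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    cvec <- (v - med) * w
    cvec / sqrt(sum(cvec^2))
  }
  xt <- norm_dev(x, med_x, mad_x)
  yt <- norm_dev(y, median(y), median(abs(y - median(y))))
  sum(xt * yt)
}
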
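test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy_percent(9, 0, 3, 0), 75)
  expect_equal(accuracy_percent(5, 3, 0, 0), 100)
  expect_equal(accuracy_percent(0, 0, 2, 3), 0)
  expect_error(accuracy_percent(0, 0, 0, 0), "positive")
  expect_error(accuracy_percent(-1), "non-negative")
})

test_that("bits per trial has the right limits and monotonicity", {
  expect_equal(bits_per_trial(12, 1), log2(12))
  expect_equal(bits_per_trial(12, 1 / 12), 0, tolerance = 1e-12)
  expect_equal(bits_per_trial(12, 0.9), 2.77, tolerance = 1e-3)
  expect_error(bits_per_trial(12, 0), "0, 1")
  expect_error(bits_per_trial(1, 0.5), ">= 2")
  expect_warning(bits_per_trial(12, 0.05), "chance")
  # strictly increasing on (1/N, 1]
  p <- seq(1 / 12 + 0.01, 1, length.out = 50)
  b <- vapply(p, function(pp) bits_per_trial(12, pp), numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("ITR scales with the decision period", {
  expect_equal(itr_bits_per_min(12, 0.9, 60, gaze_seconds = 0),
               bits_per_trial(12, 0.9))
  a <- itr_bits_per_min(12, 0.8, 1, 1)
  b <- itr_bits_per_min(12, 0.8, 3, 1)
  expect_equal(a / b, 2)       # (3+1)/(1+1)
  expect_error(itr_bits_per_min(12, 0.9, 0), "positive")
})

test_that("coefficient of variation is scale-invariant", {
  x <- c(10, 12, 9, 11)
  expect_equal(cv_percent(x), 100 * sd(x) / mean(x))
  expect_equal(cv_percent(5 * x), cv_percent(x))
  expect_equal(cv_percent(rep(7, 10)), 0)
  expect_equal(cv_percent(mean = 86.14, sd = 2.37), 2.7513, tolerance = 1e-4)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("one-way ANOVA agrees with a textbook two-pass oracle", {
  set.seed(51)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    n_per <- sample(3:8, 1)
    d <- data.frame(approach = rep(letters[1:k], each = n_per),
                    y = rnorm(k * n_per, mean = rep(rnorm(k, sd = 2), each = n_per)))
    got <- one_way_anova(d, "y")
    # oracle: explicit sums
    gm <- mean(d$y)
    means <- tapply(d$y, d$approach, mean)
    ss_t <- sum(n_per * (means - gm)^2)
    ss_e <- sum((d$y - means[d$approach])^2)
    expect_equal(got$ss[1], ss_t, tolerance = 1e-8)
    expect_equal(got$ss[2], ss_e, tolerance = 1e-8)
    expect_equal(got$ss[3], got$ss[1] + got$ss[2], tolerance = 1e-8)
    f_oracle <- (ss_t / (k - 1)) / (ss_e / (k * n_per - k))
    expect_equal(got$f[1], f_oracle, tolerance = 1e-8)
  }
  # identical groups: F = 0
  d0 <- data.frame(approach = rep(c("a", "b", "c"), each = 4),
                   y = rep(c(1, 2, 3, 4), 3))
  expect_equal(one_way_anova(d0, "y")$f[1], 0)
  expect_error(one_way_anova(data.frame(approach = "a", y = 1), "y"), "groups")
})

test_that("Tukey critical difference and declarations behave", {
  expect_equal(tukey_critical_difference(3.32, 14.19, 719), 0.466,
               tolerance = 1e-3)
  expect_equal(tukey_critical_difference(1, 0, 10), 0)
  expect_error(tukey_critical_difference(-1, 1, 10), "positive")
  set.seed(52)
  for (rep in 1:20) {
    d <- data.frame(approach = rep(c("a", "b", "c"), each = 10),
                    y = rnorm(30, rep(rnorm(3, sd = 3), each = 10)))
    tt <- tukey_test(d, "y")
    cmp <- tt$comparisons
    expect_true(all(cmp$diff >= 0))
    # consistency with mean ordering: if the extreme pair is non-significant,
    # no nested pair can be significant
    means <- sort(tapply(d$y, d$approach, mean))
    extreme <- abs(means[3] - means[1])
    if (extreme <= tt$dvs) expect_true(!any(cmp$significant))
    # declarations follow the threshold exactly
    expect_equal(cmp$significant, cmp$diff > tt$dvs)
  }
})

test_that("sliding-window experiment yields the expected grid and ceiling", {
  ep <- clean_epochs(n_blocks = 1, grid = small_grid(), trial_duration = 1.25,
                     snr_db = 60, transient = FALSE)
  refs <- build_references(ep$grid, 3, 256, 256)
  spec <- window_spec(256, step_samples = 16)
  out <- sliding_window_experiment(ep, list(cca = detector_cca(refs)), spec)
  n_pos <- length(window_starts(spec, 320))
  expect_equal(nrow(out$observations), n_pos)
  expect_true(all(out$observations$accuracy == 100))
  expect_equal(out$summary$cv[out$summary$response == "accuracy"], 0)
  expect_equal(out$observations$itr,
               rep(itr_bits_per_min(3, 1, 1, 1), n_pos))
})

test_that("window-length sweep finds the ITR-optimal operating point", {
  ep <- clean_epochs(n_blocks = 2, grid = small_grid(), trial_duration = 1,
                     snr_db = 60, transient = FALSE)
  factories <- list(cca = function(T_w) {
    refs <- build_references(ep$grid, 3, T_w, 256)
    detector_cca(refs)
  })
  sweep <- window_length_sweep(ep, factories, lengths_seconds = c(0.5, 1))
  expect_equal(nrow(sweep$table), 2L)
  expect_true(all(sweep$table$accuracy == 100))
  # at perfect accuracy the shortest window maximizes ITR
  expect_equal(sweep$best$window_seconds, 0.5)
  expect_error(window_length_sweep(ep, factories, lengths_seconds = 2),
               "bounds")
})

test_that("user aggregation averages columns and can drop the worst user", {
  per_user <- data.frame(user = paste0("u", 1:4),
                         accuracy = c(80, 90, 20, 70),
                         itr = c(50, 60, 5, 40))
  all_users <- aggregate_users(per_user)
  expect_equal(all_users[["accuracy"]], 65)
  trimmed <- aggregate_users(per_user, drop_lowest_by = "accuracy")
  expect_equal(trimmed[["accuracy"]], 80)
  expect_equal(trimmed[["itr"]], 50)
})
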
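# helper: hand-built model wrapping explicit forward parameters
manual_model <- function(W, b, wt, bt) {
  d <- nrow(W); m <- ncol(W)
  structure(list(
    forward_x = list(W = W, b = b, wt = wt, bt = bt),
    forward_y = list(W = W, b = b, wt = wt, bt = bt),
    x_center = rep(0, d), x_scale = rep(1, d),
    y_center = rep(0, d), y_scale = rep(1, d)),
    class = "nlcca_model")
}

test_that("forward_map is the tanh network it claims to be", {
  set.seed(41)
  X <- matrix(rnorm(20 * 3), 20, 3)
  # all-zero parameters: u = 0 everywhere
  m0 <- manual_model(matrix(0, 3, 4), rep(0, 4), rep(0, 4), 0)
  expect_equal(forward_map(m0, X, standardize = FALSE), rep(0, 20))
  # tiny weights: linear regime, u ~ X (W wt)
  W <- matrix(rnorm(12), 3, 4) * 1e-4
  wt <- rnorm(4)
  m1 <- manual_model(W, rep(0, 4), wt, 0)
  u <- forward_map(m1, X, standardize = FALSE)
  u_lin <- as.numeric(X %*% (W %*% wt))
  expect_lt(max(abs(u - u_lin)) / max(abs(u_lin)), 1e-6)
  # dimension mismatch
  expect_error(forward_map(m1, matrix(0, 5, 2)), "expects")
})

test_that("cost_c1 matches its closed-form anchors", {
  set.seed(42)
  u <- rnorm(500)
  u <- (u - mean(u)) / sqrt(mean((u - mean(u))^2))   # <u> = 0, <u^2> = 1
  expect_equal(cost_c1(u, u, correlation = "pearson"), -1, tolerance = 1e-12)
  expect_equal(cost_c1(u, u, correlation = "bicor"), -1, tolerance = 1e-3)
  # independent standardized variates: C1 ~ 0
  v <- rnorm(20000); v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  w <- rnorm(20000); w <- (w - mean(w)) / sqrt(mean((w - mean(w))^2))
  expect_lt(abs(cost_c1(v, w, correlation = "pearson")), 0.05)
  # penalty is linear in P1
  Wx <- matrix(1:6 / 10, 2, 3); Wy <- matrix(1, 2, 2)
  base <- cost_c1(u, u, correlation = "pearson")
  c_a <- cost_c1(u, u, Wx, Wy, P1 = 0.2, correlation = "pearson")
  c_b <- cost_c1(u, u, Wx, Wy, P1 = 0.4, correlation = "pearson")
  expect_equal(c_b - base, 2 * (c_a - base), tolerance = 1e-12)
})

test_that("reconstruction costs implement elementwise MAE/MSE plus penalty", {
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(cost_reconstruction(x, x), 0)
  expect_equal(cost_reconstruction(x + 1, x, loss = "mae"), 1)
  expect_equal(cost_reconstruction(x + 1, x, loss = "mse"), 1)
  expect_equal(cost_reconstruction(x - 2, x, loss = "mae"), 2)
  expect_equal(cost_reconstruction(x - 2, x, loss = "mse"), 4)
  expect_equal(cost_reconstruction(x, x, w = c(1, 2), P = 0.5), 2.5)
  expect_error(cost_reconstruction(x, x[1:5, ]), "shape")
})

test_that("training is deterministic, monotone per restart, and keeps the best", {
  set.seed(43)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- cbind(X[, 1] + 0.1 * rnorm(n), rnorm(n))
  m1 <- train_nlcca(X, Y, restarts = 3, maxit = 60, seed = 7)
  m2 <- train_nlcca(X, Y, restarts = 3, maxit = 60, seed = 7)
  expect_identical(m1$forward_x, m2$forward_x)
  expect_identical(m1$inverse_y, m2$inverse_y)
  d <- m1$diagnostics$restarts
  expect_true(all(d$c1_final <= d$c1_init))
  expect_equal(m1$diagnostics$C1, min(d$c1_final))
  # variates near zero mean / unit second moment under the C1 constraints
  expect_lt(abs(mean(m1$u)), 0.1)
  expect_lt(abs(sqrt(mean(m1$u^2)) - 1), 0.1)
  expect_lt(abs(sqrt(mean(m1$v^2)) - 1), 0.1)
  expect_error(train_nlcca(X[1:10, ], Y[1:10, ]), "at least 30")
})

test_that("on linear data NLCCA approaches the linear CCA optimum as P1 grows", {
  set.seed(44)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3)
  A <- matrix(rnorm(6), 2, 3)
  Y <- X %*% t(A) + 0.1 * matrix(rnorm(n * 2), n, 2)
  rho_lin <- cca_fit(t(X), t(Y))$rho[1]
  m <- train_nlcca(X, Y, P1 = 10, restarts = 2, maxit = 250, seed = 2)
  expect_lt(abs(abs(bicor(m$u, m$v)) - rho_lin), 0.05)
  # nonlinearity (residual of the best linear map) shrinks as P1 grows
  dev_from_linear <- function(P1) {
    mm <- train_nlcca(X, Y, P1 = P1, restarts = 2, maxit = 250, seed = 2)
    mean(stats::lm.fit(cbind(1, X), mm$u)$residuals^2) / mean(mm$u^2)
  }
  devs <- vapply(c(0.01, 0.1, 1, 10), dev_from_linear, numeric(1))
  expect_true(all(diff(devs) <= 0.02))   # non-increasing up to optimizer noise
})

test_that("NLCCA uncovers a quadratic relation invisible to linear CCA", {
  set.seed(45)
  n <- 2000
  z <- runif(n, -1, 1)
  X <- cbind(z, 0.5 * z) + 0.05 * matrix(rnorm(2 * n), n, 2)
  Y <- cbind(z^2, 1 - z^2) + 0.05 * matrix(rnorm(2 * n), n, 2)
  rho_lin <- cca_fit(t(X), t(Y))$rho[1]
  m <- train_nlcca(X, Y, P1 = 0.01, restarts = 3, maxit = 400, seed = 4)
  expect_gte(abs(bicor(m$u, m$v)) - rho_lin, 0.1)
})

test_that("inverse maps reconstruct the training views", {
  set.seed(46)
  n <- 300
  z <- rnorm(n)
  X <- cbind(z, -z) + 0.05 * matrix(rnorm(2 * n), n, 2)
  Y <- cbind(z, 2 * z) + 0.05 * matrix(rnorm(2 * n), n, 2)
  m <- train_nlcca(X, Y, restarts = 2, maxit = 200, seed = 3)
  xhat <- inverse_map(m, m$u, view = "x")
  Xs <- scale(X)
  expect_lt(mean(abs(xhat - Xs)), 0.25)   # strong 1-D structure: small MAE
  expect_equal(m$diagnostics$C2,
               cost_reconstruction(xhat, Xs, m$inverse_x$w, m$P2, "mae"))
})

test_that("model JSON serialization round-trips the fitted mappings", {
  set.seed(47)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- cbind(X[, 1] + 0.1 * rnorm(n), rnorm(n))
  m <- train_nlcca(X, Y, restarts = 1, maxit = 50, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  save_nlcca_model(m, f)
  m2 <- load_nlcca_model(f)
  expect_lt(max(abs(forward_map(m, X) - forward_map(m2, X))), 1e-12)
  expect_lt(max(abs(inverse_map(m, m$u) - inverse_map(m2, m$u))), 1e-12)
  expect_equal(m2$diagnostics$C1, m$diagnostics$C1)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(load_nlcca_model(bad), "not an ssvepr")
})

test_that("template classification recovers stimuli and flags pure noise", {
  ep <- clean_epochs(n_blocks = 2, grid = small_grid(), snr_db = 10, seed = 6)
  refs <- build_references(ep$grid, 3, 256, 256)
  train <- subset_trials(ep, ep$block_ids == 1)
  test <- subset_trials(ep, ep$block_ids == 2)
  tmpl <- train_ssvep_templates(train, refs, restarts = 2, maxit = 120, seed = 5)
  for (i in seq_len(n_trials(test))) {
    res <- nlcca_classify(trial_matrix(test, i)[, 1:256], tmpl)
    expect_equal(res$decided, test$labels[i])
  }
  # inference determinism
  w <- trial_matrix(test, 1)[, 1:256]
  expect_identical(nlcca_classify(w, tmpl), nlcca_classify(w, tmpl))
  # pure-noise window: small scores, low-confidence flag
  set.seed(99)
  noise <- matrix(rnorm(8 * 256), 8)
  nr <- nlcca_classify(noise, tmpl)
  expect_lt(max(abs(nr$scores)), 0.5)
  expect_true(nr$low_confidence)
  expect_error(nlcca_classify(noise[, 1:100], tmpl), "trained on")
})
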
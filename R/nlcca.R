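# Robust nonlinear CCA: double-barreled single-hidden-layer tanh networks
# mapping each view to a canonical variate, trained by minimizing the
# correlation cost C1 (biweight midcorrelation by default), plus inverse
# mapping networks reconstructing each view from its variate under MAE costs.

# ---- parameter packing ------------------------------------------------------

fwd_par_count <- function(d, m) d * m + m + m + 1L

unpack_forward <- function(theta, d, m) {
  stopifnot(length(theta) == fwd_par_count(d, m))
  i <- 0L
  W <- matrix(theta[seq_len(d * m)], d, m); i <- d * m
  b <- theta[i + seq_len(m)]; i <- i + m
  wt <- theta[i + seq_len(m)]; i <- i + m
  bt <- theta[i + 1L]
  list(W = W, b = b, wt = wt, bt = bt)
}

pack_forward <- function(p) c(as.vector(p$W), p$b, p$wt, p$bt)

# Single-hidden-layer tanh net with linear output: X is n x d (rows =
# samples), returns list(u = n-vector, H = n x m hidden activations).
fwd_eval <- function(p, X) {
  Z <- X %*% p$W + matrix(p$b, nrow(X), length(p$b), byrow = TRUE)
  H <- tanh(Z)
  list(u = as.numeric(H %*% p$wt + p$bt), H = H)
}

# Backprop dL/dparams given dL/du (g, n-vector).
fwd_grad <- function(p, X, H, g) {
  dH <- (g %o% p$wt) * (1 - H^2)
  list(W = crossprod(X, dH), b = colSums(dH),
       wt = as.numeric(crossprod(H, g)), bt = sum(g))
}

# ---- cost functions ---------------------------------------------------------

#' Double-barreled correlation cost C1
#'
#' `-cor(u, v) + <u>^2 + <v>^2 + (<u^2>^(1/2) - 1)^2 + (<v^2>^(1/2) - 1)^2 +
#' P1 * (sum(Wx^2) + sum(Wy^2))`: the negative (bi)correlation plus
#' zero-mean/unit-variance constraint terms for both variates and an L2
#' penalty on the hidden-layer weights of the two barrels only. At the ideal
#' solution (perfectly correlated standardized variates, weights ignored)
#' C1 = -1.
#'
#' @param u,v canonical variates (equal length).
#' @param Wx,Wy hidden-layer weight matrices entering the penalty (optional).
#' @param P1 weight-penalty coefficient.
#' @param correlation `"bicor"` (robust, default) or `"pearson"`.
#' @export
cost_c1 <- function(u, v, Wx = NULL, Wy = NULL, P1 = 0,
                    correlation = c("bicor", "pearson")) {
  correlation <- match.arg(correlation)
  stopifnot(length(u) == length(v))
  r <- if (correlation == "bicor") bicor(u, v) else stats::cor(u, v)
  if (!is.finite(r)) stop("degenerate variates in cost_c1", call. = FALSE)
  pen <- P1 * (sum(Wx^2) + sum(Wy^2))
  -r + mean(u)^2 + mean(v)^2 +
    (sqrt(mean(u^2)) - 1)^2 + (sqrt(mean(v^2)) - 1)^2 + pen
}

#' Inverse-mapping reconstruction cost (C2 / C3)
#'
#' Elementwise mean reconstruction loss — MAE by default, the robust choice;
#' MSE selectable — plus `P` times the squared input-layer weights of the
#' inverse network.
#'
#' @param xhat,x reconstruction and target (equal shape).
#' @param w input-layer weight vector of the inverse network (optional).
#' @param P weight-penalty coefficient.
#' @param loss `"mae"` or `"mse"`.
#' @export
cost_reconstruction <- function(xhat, x, w = NULL, P = 0,
                                loss = c("mae", "mse")) {
  loss <- match.arg(loss)
  if (length(xhat) != length(x)) stop("shape mismatch", call. = FALSE)
  e <- as.numeric(xhat) - as.numeric(x)
  base <- if (loss == "mae") mean(abs(e)) else mean(e^2)
  base + P * sum(w^2)
}

# Correlation term and its gradient wrt u (v fixed).
cor_and_grad_u <- function(u, v, correlation) {
  if (correlation == "bicor") {
    r <- bicor(u, v)
    list(r = r, g = bicor_gradient_full(u, v))
  } else {
    eu <- u - mean(u); ev <- v - mean(v)
    Du <- sqrt(sum(eu^2)); Dv <- sqrt(sum(ev^2))
    ut <- eu / Du; vt <- ev / Dv
    r <- sum(ut * vt)
    list(r = r, g = (vt - r * ut) / Du)
  }
}

# dC1/du for the constraint terms (excluding the correlation and penalty).
constraint_grad <- function(u) {
  n <- length(u)
  m2 <- mean(u^2)
  2 * mean(u) / n + 2 * (sqrt(m2) - 1) * u / (n * sqrt(m2))
}

# ---- training ---------------------------------------------------------------

#' Train a robust nonlinear CCA model
#'
#' Fits the double-barreled forward networks by quasi-Newton minimization of
#' [cost_c1()] (analytic gradients: the biweight-midcorrelation derivative
#' chained through the tanh layers), restarted from several small random
#' initializations with the best restart kept by final C1. The inverse
#' mapping networks are then fitted by minimizing the reconstruction costs C2
#' and C3 (MAE by default, smoothed for optimization). Inputs are
#' standardized internally; the constants are stored in the model.
#'
#' @param X view-1 samples, matrix `[n x d_x]` (rows are observations, e.g.
#'   time samples; columns are variables, e.g. channels). `n >= 30`.
#' @param Y view-2 samples, matrix `[n x d_y]`.
#' @param hidden hidden-layer size of each forward barrel and inverse map.
#' @param P1,P2,P3 weight penalties of C1, C2, C3.
#' @param restarts random restarts for the forward stage.
#' @param maxit iteration cap per optimization.
#' @param tol relative tolerance on cost change.
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param correlation `"bicor"` (robust) or `"pearson"`.
#' @param loss reconstruction loss, `"mae"` (robust) or `"mse"`.
#' @return object of class `nlcca_model` with the network parameters,
#'   standardization constants, training variates `u`, `v` and diagnostics
#'   (per-restart initial/final C1, final C1/C2/C3).
#' @export
train_nlcca <- function(X, Y, hidden = 4L, P1 = 0.1, P2 = 0.01, P3 = 0.01,
                        restarts = 5L, maxit = 500L, tol = 1e-6, seed = 1L,
                        correlation = c("bicor", "pearson"),
                        loss = c("mae", "mse")) {
  correlation <- match.arg(correlation)
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows",
                               call. = FALSE)
  if (nrow(X) < 30L) stop("need at least 30 samples", call. = FALSE)
  std <- function(M) {
    ctr <- colMeans(M); scl <- apply(M, 2L, stats::sd)
    if (any(scl <= 0)) stop("constant column in training data", call. = FALSE)
    list(ctr = ctr, scl = scl, Z = sweep(sweep(M, 2L, ctr), 2L, scl, "/"))
  }
  sx <- std(X); sy <- std(Y)
  Xs <- sx$Z; Ys <- sy$Z
  dx <- ncol(Xs); dy <- ncol(Ys); m <- as.integer(hidden)
  nx <- fwd_par_count(dx, m); ny <- fwd_par_count(dy, m)

  c1_fn <- function(theta) {
    px <- unpack_forward(theta[seq_len(nx)], dx, m)
    py <- unpack_forward(theta[nx + seq_len(ny)], dy, m)
    fu <- fwd_eval(px, Xs); fv <- fwd_eval(py, Ys)
    val <- tryCatch(
      cost_c1(fu$u, fv$u, px$W, py$W, P1, correlation),
      error = function(e) NA_real_)
    if (!is.finite(val)) 10 else val
  }
  c1_gr <- function(theta) {
    px <- unpack_forward(theta[seq_len(nx)], dx, m)
    py <- unpack_forward(theta[nx + seq_len(ny)], dy, m)
    fu <- fwd_eval(px, Xs); fv <- fwd_eval(py, Ys)
    cg <- tryCatch(cor_and_grad_u(fu$u, fv$u, correlation),
                   error = function(e) NULL)
    if (is.null(cg)) return(numeric(length(theta)))
    # symmetric gradient wrt v
    cgv <- tryCatch(cor_and_grad_u(fv$u, fu$u, correlation),
                    error = function(e) NULL)
    if (is.null(cgv)) return(numeric(length(theta)))
    gu <- -cg$g + constraint_grad(fu$u)
    gv <- -cgv$g + constraint_grad(fv$u)
    gx <- fwd_grad(px, Xs, fu$H, gu)
    gy <- fwd_grad(py, Ys, fv$H, gv)
    gx$W <- gx$W + 2 * P1 * px$W
    gy$W <- gy$W + 2 * P1 * py$W
    c(pack_forward(gx), pack_forward(gy))
  }

  best <- NULL
  diag_restarts <- data.frame(restart = integer(0), c1_init = numeric(0),
                              c1_final = numeric(0))
  for (r in seq_len(restarts)) {
    set.seed((seed + 1000L * r) %% .Machine$integer.max)
    theta0 <- stats::rnorm(nx + ny, sd = 0.1)
    c1_0 <- c1_fn(theta0)
    fit <- tryCatch(
      stats::optim(theta0, c1_fn, c1_gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = tol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    diag_restarts <- rbind(diag_restarts,
                           data.frame(restart = r, c1_init = c1_0,
                                      c1_final = fit$value))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("NLCCA training diverged in every restart", call. = FALSE)
  }
  px <- unpack_forward(best$par[seq_len(nx)], dx, m)
  py <- unpack_forward(best$par[nx + seq_len(ny)], dy, m)
  u <- fwd_eval(px, Xs)$u
  v <- fwd_eval(py, Ys)$u

  inv_x <- fit_inverse(u, Xs, m, P2, loss, maxit, tol, seed + 11L)
  inv_y <- fit_inverse(v, Ys, m, P3, loss, maxit, tol, seed + 13L)

  structure(
    list(forward_x = px, forward_y = py,
         inverse_x = inv_x$par, inverse_y = inv_y$par,
         hidden = m, P1 = P1, P2 = P2, P3 = P3,
         correlation = correlation, loss = loss,
         x_center = sx$ctr, x_scale = sx$scl,
         y_center = sy$ctr, y_scale = sy$scl,
         u = u, v = v,
         diagnostics = list(restarts = diag_restarts,
                            C1 = best$value, C2 = inv_x$value,
                            C3 = inv_y$value)),
    class = "nlcca_model")
}

# Inverse mapping x_hat = Wt %*% tanh(w * u + b) + bt fitted by BFGS on the
# (smoothed) reconstruction cost.
fit_inverse <- function(u, Xs, m, P, loss, maxit, tol, seed) {
  n <- length(u); d <- ncol(Xs)
  npar <- m + m + d * m + d
  unpack <- function(th) {
    w <- th[seq_len(m)]
    b <- th[m + seq_len(m)]
    Wt <- matrix(th[2 * m + seq_len(d * m)], d, m)
    bt <- th[2 * m + d * m + seq_len(d)]
    list(w = w, b = b, Wt = Wt, bt = bt)
  }
  eps <- 1e-8
  fn <- function(th) {
    p <- unpack(th)
    H <- tanh(outer(u, p$w) + matrix(p$b, n, m, byrow = TRUE))
    E <- H %*% t(p$Wt) + matrix(p$bt, n, d, byrow = TRUE) - Xs
    base <- if (loss == "mae") mean(sqrt(E^2 + eps)) else mean(E^2)
    base + P * sum(p$w^2)
  }
  gr <- function(th) {
    p <- unpack(th)
    H <- tanh(outer(u, p$w) + matrix(p$b, n, m, byrow = TRUE))
    E <- H %*% t(p$Wt) + matrix(p$bt, n, d, byrow = TRUE) - Xs
    G <- if (loss == "mae") E / sqrt(E^2 + eps) / length(E) else
      2 * E / length(E)
    dWt <- crossprod(G, H)
    dbt <- colSums(G)
    dH <- G %*% p$Wt
    dZ <- dH * (1 - H^2)
    dw <- colSums(dZ * u) + 2 * P * p$w
    db <- colSums(dZ)
    c(dw, db, as.vector(dWt), dbt)
  }
  set.seed(seed %% .Machine$integer.max)
  th0 <- stats::rnorm(npar, sd = 0.1)
  fit <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  p <- unpack(fit$par)
  # report the exact (unsmoothed) cost
  H <- tanh(outer(u, p$w) + matrix(p$b, n, m, byrow = TRUE))
  xhat <- H %*% t(p$Wt) + matrix(p$bt, n, d, byrow = TRUE)
  list(par = p, value = cost_reconstruction(xhat, Xs, p$w, P, loss))
}

#' @export
print.nlcca_model <- function(x, ...) {
  cat(sprintf(
    "<nlcca_model> hidden %d, %s correlation, %s loss | C1 = %.4f, C2 = %.4f, C3 = %.4f\n",
    x$hidden, x$correlation, x$loss,
    x$diagnostics$C1, x$diagnostics$C2, x$diagnostics$C3))
  invisible(x)
}

#' Map new data through a fitted forward barrel
#'
#' Standardizes `newdata` with the model's stored constants (unless
#' `standardize = FALSE`) and evaluates the requested forward network.
#'
#' @param model an `nlcca_model`.
#' @param newdata matrix `[n x d]` with the view's variables as columns.
#' @param view `"x"` or `"y"`.
#' @param standardize apply the stored standardization first.
#' @return numeric vector: the canonical variate.
#' @export
forward_map <- function(model, newdata, view = c("x", "y"),
                        standardize = TRUE) {
  view <- match.arg(view)
  newdata <- as.matrix(newdata)
  p <- if (view == "x") model$forward_x else model$forward_y
  if (ncol(newdata) != nrow(p$W)) {
    stop(sprintf("newdata has %d variables but the %s barrel expects %d",
                 ncol(newdata), view, nrow(p$W)), call. = FALSE)
  }
  if (standardize) {
    ctr <- if (view == "x") model$x_center else model$y_center
    scl <- if (view == "x") model$x_scale else model$y_scale
    newdata <- sweep(sweep(newdata, 2L, ctr), 2L, scl, "/")
  }
  fwd_eval(p, newdata)$u
}

#' Reconstruct a view from its canonical variate
#'
#' Evaluates the fitted inverse mapping network; reconstructions are on the
#' standardized scale unless `rescale = TRUE`.
#'
#' @param model an `nlcca_model`.
#' @param variate numeric vector `u` (for `view = "x"`) or `v`.
#' @param view which view to reconstruct.
#' @param rescale undo the training standardization.
#' @return matrix `[n x d]` of reconstructions.
#' @export
inverse_map <- function(model, variate, view = c("x", "y"), rescale = FALSE) {
  view <- match.arg(view)
  p <- if (view == "x") model$inverse_x else model$inverse_y
  n <- length(variate); m <- length(p$w)
  H <- tanh(outer(variate, p$w) + matrix(p$b, n, m, byrow = TRUE))
  out <- H %*% t(p$Wt) + matrix(p$bt, n, nrow(p$Wt), byrow = TRUE)
  if (rescale) {
    ctr <- if (view == "x") model$x_center else model$y_center
    scl <- if (view == "x") model$x_scale else model$y_scale
    out <- sweep(sweep(out, 2L, scl, "*"), 2L, ctr, "+")
  }
  out
}

# ---- model serialization ----------------------------------------------------

#' Save / load an NLCCA model as JSON
#'
#' Serializes every network parameter, the standardization constants, the
#' hyperparameters, diagnostics and (if present) the stored template variate
#' at full double precision, so a round trip reproduces the model's mappings
#' exactly.
#'
#' @param model an `nlcca_model`.
#' @param path file to write / read.
#' @return `save_nlcca_model` returns `path` invisibly; `load_nlcca_model`
#'   returns the restored `nlcca_model`.
#' @export
save_nlcca_model <- function(model, path) {
  payload <- unclass(model)
  payload$format <- "ssvepr-nlcca-model"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_nlcca_model
#' @export
load_nlcca_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "ssvepr-nlcca-model")) {
    stop("not an ssvepr NLCCA model file", call. = FALSE)
  }
  raw$format <- NULL
  fix_net <- function(p, d, m) {
    p$W <- matrix(as.numeric(p$W), d, m)
    p
  }
  m <- raw$hidden
  raw$forward_x <- fix_net(raw$forward_x, length(raw$x_center), m)
  raw$forward_y <- fix_net(raw$forward_y, length(raw$y_center), m)
  fix_inv <- function(p, d, m) {
    p$Wt <- matrix(as.numeric(p$Wt), d, m)
    p
  }
  raw$inverse_x <- fix_inv(raw$inverse_x, length(raw$x_center), m)
  raw$inverse_y <- fix_inv(raw$inverse_y, length(raw$y_center), m)
  structure(raw, class = "nlcca_model")
}

# ---- SSVEP template training and classification -----------------------------

#' Train one NLCCA template model per stimulus
#'
#' For each stimulus, the x-view observations are the per-sample channel
#' vectors of its training windows (stacked over trials) and the y-view is the
#' stimulus' harmonic reference repeated per trial. The stored template `v_k`
#' is the y-barrel variate of the reference over a single window.
#'
#' @param epochs training [epoch_array()] (e.g. all but a held-out block).
#' @param refs a [build_references()] set defining the window length and
#'   harmonics; windows are taken from `start_sample` of each trial.
#' @param start_sample 0-based window start inside each trial.
#' @param ... passed to [train_nlcca()].
#' @return object of class `nlcca_template_set`: list of `nlcca_model`s (one
#'   per stimulus), each with a `template_v` field, plus the `refs` used.
#' @export
train_ssvep_templates <- function(epochs, refs, start_sample = 0L, ...) {
  T_w <- refs$T_samples
  idx <- (start_sample + 1L):(start_sample + T_w)
  models <- vector("list", refs$grid$K)
  for (k in seq_len(refs$grid$K)) {
    trials <- which(epochs$labels == k)
    if (length(trials) == 0L) {
      stop(sprintf("no training trials for stimulus %d", k), call. = FALSE)
    }
    Xk <- do.call(rbind, lapply(trials, function(i)
      t(trial_matrix(epochs, i)[, idx, drop = FALSE])))
    Yk <- do.call(rbind, rep(list(t(refs$Y[[k]])), length(trials)))
    model <- train_nlcca(Xk, Yk, ...)
    model$template_v <- forward_map(model, t(refs$Y[[k]]), view = "y")
    models[[k]] <- model
  }
  structure(list(models = models, refs = refs), class = "nlcca_template_set")
}

#' NLCCA template classification for one window
#'
#' Maps the window through each stimulus' x-barrel and scores it by the
#' biweight midcorrelation between the resulting variate and that stimulus'
#' stored template variate; the decided stimulus is the argmax (lowest index
#' on ties). A best score below `threshold` flags the decision as low
#' confidence.
#'
#' @param window `[channel, sample]` matrix or single-trial [epoch_array()].
#' @param templates an [train_ssvep_templates()] result.
#' @param threshold low-confidence cutoff on the best score.
#' @return a [detection_result()] with kind `"nlcca_bicor"`.
#' @export
nlcca_classify <- function(window, templates, threshold = 0.3) {
  X <- as_window_matrix(window)
  refs <- templates$refs
  if (ncol(X) != refs$T_samples) {
    stop(sprintf("window has %d samples but templates were trained on %d",
                 ncol(X), refs$T_samples), call. = FALSE)
  }
  scores <- vapply(templates$models, function(m) {
    u_hat <- forward_map(m, t(X), view = "x")
    tryCatch(bicor(u_hat, m$template_v), error = function(e) 0)
  }, numeric(1))
  detection_result(scores, "nlcca_bicor",
                   low_confidence = max(scores) < threshold)
}
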
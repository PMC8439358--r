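#' LASSO design matrix over all stimuli
#'
#' Stacks the harmonic sin/cos references of every stimulus into a
#' `T x (K * 2 * Nh)` design whose columns are unit-L2-normalized. Column
#' order is frequency-major: all `2*Nh` regressors of stimulus 1, then
#' stimulus 2, and so on.
#'
#' @param refs a [build_references()] set.
#' @return numeric matrix with a `frequency` attribute mapping each column to
#'   its stimulus index.
#' @export
lasso_design <- function(refs) {
  blocks <- lapply(refs$Y, t)
  X <- do.call(cbind, blocks)
  norms <- sqrt(colSums(X^2))
  X <- sweep(X, 2L, norms, "/")
  attr(X, "frequency") <- rep(seq_along(refs$Y), each = 2L * refs$Nh)
  X
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' LASSO fit by cyclic coordinate descent
#'
#' Minimizes `||y - X beta||_2^2 + lambda * ||beta||_1` (no factor 1/2, no
#' intercept) by coordinate-wise soft-thresholding. With unit-norm columns the
#' update is `beta_j <- soft(X_j' r + beta_j, lambda / 2)`.
#'
#' @param y numeric response vector (one channel's window).
#' @param X design matrix (`length(y)` rows).
#' @param lambda penalty, `>= 0`. `lambda >= 2 * max|X'y|` forces the exact
#'   zero solution.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep.
#' @param max_sweeps sweep budget; non-convergence is an error carrying the
#'   last iterate in its condition data.
#' @return object of class `lasso_estimate`: `beta`, `lambda`, `objective`
#'   (value per sweep, non-increasing), `sweeps`, `converged`.
#' @export
lasso_fit <- function(y, X, lambda, tol = 1e-7, max_sweeps = 10000L) {
  stopifnot(lambda >= 0, length(y) == nrow(X))
  p <- ncol(X)
  col_ss <- colSums(X^2)
  if (any(col_ss <= 0)) stop("zero column in LASSO design", call. = FALSE)
  beta <- numeric(p)
  r <- y
  obj <- function(b, res) sum(res^2) + lambda * sum(abs(b))
  objective <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(X[, j] * r) + bj_old * col_ss[j]
      bj_new <- soft_threshold(z, lambda / 2) / col_ss[j]
      if (bj_new != bj_old) {
        r <- r - X[, j] * (bj_new - bj_old)
        beta[j] <- bj_new
        delta_max <- max(delta_max, abs(bj_new - bj_old))
      }
    }
    objective <- c(objective, obj(beta, r))
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("ssvepr_lasso_nonconvergence", "error", "condition"),
      list(message = sprintf("LASSO did not converge in %d sweeps", max_sweeps),
           call = sys.call(-1), beta = beta))
    stop(cond)
  }
  structure(list(beta = beta, lambda = lambda, objective = objective,
                 sweeps = length(objective), converged = converged),
            class = "lasso_estimate")
}

#' @export
print.lasso_estimate <- function(x, ...) {
  cat(sprintf("<lasso_estimate> %d coefficients (%d nonzero), lambda = %g, %d sweeps\n",
              length(x$beta), sum(x$beta != 0), x$lambda, x$sweeps))
  invisible(x)
}

#' LASSO frequency detection for one window
#'
#' Fits one LASSO per channel against the all-stimulus harmonic design and
#' scores each stimulus by the channel-averaged sum of its coefficients
#' (signed by default; `use_abs = TRUE` sums magnitudes instead, which is
#' phase-agnostic). The decided stimulus is the argmax.
#'
#' @param window `[channel, sample]` matrix or single-trial [epoch_array()].
#' @param refs a [build_references()] set matching the window length.
#' @param lambda shared penalty for all channels; `NULL` picks
#'   `lambda_ratio * 2 * max|X'y|` per channel (a fixed fraction of each
#'   channel's deactivation bound).
#' @param lambda_ratio fraction of the deactivation bound used when `lambda`
#'   is `NULL`; see [lasso_calibrate_lambda()] for data-driven selection.
#' @param use_abs sum `|beta|` instead of signed coefficients.
#' @param ... passed to [lasso_fit()].
#' @return a [detection_result()] with kind `"lasso_contribution"`.
#' @export
lasso_classify <- function(window, refs, lambda = NULL, lambda_ratio = 0.1,
                           use_abs = FALSE, ...) {
  Xw <- as_window_matrix(window)
  if (ncol(Xw) != refs$T_samples) {
    stop(sprintf("window has %d samples but references were built for %d",
                 ncol(Xw), refs$T_samples), call. = FALSE)
  }
  D <- lasso_design(refs)
  freq_of <- attr(D, "frequency")
  K <- refs$grid$K
  N <- nrow(Xw)
  scores <- numeric(K)
  any_active <- FALSE
  for (ch in seq_len(N)) {
    y <- Xw[ch, ] - mean(Xw[ch, ])
    lam <- if (is.null(lambda)) lambda_ratio * 2 * max(abs(crossprod(D, y)))
           else lambda
    fit <- lasso_fit(y, D, lam, ...)
    if (any(fit$beta != 0)) any_active <- TRUE
    b <- if (use_abs) abs(fit$beta) else fit$beta
    scores <- scores + vapply(seq_len(K), function(f)
      sum(b[freq_of == f]), numeric(1))
  }
  scores <- scores / N
  detection_result(scores, "lasso_contribution", degenerate = !any_active)
}

#' Calibrate the LASSO penalty on a synthetic calibration set
#'
#' Grid-searches the `lambda_ratio` (fraction of the per-channel deactivation
#' bound) maximizing detection accuracy on held-out calibration epochs —
#' the offline, subject-independent penalty selection the detector assumes.
#'
#' @param epochs calibration [epoch_array()] (e.g. a synthetic dataset).
#' @param refs references matching the calibration window length.
#' @param ratios candidate `lambda_ratio` values.
#' @param ... passed to [lasso_classify()].
#' @return the ratio with the highest accuracy (ties toward the sparsest,
#'   i.e. largest, ratio), with the accuracy grid as attribute `"accuracy"`.
#' @export
lasso_calibrate_lambda <- function(epochs, refs,
                                   ratios = c(0.02, 0.05, 0.1, 0.2, 0.4), ...) {
  acc <- vapply(ratios, function(r) {
    correct <- vapply(seq_len(n_trials(epochs)), function(i) {
      w <- trial_matrix(epochs, i)[, seq_len(refs$T_samples), drop = FALSE]
      lasso_classify(w, refs, lambda_ratio = r, ...)$decided == epochs$labels[i]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  best <- ratios[max(which(acc == max(acc)))]
  attr(best, "accuracy") <- stats::setNames(acc, ratios)
  best
}
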
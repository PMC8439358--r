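#' Canonical correlation analysis between a window and a reference
#'
#' Standard CCA between the rows of `X` (EEG channels) and the rows of `Y`
#' (sinusoidal references), solved by whitening both covariances and taking
#' the SVD of the whitened cross-covariance. Nearly rank-deficient windows
#' stay solvable through a tiny relative ridge plus an eigenvalue floor in
#' the whitening step (with a warning); the regularization is small enough
#' that the canonical correlations are invariant (to 1e-8) under invertible
#' recombinations of either view's rows.
#'
#' @param X numeric matrix `[variables x observations]`, e.g. channels by
#'   samples; rows are centered internally.
#' @param Y numeric matrix `[variables x observations]` with the same number
#'   of columns.
#' @return object of class `cca_result`: `rho` (canonical correlations,
#'   descending, clipped to `[0, 1]`), `Wx`, `Wy` (weight matrices, one
#'   column per correlation; variates `t(X_c) %*% Wx` have unit sample
#'   variance).
#' @export
cca_fit <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || ncol(X) != ncol(Y)) {
    stop("X and Y must be matrices with the same number of columns", call. = FALSE)
  }
  n <- ncol(X)
  if (n <= nrow(X) + nrow(Y)) {
    stop("need more observations than total variables", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / (n - 1)
  Cyy <- tcrossprod(Yc) / (n - 1)
  Cxy <- tcrossprod(Xc, Yc) / (n - 1)
  tx <- sum(diag(Cxx)); ty <- sum(diag(Cyy))
  if (tx <= 0 || ty <= 0) stop("zero-variance input to cca_fit", call. = FALSE)
  # tiny relative ridge for strict positive-definiteness; rank deficiency is
  # handled by the eigenvalue floor in inv_sqrt_sym (with a warning)
  Cxx <- Cxx + diag(1e-12 * tx, nrow(X))
  Cyy <- Cyy + diag(1e-12 * ty, nrow(Y))
  Wxh <- inv_sqrt_sym(Cxx)
  Wyh <- inv_sqrt_sym(Cyy)
  sv <- svd(Wxh %*% Cxy %*% Wyh)
  rho <- pmin(pmax(sv$d, 0), 1)
  structure(list(rho = rho, Wx = Wxh %*% sv$u, Wy = Wyh %*% sv$v),
            class = "cca_result")
}

# Symmetric inverse square root; warns on rank deficiency.
inv_sqrt_sym <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    warning("rank-deficient covariance; regularized solve", call. = FALSE)
  }
  vals <- pmax(e$values, tol)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result> rho:", paste(sprintf("%.4f", x$rho), collapse = " "), "\n")
  invisible(x)
}

#' CCA frequency detection for one window
#'
#' Scores every stimulus by the leading canonical correlation between the
#' window and that stimulus' harmonic reference, then picks the argmax.
#'
#' @param window `[channel, sample]` matrix or single-trial [epoch_array()].
#' @param refs a [build_references()] set matching the window length and rate.
#' @return a [detection_result()] with kind `"cca_rho"`.
#' @export
cca_classify <- function(window, refs) {
  X <- as_window_matrix(window)
  if (ncol(X) != refs$T_samples) {
    stop(sprintf("window has %d samples but references were built for %d",
                 ncol(X), refs$T_samples), call. = FALSE)
  }
  if (all(abs(X - mean(X)) < .Machine$double.eps * 100)) {
    return(detection_result(rep(0, refs$grid$K), "cca_rho", degenerate = TRUE))
  }
  scores <- vapply(refs$Y, function(Yk) cca_fit(X, Yk)$rho[1L], numeric(1))
  detection_result(scores, "cca_rho")
}
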
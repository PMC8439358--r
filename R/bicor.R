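#' Lp norm
#'
#' `(sum(|e_i|^p))^(1/p)` for `p >= 1`.
#'
#' @param e numeric vector (non-empty).
#' @param p norm order.
#' @export
lp_norm <- function(e, p = 2) {
  if (length(e) == 0L) stop("`e` must be non-empty", call. = FALSE)
  if (p < 1) stop("`p` must be >= 1", call. = FALSE)
  sum(abs(e)^p)^(1 / p)
}

# Median absolute deviation without the Gaussian consistency factor.
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

# Biweight intermediates for one vector: scaled deviations u, weights w,
# weighted deviations c = (x - med) * w, and normalized deviations c / ||c||.
biweight_parts <- function(x, one_sided_indicator = FALSE) {
  med <- stats::median(x)
  mad <- raw_mad(x)
  if (mad <= 0) {
    stop("degenerate scale: mad is zero, biweight midcorrelation undefined",
         call. = FALSE)
  }
  u <- (x - med) / (9 * mad)
  ind <- if (one_sided_indicator) as.numeric(1 - u > 0) else
    as.numeric(abs(u) < 1)
  w <- (1 - u^2)^2 * ind
  cvec <- (x - med) * w
  D <- sqrt(sum(cvec^2))
  if (D <= 0) stop("degenerate scale: all biweights vanish", call. = FALSE)
  list(med = med, mad = mad, u = u, ind = ind, w = w, c = cvec, D = D,
       tilde = cvec / D)
}

#' Biweight midcorrelation
#'
#' Robust correlation built from median/MAD-scaled deviations downweighted by
#' the Tukey biweight: samples more than 9 raw MADs from the median get zero
#' weight, so a single gross outlier cannot dominate. Always lies in
#' `[-1, 1]`; for clean Gaussian data it closely tracks the Pearson
#' correlation. The MAD is used without the Gaussian consistency factor.
#'
#' @param x,y numeric vectors of equal length `>= 3` with nonzero MAD.
#' @param one_sided_indicator use the one-sided indicator `I(1 - u > 0)`
#'   instead of the standard two-sided `I(|u| < 1)` in the biweight. The
#'   standard form is the default; the one-sided variant keeps full weight on
#'   extreme negative deviations.
#' @param details also return the intermediates (medians, MADs, scaled
#'   deviations, weights, normalized deviations) as attribute
#'   `"intermediate"`.
#' @return the midcorrelation `delta` in `[-1, 1]`.
#' @export
bicor <- function(x, y, one_sided_indicator = FALSE, details = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  px <- biweight_parts(x, one_sided_indicator)
  py <- biweight_parts(y, one_sided_indicator)
  delta <- sum(px$tilde * py$tilde)
  delta <- min(1, max(-1, delta))
  if (details) {
    attr(delta, "intermediate") <- list(x = px, y = py)
  }
  delta
}

#' Gradient of the biweight midcorrelation in its first argument
#'
#' Analytic `d bicor(x, y) / d x_i` treating `med(x)` and `mad(x)` as locally
#' constant (they are piecewise constant in any single coordinate). With
#' `c_i = (x_i - med) w_i`, `D = ||c||`, and
#' `c'_i = (1 - u_i^2)(1 - 5 u_i^2) I(|u_i| < 1)`, the full chain rule gives
#' `(c'_i / D) * (y~_i - delta * x~_i)`; coordinates at zero weight
#' (`|u_i| >= 1`) contribute a zero weight-factor derivative.
#'
#' @inheritParams bicor
#' @return numeric vector of partial derivatives, same length as `x`.
#' @export
bicor_gradient <- function(x, y, one_sided_indicator = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  px <- biweight_parts(x, one_sided_indicator)
  py <- biweight_parts(y, one_sided_indicator)
  delta <- sum(px$tilde * py$tilde)
  cp <- (1 - px$u^2) * (1 - 5 * px$u^2) * px$ind
  (cp / px$D) * (py$tilde - delta * px$tilde)
}

# Subgradient of the sample median at x: mass on the middle order statistics.
median_subgrad <- function(x) {
  n <- length(x)
  g <- numeric(n)
  o <- order(x)
  if (n %% 2L == 1L) {
    g[o[(n + 1L) %/% 2L]] <- 1
  } else {
    g[o[c(n %/% 2L, n %/% 2L + 1L)]] <- 0.5
  }
  g
}

# Exact (almost-everywhere) gradient of bicor(x, y) in x, including the
# dependence of med(x) and mad(x) on x. The frozen-statistic form
# (bicor_gradient) is a poor search direction for joint parameter updates
# because bicor is invariant to positive affine maps of x, a structure only
# the med/mad terms encode. Used by NLCCA training.
bicor_gradient_full <- function(x, y) {
  px <- biweight_parts(x)
  py <- biweight_parts(y)
  delta <- sum(px$tilde * py$tilde)
  resid <- py$tilde - delta * px$tilde          # d delta / d c_i * D
  cp <- (1 - px$u^2) * (1 - 5 * px$u^2) * px$ind
  g_frozen <- (cp / px$D) * resid
  # d delta / d med and d delta / d mad
  ddelta_dmed <- -sum(resid * cp) / px$D
  ddelta_dmad <- sum(resid * 36 * px$u^3 * (1 - px$u^2) * px$ind) / px$D
  # d med / d x and d mad / d x (mad = median of |x - med|)
  dmed <- median_subgrad(x)
  b <- abs(x - px$med)
  q <- median_subgrad(b)
  r <- sign(x - px$med)
  dmad <- q * r - dmed * sum(q * r)
  g_frozen + ddelta_dmed * dmed + ddelta_dmad * dmad
}
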
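# Monotone quadratic B-spline regression.
#
# A nondecreasing fit is obtained by constraining the B-spline
# coefficients to be nondecreasing (sufficient for monotonicity of the
# spline itself). Writing the coefficients as a free intercept plus
# cumulative nonnegative increments turns the constrained least-squares
# problem into NNLS, solved by the Lawson-Hanson algorithm
# (pracma::lsqnonneg) after splitting the free intercept into its
# positive and negative parts.

quadratic_bspline_basis <- function(u, knots) {
  ord <- 3L  # quadratic
  boundary <- range(knots)
  aug <- c(rep(boundary[1L], ord - 1L), knots, rep(boundary[2L], ord - 1L))
  splines::splineDesign(aug, u, ord = ord, outer.ok = FALSE)
}

#' Fit a monotone nondecreasing quadratic B-spline
#'
#' Least-squares quadratic spline fit of `y` on `u` subject to a
#' monotone-nondecreasing constraint, as used for the shared
#' response curve of a dilution-series array. Knots are placed at
#' equally spaced quantiles of `u`; monotonicity is enforced through
#' nonnegativity of the first differences of the spline coefficients.
#'
#' @param u Numeric covariate (effective log-concentration, `x + d`).
#' @param y Numeric response (spot intensities), same length as `u`.
#' @param n_knots Number of interior+boundary knots; default
#'   `min(20, floor(n/10))` (at least 4).
#' @return An object of class `monotone_curve` with fields `knots`,
#'   `coefficients` and `domain`. Evaluate with [predict.monotone_curve()];
#'   evaluation outside the domain clamps to the boundary value.
#' @export
fit_monotone_curve <- function(u, y, n_knots = NULL) {
  keep <- is.finite(u) & is.finite(y)
  u <- u[keep]; y <- y[keep]
  if (length(u) < 5L) stop("need at least 5 points to fit the curve", call. = FALSE)
  if (diff(range(u)) <= 0) stop("degenerate u-range: all values equal", call. = FALSE)
  if (is.null(n_knots)) n_knots <- max(4L, min(20L, floor(length(u) / 10)))
  probs <- seq(0, 1, length.out = n_knots)
  knots <- unique(stats::quantile(u, probs, names = FALSE, type = 7))
  if (length(knots) < 2L) knots <- range(u)
  B <- quadratic_bspline_basis(u, knots)
  p <- ncol(B)
  # coefficients c = b0 + L %*% delta with delta >= 0 and b0 free;
  # profiling out b0 (projecting the intercept direction out of the
  # design and response) leaves a pure NNLS problem in delta
  L <- outer(seq_len(p), seq_len(p - 1L), function(i, j) as.numeric(i > j))
  ones <- rowSums(B)          # B %*% 1 (the intercept direction)
  W <- B %*% L
  proj <- function(v) v - ones * sum(ones * v) / sum(ones^2)
  MW <- apply(W, 2L, proj)
  fit <- pracma::lsqnonneg(MW, proj(y))
  delta <- fit$x
  b0 <- sum(ones * (y - W %*% delta)) / sum(ones^2)
  coefs <- b0 + as.vector(L %*% delta)
  structure(
    list(knots = knots, coefficients = coefs, domain = range(u)),
    class = "monotone_curve")
}

#' Evaluate a fitted monotone curve
#'
#' @param object A `monotone_curve`.
#' @param newdata Numeric vector of `u` values; values outside the
#'   fitted domain are clamped to the boundary.
#' @param ... Unused.
#' @return Numeric vector of fitted intensities.
#' @export
predict.monotone_curve <- function(object, newdata, ...) {
  u <- pmin(pmax(newdata, object$domain[1L]), object$domain[2L])
  B <- quadratic_bspline_basis(u, object$knots)
  as.vector(B %*% object$coefficients)
}

#' @export
print.monotone_curve <- function(x, ...) {
  cat(sprintf("Monotone quadratic B-spline: %d knots on [%.3g, %.3g]\n",
              length(x$knots), x$domain[1L], x$domain[2L]))
  invisible(x)
}

# Internal: generic evaluation of a response curve (monotone_curve,
# additive-model curve, or plain function) with boundary clamping.
eval_curve <- function(curve, u) {
  if (inherits(curve, "monotone_curve")) return(predict(curve, u))
  if (is.function(curve)) return(curve(u))
  if (inherits(curve, "additive_curve")) return(predict_additive_curve(curve, u))
  stop("unsupported curve object of class ", paste(class(curve), collapse = "/"))
}

curve_domain <- function(curve) {
  if (inherits(curve, "monotone_curve")) return(curve$domain)
  if (inherits(curve, "additive_curve")) return(curve$domain)
  stop("curve has no recorded domain; supply bounds explicitly")
}
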
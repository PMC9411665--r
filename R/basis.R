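## Penalized cubic B-spline basis for the smooth TAS effect.
##
## Knots are quantile-spaced over the observed covariate; the roughness
## penalty is built from second-order divided differences of the spline
## coefficients with respect to the Greville abscissae, so that its null
## space is exactly the constant and linear functions for any knot placement
## (plain second differences have that null space only for uniform knots).

#' Build a penalized B-spline basis
#'
#' @param x Covariate values (>= `k` distinct values required).
#' @param k Basis dimension (number of B-spline functions, default 10).
#' @param degree Spline degree (default 3, cubic).
#' @return List with `design` (column-centered basis, n x k), `design_raw`
#'   (uncentered; rows sum to 1), `penalty` (k x k, PSD, rank k-2, null
#'   space = coefficients representing affine functions), `knots` (full knot
#'   vector), `greville` (Greville abscissae), `k`, `degree`, `x_range`.
#' @export
build_penalized_basis <- function(x, k = 10, degree = 3) {
  xs <- sort(unique(x))
  if (length(xs) < k)
    ep_config_error("basis dimension k = %d exceeds the %d distinct covariate values",
                    k, length(xs))
  n_interior <- k - degree - 1
  a <- min(xs); b <- max(xs)
  # quantiles of the distinct covariate values: heavy ties (many identical
  # low-TAS occasions) must not collapse interior knots onto each other
  interior <- if (n_interior > 0) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    stats::quantile(xs, probs, type = 7, names = FALSE)
  } else numeric(0)
  interior <- interior[interior > a & interior < b]
  if (length(interior) != n_interior || anyDuplicated(interior))
    ep_config_error("tied covariate values leave too few distinct quantile knots for k = %d", k)
  knots <- c(rep(a, degree + 1), interior, rep(b, degree + 1))
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  greville <- vapply(seq_len(k), function(j)
    mean(knots[(j + 1):(j + degree)]), numeric(1))
  D <- matrix(0, k - 2, k)
  for (j in seq_len(k - 2)) {
    h1 <- greville[j + 1] - greville[j]
    h2 <- greville[j + 2] - greville[j + 1]
    D[j, j:(j + 2)] <- c(1 / h1, -(1 / h1 + 1 / h2), 1 / h2)
  }
  list(design = sweep(B, 2, colMeans(B)), design_raw = B,
       penalty = crossprod(D), knots = knots, greville = greville,
       k = k, degree = degree, x_range = c(a, b))
}

# Evaluate the raw basis at new x, extrapolating linearly beyond the
# training range (value + first derivative at the boundary).
basis_eval <- function(basis, x) {
  a <- basis$x_range[1]; b <- basis$x_range[2]
  ord <- basis$degree + 1
  xc <- pmin(pmax(x, a), b)
  B <- splines::splineDesign(basis$knots, xc, ord = ord)
  outside <- which(x < a | x > b)
  if (length(outside)) {
    Bd <- splines::splineDesign(basis$knots, xc[outside], ord = ord, derivs = 1)
    B[outside, ] <- B[outside, , drop = FALSE] + (x[outside] - xc[outside]) * Bd
  }
  B
}
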
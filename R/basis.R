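## Basis sets for the effect function and the score-transformation algebra.

#' Construct a basis for the effect function
#'
#' The effect function is parameterised as
#' \eqn{\beta(t) = \sum_{l=1}^L \gamma_l b_l(t)}. Two standard choices are
#' supported: the FPCA eigenfunctions themselves (in which case the
#' transformation matrix is the identity and the fitted coefficients are the
#' pseudo-exposure effects directly), and polynomials. Polynomial curves are
#' evaluated on the rescaled time \eqn{u = t/T}, i.e.
#' \eqn{b_l(t) = (t/T)^{l-1}}, which keeps the design well conditioned for
#' domains extending to tens of time units; the fitted curve is invariant to
#' this rescaling and coefficients on the natural \eqn{t^{l-1}} scale are
#' recoverable via \code{\link{polyCoefOnTimeScale}}.
#'
#' @param kind "eigenfunction" or "polynomial".
#' @param degree polynomial degree (basis has \code{degree + 1} curves);
#'   degree 0 gives the single constant curve used for constant-effect fits.
#' @param grid evaluation grid (defaults to the model grid).
#' @param model an \code{FpcaModel}, required for the eigenfunction kind.
#' @return an \code{\linkS4class{EffectBasis}}.
#' @export
#' @examples
#' b <- makeBasis("polynomial", degree = 1, grid = seq(0, 50, length.out = 101))
makeBasis <- function(kind = c("eigenfunction", "polynomial"), degree = 1L,
                      grid = NULL, model = NULL) {
  kind <- match.arg(kind)
  if (kind == "eigenfunction") {
    if (is.null(model)) stop("eigenfunction basis requires an FpcaModel")
    if (is.null(grid)) grid <- model@grid
    curves <- if (identical(grid, model@grid)) model@phi
              else interpCurves(model@grid, model@phi, grid)
    return(new("EffectBasis", kind = "eigenfunction", curves = curves,
               grid = grid, degree = NA_integer_))
  }
  if (is.null(grid)) stop("polynomial basis requires a grid")
  if (degree < 0L) stop("'degree' must be non-negative")
  tMax <- max(grid)
  if (tMax <= 0) stop("polynomial basis requires a positive domain endpoint")
  curves <- outer(grid / tMax, 0:degree, "^")
  new("EffectBasis", kind = "polynomial", curves = curves, grid = grid,
      degree = as.integer(degree))
}

#' Polynomial coefficients on the natural time scale
#'
#' Converts coefficients fitted on the rescaled basis \eqn{(t/T)^{l-1}} to
#' the \eqn{t^{l-1}} scale.
#'
#' @param gamma fitted coefficients.
#' @param basis the polynomial \code{EffectBasis} they belong to.
#' @return coefficients \eqn{\gamma_l} such that
#'   \eqn{\beta(t) = \sum_l \gamma_l t^{l-1}}.
#' @export
polyCoefOnTimeScale <- function(gamma, basis) {
  if (basis@kind != "polynomial") stop("basis is not polynomial")
  gamma / max(basis@grid)^(seq_along(gamma) - 1)
}

#' Score transformation matrix
#'
#' \eqn{B_{kl} = \int_0^T \phi_k(t) b_l(t) dt} under trapezoid quadrature on
#' the shared grid. When the basis equals the eigenfunctions, \eqn{B} is the
#' identity.
#'
#' @param phi eigenfunction matrix (grid x K) or an \code{FpcaModel}.
#' @param basis an \code{EffectBasis} on the same grid.
#' @param grid the shared grid (defaults to the basis grid).
#' @return K x L matrix.
#' @export
transformMatrix <- function(phi, basis, grid = NULL) {
  if (is(phi, "FpcaModel")) {
    if (is.null(grid)) grid <- phi@grid
    phi <- phi@phi
  }
  if (is.null(grid)) grid <- basis@grid
  if (length(grid) != length(basis@grid) ||
      max(abs(grid - basis@grid)) > 1e-8)
    stop("eigenfunctions and basis must share the same grid")
  if (nrow(phi) != length(grid)) stop("eigenfunction grid mismatch")
  w <- quadWeights(grid)
  crossprod(phi, w * basis@curves)
}

#' Transform pseudo-exposure scores
#'
#' \eqn{\xi^* = B' \xi} per subject; with \eqn{L \le K} this maps the K
#' principal component scores to the L transformed pseudo-exposures of the
#' chosen basis.
#'
#' @param xi score matrix (n x K).
#' @param B transformation matrix (K x L) from \code{\link{transformMatrix}}.
#' @return n x L matrix.
#' @export
transformScores <- function(xi, B) {
  xi <- as.matrix(xi)
  if (ncol(xi) != nrow(B)) stop("score and transform dimensions do not conform")
  if (ncol(B) > nrow(B)) stop("more basis functions than principal components; ",
                              "identification requires L <= K")
  out <- xi %*% B
  rownames(out) <- rownames(xi)
  out
}
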
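#' @include AllClasses.R
NULL

#' Accessors for fitted objects
#'
#' Small accessor generics so that slots never need to be reached directly:
#' \code{timePoints} returns the evaluation grid, \code{meanCurve} the FPCA
#' mean function, \code{eigenFunctions}/\code{eigenValues} the spectral
#' decomposition, \code{noiseVariance} the measurement-error variance,
#' \code{scores} the PACE score matrix, \code{fve} the cumulative fraction of
#' variance explained and \code{basisCurves} the basis evaluation matrix.
#'
#' @param object an S4 object from this package.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("meanCurve", function(object) standardGeneric("meanCurve"))
#' @rdname accessors
#' @export
setGeneric("eigenFunctions", function(object) standardGeneric("eigenFunctions"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("noiseVariance", function(object) standardGeneric("noiseVariance"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("fve", function(object) standardGeneric("fve"))
#' @rdname accessors
#' @export
setGeneric("basisCurves", function(object) standardGeneric("basisCurves"))
#' @rdname accessors
#' @export
setGeneric("acceptedSet", function(object) standardGeneric("acceptedSet"))

#' @rdname accessors
#' @export
setMethod("timePoints", "FpcaModel", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("timePoints", "EffectBasis", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("timePoints", "EffectCurve", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("meanCurve", "FpcaModel", function(object) object@mu)
#' @rdname accessors
#' @export
setMethod("eigenFunctions", "FpcaModel", function(object) object@phi)
#' @rdname accessors
#' @export
setMethod("eigenValues", "FpcaModel", function(object) object@lambda)
#' @rdname accessors
#' @export
setMethod("noiseVariance", "FpcaModel", function(object) object@sigma2)
#' @rdname accessors
#' @export
setMethod("scores", "FpcaModel", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("fve", "FpcaModel", function(object) object@fve)
#' @rdname accessors
#' @export
setMethod("basisCurves", "EffectBasis", function(object) object@curves)
#' @rdname accessors
#' @export
setMethod("acceptedSet", "LmRegion",
          function(object) object@candidates[object@accepted, , drop = FALSE])

#' @describeIn accessors coefficients of a fitted MPCMR model.
#' @export
setMethod("coef", "MpcmrFit", function(object) object@estimate)

#' @describeIn accessors covariance matrix of the fitted coefficients.
#' @export
setMethod("vcov", "MpcmrFit", function(object) object@Sigma)

#' Coerce an effect curve to a data frame
#'
#' @param x an \code{EffectCurve}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data frame with columns \code{t}, \code{beta}, \code{se},
#'   \code{lo}, \code{hi}.
#' @export
as.data.frame.EffectCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(t = x@grid, beta = x@beta, se = x@se, lo = x@lo, hi = x@hi)
}

#' Plot an effect curve with its Wald band
#'
#' @param x an \code{EffectCurve}.
#' @param band optional two-column matrix or data frame (lo, hi) of an
#'   identification-robust band on the same grid, drawn dashed.
#' @param ... passed to \code{plot}.
#' @export
plotEffectCurve <- function(x, band = NULL, ...) {
  df <- as.data.frame(x)
  ylim <- range(df$lo, df$hi, if (!is.null(band)) unlist(band), finite = TRUE)
  graphics::plot(df$t, df$beta, type = "l", lwd = 2, ylim = ylim,
                 xlab = "time", ylab = expression(beta(t)), ...)
  graphics::lines(df$t, df$lo, lty = 2)
  graphics::lines(df$t, df$hi, lty = 2)
  if (!is.null(band)) {
    graphics::lines(df$t, band[[1L]], lty = 3, col = "grey40")
    graphics::lines(df$t, band[[2L]], lty = 3, col = "grey40")
  }
  graphics::abline(h = 0, col = "grey70")
  invisible(df)
}
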
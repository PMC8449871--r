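#' Sauter mean diameter (d32)
#'
#' The volume-surface mean diameter of a droplet population,
#' \eqn{d_{32} = \sum d_i^3 / \sum d_i^2}.  For any non-degenerate set it is
#' at least the arithmetic mean, with equality only for monodisperse sets.
#'
#' @param x positive diameters (micrometres), or a [DropletSet-class].
#' @return the Sauter mean diameter, same units as the input.
#' @examples
#' sauterMean(c(1, 2, 3))   # 36/14
#' @export
setGeneric("sauterMean", function(x) standardGeneric("sauterMean"))

#' Yield value (static flow limit) of a flow curve
#'
#' Reads the yield value \eqn{\tau_y} of a plastic-type fluid off its flow
#' curve: the stress at the minimum sweep frequency (the matrix must be
#' overcome by a suspended element's own weight before it deforms).
#'
#' @param curve a [FlowCurve-class].
#' @param method \code{"point"} (default): the stress at the lowest
#'   frequency.  \code{"plateau"}: the median stress over the lowest decade
#'   of frequencies, used when at least three points fall in that decade
#'   (falls back to \code{"point"} otherwise); a smoother low-frequency
#'   plateau estimate for noisy sweeps.
#' @return yield value in Pa.
#' @export
setGeneric("yieldValue", function(curve, method = c("point", "plateau"))
  standardGeneric("yieldValue"))

#' @describeIn DropletSet-class droplet diameters in micrometres.
#' @param x,object a \code{DropletSet}.
#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))

#' @describeIn DropletSet-class number of measured droplets.
#' @export
setGeneric("nDroplets", function(x) standardGeneric("nDroplets"))

#' @describeIn FlowCurve-class sweep frequencies in Hz.
#' @param x,object a \code{FlowCurve}.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @describeIn FlowCurve-class stresses in Pa.
#' @export
setGeneric("stresses", function(x) standardGeneric("stresses"))

#' @describeIn DoeFit-class coefficient table (term, estimate, se, t).
#' @param x,object a \code{DoeFit}.
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @describeIn DoeFit-class named R-squared vector (raw, adjusted,
#'   predicted, and their no-block counterparts).
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @describeIn DoeFit-class coded model terms.
#' @export
setGeneric("modelTerms", function(x) standardGeneric("modelTerms"))

#' @describeIn DoeFit-class name of the response transform.
#' @export
setGeneric("transformName", function(x) standardGeneric("transformName"))
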
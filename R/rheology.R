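#' Construct a FlowCurve
#'
#' @param frequency strictly increasing positive sweep frequencies (Hz).
#' @param stress stresses in Pa, parallel to \code{frequency}.
#' @param sampleId sample identifier.
#' @param temperature measurement temperature (degrees C).
#' @return a [FlowCurve-class].
#' @export
flowCurve <- function(frequency, stress, sampleId = NA_character_,
                      temperature = 25) {
  o <- order(frequency)
  new("FlowCurve", frequency = as.numeric(frequency)[o],
      stress = as.numeric(stress)[o], sampleId = sampleId,
      temperature = temperature)
}

#' @export
setMethod("frequencies", "FlowCurve", function(x) x@frequency)

#' @export
setMethod("stresses", "FlowCurve", function(x) x@stress)

setMethod("show", "FlowCurve", function(object) {
  cat(sprintf("FlowCurve '%s': %d points, %.3g-%.3g Hz, stress %.3g-%.3g Pa\n",
              object@sampleId, length(object@frequency),
              min(object@frequency), max(object@frequency),
              min(object@stress), max(object@stress)))
})

#' @rdname yieldValue
#' @export
setMethod("yieldValue", "FlowCurve", function(curve,
                                              method = c("point",
                                                         "plateau")) {
  method <- match.arg(method)
  f <- curve@frequency
  s <- curve@stress
  if (method == "plateau") {
    low <- s[f <= min(f) * 10]
    if (length(low) >= 3L) return(median(low))
  }
  s[which.min(f)]
})

#' Fit a Herschel-Bulkley model to a flow curve
#'
#' Nonlinear least squares of \eqn{\sigma = \tau_0 + K f^n} with bound
#' constraints \eqn{\tau_0 \ge 0}, \eqn{K \ge 0}, \eqn{0 < n \le 2},
#' via Levenberg-Marquardt.  A model-based cross-check of the direct
#' lowest-frequency reading of [yieldValue()].
#'
#' @param curve a [FlowCurve-class] with at least 4 points.
#' @return list with \code{tau0}, \code{K}, \code{n}, \code{residualSd}
#'   and the \code{fit} object.
#' @examples
#' fc <- generateFlowCurve(flowCurveSpec(1, 1, 0.5))
#' fitHerschelBulkley(fc)$tau0
#' @export
fitHerschelBulkley <- function(curve) {
  stopifnot(is(curve, "FlowCurve"))
  f <- curve@frequency
  s <- curve@stress
  if (length(f) < 4L) stop("need at least 4 points for a Herschel-Bulkley fit")
  start <- list(tau0 = max(min(s), 1e-6),
                K = max((max(s) - min(s)) / max(max(f)^0.5, 1), 1e-6),
                n = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ tau0 + K * f^n, start = start,
                      lower = c(0, 0, 1e-6), upper = c(Inf, Inf, 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Herschel-Bulkley fit failed to converge: ",
           conditionMessage(e)))
  cf <- coef(fit)
  list(tau0 = unname(cf["tau0"]), K = unname(cf["K"]), n = unname(cf["n"]),
       residualSd = sqrt(mean(resid(fit)^2)), fit = fit)
}
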
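# cache for the fixture-calibrated micro-stress slope
.creamdexCache <- new.env(parent = emptyenv())

#' Calibrate the micro-stress slope k
#'
#' The droplet micro-stress is modelled as linear in the droplet diameter,
#' \eqn{\sigma = k d}; this fits k by through-origin least squares on
#' (diameter, pressure) pairs.  The default pairs are the ten printed in
#' the bundled creaming table ([creamingTable()]); they are consistent with
#' a single constant to well under 2\% relative residual, which is the
#' empirical justification of the linear law.  Physically, k plays the
#' role of an effective buoyancy factor (density contrast times g times a
#' geometric prefactor).
#'
#' @param diametersUm droplet diameters in micrometres.
#' @param pressuresPa micro-stresses in Pa.
#' @return k in Pa per metre of diameter.
#' @examples
#' calibrateMicroStress()   # ~ 32.5 Pa/m
#' @export
calibrateMicroStress <- function(diametersUm = NULL, pressuresPa = NULL) {
  if (is.null(diametersUm)) {
    tab <- creamingTable()
    diametersUm <- c(tab$ads_um, tab$lds_um)
    pressuresPa <- c(tab$ads_pressure_pa, tab$lds_pressure_pa)
  }
  if (length(diametersUm) != length(pressuresPa) || !length(diametersUm))
    stop("need matching non-empty diameter and pressure vectors")
  d_m <- diametersUm * 1e-6
  sum(pressuresPa * d_m) / sum(d_m^2)
}

#' Default micro-stress slope (fixture calibrated, cached)
#'
#' @return k in Pa/m from [calibrateMicroStress()] on the bundled table.
#' @export
kStar <- function() {
  if (is.null(.creamdexCache$k)) .creamdexCache$k <- calibrateMicroStress()
  .creamdexCache$k
}

#' Micro-stress of a suspended droplet
#'
#' The stress a single dispersed droplet exerts on the surrounding matrix,
#' taken linear in its diameter: \eqn{\sigma = k d}.  Compared against the
#' static flow limit of the matrix, it decides whether the droplet can
#' deform the matrix by its own weight.
#'
#' @param diameterUm droplet diameter in micrometres (> 0).
#' @param k stress-per-length slope in Pa/m (> 0); defaults to the
#'   fixture-calibrated [kStar()].
#' @return micro-stress in Pa.
#' @examples
#' microStress(12.49)   # ~ 4.06e-4 Pa
#' @export
microStress <- function(diameterUm, k = kStar()) {
  if (any(diameterUm <= 0)) stop("diameter must be > 0")
  if (any(k <= 0)) stop("k must be > 0")
  k * diameterUm * 1e-6
}

#' Creaming index
#'
#' The ratio of the matrix yield stress to a droplet's micro-stress: the
#' minimum number of droplets an aggregate must contain for its weight to
#' overcome the static flow limit and cream.  The higher the index, the
#' more stable the emulsion.  Real-valued; round only for display.
#'
#' @param tauY yield value of the matrix in Pa (> 0).
#' @param sigma droplet micro-stress in Pa (> 0).
#' @return dimensionless droplet count.
#' @examples
#' round(creamingIndex(3.01e-1, 4.03e-4))   # 747
#' @export
creamingIndex <- function(tauY, sigma) {
  if (any(tauY <= 0)) stop("tauY must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0 (division by zero otherwise)")
  tauY / sigma
}

#' Assess the creaming stability of one emulsion
#'
#' Assembles the full creaming workup of a sample: the average droplet
#' size (ADS, the Sauter mean d32), the largest droplet size (LDS, the
#' maximum observed diameter), their micro-stresses under the linear law,
#' and both creaming indices against the matrix yield value.  Since
#' LDS >= ADS, the ADS index is always the larger of the two; the pair
#' brackets the droplet count an aggregate needs in order to cream.
#'
#' @param sampleId sample identifier.
#' @param tauY matrix yield value in Pa.
#' @param diameters a [DropletSet-class] or positive numeric vector of
#'   diameters in micrometres.
#' @param k micro-stress slope in Pa/m; defaults to [kStar()].
#' @return a [CreamingAssessment-class].
#' @export
assessCreaming <- function(sampleId, tauY, diameters, k = kStar()) {
  d <- if (is(diameters, "DropletSet")) diameters(diameters)
       else as.numeric(diameters)
  if (!length(d)) stop("no diameters given")
  ads <- sauterMean(d)
  lds <- max(d)
  sAds <- microStress(ads, k)
  sLds <- microStress(lds, k)
  new("CreamingAssessment", sampleId = as.character(sampleId), tauY = tauY,
      ads = ads, lds = lds, sigmaAds = sAds, sigmaLds = sLds,
      ciAds = creamingIndex(tauY, sAds), ciLds = creamingIndex(tauY, sLds),
      k = k)
}

setMethod("show", "CreamingAssessment", function(object) {
  cat(sprintf("CreamingAssessment '%s': tauY %.3g Pa, k %.3g Pa/m\n",
              object@sampleId, object@tauY, object@k))
  cat(sprintf("  ADS %.2f um -> sigma %.3g Pa, index %.0f\n",
              object@ads, object@sigmaAds, object@ciAds))
  cat(sprintf("  LDS %.2f um -> sigma %.3g Pa, index %.0f\n",
              object@lds, object@sigmaLds, object@ciLds))
})

#' @describeIn CreamingAssessment-class creaming index for the average
#'   droplet size.
#' @param x,object a \code{CreamingAssessment}.
#' @export
ciAds <- function(x) x@ciAds

#' @describeIn CreamingAssessment-class creaming index for the largest
#'   droplet size.
#' @export
ciLds <- function(x) x@ciLds

#' One-row data.frame view of an assessment
#'
#' @param x a [CreamingAssessment-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame mirroring the creaming-table layout.
#' @export
as.data.frame.CreamingAssessment <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(sample = x@sampleId, yield_pa = x@tauY, ads_um = x@ads,
             lds_um = x@lds, ads_pressure_pa = x@sigmaAds,
             lds_pressure_pa = x@sigmaLds, ci_ads = x@ciAds,
             ci_lds = x@ciLds)
}
setMethod("as.data.frame", "CreamingAssessment",
          as.data.frame.CreamingAssessment)

#' Select storage-stable emulsions
#'
#' Applies the stability-selection rule of the screening stage: keep the
#' emulsions whose droplet-size variation after 5 h of storage is strictly
#' below \code{varMax} percent and whose ordinal creaming class is at
#' least \code{classMin}.  Boundary semantics are strict on the variation
#' (12.0\% exactly is excluded) and inclusive on the class.
#'
#' @param records data.frame with columns \code{size_var_pct} and
#'   \code{creaming_class} (e.g. [designTable()]).
#' @param varMax variation cutoff in percent (default 12).
#' @param classMin minimum creaming class (default 3).
#' @return the selected rows, input order preserved (possibly empty).
#' @examples
#' selectStable(designTable())$run   # 8, 10, 11, 18, 24
#' @export
selectStable <- function(records, varMax = 12, classMin = 3) {
  need <- c("size_var_pct", "creaming_class")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(records$size_var_pct)))
    stop("non-finite size variation")
  if (any(!records$creaming_class %in% 1:5))
    stop("creaming_class values must lie in 1..5")
  records[records$size_var_pct < varMax &
            records$creaming_class >= classMin, , drop = FALSE]
}
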
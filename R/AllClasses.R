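#' Specification of a synthetic emulsion micrograph
#'
#' Describes a square bright-field micrograph of an oil-in-water emulsion:
#' image geometry, the micron calibration (given, as in routine practice, by
#' the full physical width of the image), the droplet population (log-normal
#' diameters), rendering polarity and additive intensity noise.
#'
#' @slot widthPx image width and height in pixels.
#' @slot widthUm physical width of the image in micrometres; the pixel size
#'   is \code{widthUm / widthPx} um/px.
#' @slot nDroplets number of droplets to render.
#' @slot meanlog,sdlog parameters of the log-normal diameter distribution,
#'   on the log-micrometre scale.
#' @slot allowOverlap if \code{FALSE} (default) droplets are packed without
#'   touching, with a bounded number of placement retries.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise
#'   (intensities live in [0, 1] and are clipped after noising).
#' @slot polarity \code{"dark"} for dark droplets on a light background
#'   (oil under bright field) or \code{"bright"} for the reverse.
#' @slot seed integer seed making the rendering reproducible.
#' @seealso [micrographSpec()], [generateMicrograph()]
#' @export
setClass("MicrographSpec",
  representation(
    widthPx = "integer", widthUm = "numeric", nDroplets = "integer",
    meanlog = "numeric", sdlog = "numeric", allowOverlap = "logical",
    noiseSd = "numeric", polarity = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@widthPx <= 0L) msg <- c(msg, "widthPx must be > 0")
    if (object@widthUm <= 0) msg <- c(msg, "widthUm must be > 0")
    if (object@nDroplets < 0L) msg <- c(msg, "nDroplets must be >= 0")
    if (object@sdlog < 0) msg <- c(msg, "sdlog must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (!object@polarity %in% c("dark", "bright"))
      msg <- c(msg, "polarity must be 'dark' or 'bright'")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic flow curve
#'
#' Parameters of a Herschel-Bulkley (plastic-type) stress response
#' \eqn{\sigma(f) = \tau_0 + K f^n} sampled on a frequency grid, with
#' additive Gaussian noise.  The yield stress \eqn{\tau_0} plays the role of
#' the static flow limit of the matrix.
#'
#' @slot yieldStress yield stress \eqn{\tau_0} in Pa.
#' @slot consistency consistency coefficient K in Pa s^n.
#' @slot flowIndex flow behaviour index n (0 < n <= 1, shear thinning).
#' @slot freqGrid strictly increasing positive frequencies in Hz; the
#'   laboratory sweep spans 0.05-500 Hz.
#' @slot noiseSd standard deviation of additive stress noise in Pa.
#' @slot seed integer seed.
#' @seealso [flowCurveSpec()], [generateFlowCurve()]
#' @export
setClass("FlowCurveSpec",
  representation(
    yieldStress = "numeric", consistency = "numeric", flowIndex = "numeric",
    freqGrid = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@yieldStress < 0) msg <- c(msg, "yieldStress must be >= 0")
    if (object@consistency < 0) msg <- c(msg, "consistency must be >= 0")
    if (object@flowIndex <= 0 || object@flowIndex > 1)
      msg <- c(msg, "flowIndex must be in (0, 1]")
    if (length(object@freqGrid) == 0L)
      msg <- c(msg, "freqGrid must be non-empty")
    else {
      if (any(object@freqGrid <= 0)) msg <- c(msg, "freqGrid must be positive")
      if (is.unsorted(object@freqGrid, strictly = TRUE))
        msg <- c(msg, "freqGrid must be strictly increasing")
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Measured droplet diameters of one emulsion at one time point
#'
#' Holds the diameters (micrometres) measured on one or more micrographs of
#' an emulsion, together with the image identifier and the time point
#' (\code{"T0"} after preparation; \code{"T5top"} / \code{"T5bottom"} for the
#' cream and serum phases after 5 h of storage).
#'
#' @slot diameters positive droplet diameters in micrometres.
#' @slot sourceImage identifier of the source image(s).
#' @slot timepoint one of \code{"T0"}, \code{"T5top"}, \code{"T5bottom"}.
#' @seealso [dropletSet()], [sauterMean()], [sizeSummary()]
#' @export
setClass("DropletSet",
  representation(diameters = "numeric", sourceImage = "character",
                 timepoint = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@diameters) && any(object@diameters <= 0))
      msg <- c(msg, "all diameters must be > 0")
    if (!object@timepoint %in% c("T0", "T5top", "T5bottom"))
      msg <- c(msg, "timepoint must be one of 'T0', 'T5top', 'T5bottom'")
    if (length(msg)) msg else TRUE
  })

#' An oscillatory flow curve
#'
#' Stress versus sweep frequency for an emulsion or its continuous-phase
#' matrix, as measured in a small-amplitude oscillatory frequency sweep.
#'
#' @slot frequency strictly increasing positive frequencies in Hz.
#' @slot stress stresses in Pa (>= 0), parallel to \code{frequency}.
#' @slot sampleId sample identifier.
#' @slot temperature measurement temperature in degrees Celsius.
#' @seealso [flowCurve()], [yieldValue()], [fitHerschelBulkley()]
#' @export
setClass("FlowCurve",
  representation(frequency = "numeric", stress = "numeric",
                 sampleId = "character", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequency) != length(object@stress))
      msg <- c(msg, "frequency and stress must have equal length")
    if (length(object@frequency) == 0L)
      msg <- c(msg, "flow curve must be non-empty")
    else {
      if (any(object@frequency <= 0)) msg <- c(msg, "frequencies must be > 0")
      if (is.unsorted(object@frequency, strictly = TRUE))
        msg <- c(msg, "frequencies must be strictly increasing")
      if (any(object@stress < 0)) msg <- c(msg, "stresses must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' A fitted coded-factor response model
#'
#' Result of an ordinary-least-squares fit of a (possibly Box-Cox
#' transformed) response on coded design factors, two-factor interactions
#' and fixed block indicators.
#'
#' @slot response name of the modelled response.
#' @slot transform the named response transform (\code{"log10"},
#'   \code{"sqrt"}, \code{"inverse-sqrt"} or \code{"identity"}).
#' @slot lambda the Box-Cox lambda the scan selected (NA when the transform
#'   was imposed rather than scanned).
#' @slot terms the coded model terms (main effects \code{A}..\code{E} and
#'   two-letter interactions).
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{se}, \code{t}; includes the constant and block contrasts.
#'   With sum-to-zero block contrasts the constant is the grand constant of
#'   the linearisation equation.
#' @slot r2 named numeric: \code{raw}, \code{adjusted}, \code{predicted}
#'   (leave-one-out PRESS based), plus \code{raw_noblock},
#'   \code{adjusted_noblock}, \code{predicted_noblock} from a refit without
#'   block columns.
#' @slot dfResidual residual degrees of freedom.
#' @slot fit the underlying \code{lm} object.
#' @seealso [fitLinearModel()], [effectPareto()], [predictResponse()]
#' @export
setClass("DoeFit",
  representation(
    response = "character", transform = "character", lambda = "numeric",
    terms = "character", coefficients = "data.frame", r2 = "numeric",
    dfResidual = "integer", fit = "ANY"),
  validity = function(object) {
    msg <- character()
    if (!object@transform %in% c("log10", "sqrt", "inverse-sqrt", "identity"))
      msg <- c(msg, "unknown transform")
    needed <- c("term", "estimate", "se", "t")
    if (!all(needed %in% names(object@coefficients)))
      msg <- c(msg, "coefficients must have columns term/estimate/se/t")
    if (!all(c("raw", "adjusted", "predicted") %in% names(object@r2)))
      msg <- c(msg, "r2 must contain raw/adjusted/predicted")
    else if (object@r2[["predicted"]] > object@r2[["raw"]] + 1e-12 ||
             object@r2[["adjusted"]] > object@r2[["raw"]] + 1e-12)
      msg <- c(msg, "adjusted and predicted R^2 cannot exceed raw R^2")
    if (length(msg)) msg else TRUE
  })

#' Creaming assessment of one emulsion
#'
#' Micro-stresses and creaming indices for the average (Sauter mean, ADS)
#' and largest (LDS) droplet of an emulsion, against the yield stress of
#' its continuous phase.  The creaming index \eqn{\tau_y / \sigma} is read
#' as the minimum number of droplets an aggregate must contain for its
#' weight to overcome the static flow limit; larger is more stable.
#'
#' @slot sampleId sample identifier.
#' @slot tauY yield value of the matrix in Pa.
#' @slot ads,lds average (d32) and largest droplet diameter in micrometres.
#' @slot sigmaAds,sigmaLds droplet micro-stresses in Pa.
#' @slot ciAds,ciLds creaming indices (dimensionless droplet counts).
#' @slot k micro-stress slope used, in Pa per metre of diameter.
#' @seealso [assessCreaming()], [creamingIndex()], [microStress()]
#' @export
setClass("CreamingAssessment",
  representation(
    sampleId = "character", tauY = "numeric", ads = "numeric", lds = "numeric",
    sigmaAds = "numeric", sigmaLds = "numeric", ciAds = "numeric",
    ciLds = "numeric", k = "numeric"),
  validity = function(object) {
    msg <- character()
    vals <- c(object@tauY, object@ads, object@lds, object@sigmaAds,
              object@sigmaLds, object@ciAds, object@ciLds, object@k)
    if (any(vals <= 0)) msg <- c(msg, "all quantities must be > 0")
    if (object@lds < object@ads - 1e-9)
      msg <- c(msg, "largest droplet cannot be smaller than the Sauter mean")
    if (abs(object@ciAds - object@tauY / object@sigmaAds) > 1e-6 * object@ciAds)
      msg <- c(msg, "ciAds must equal tauY / sigmaAds")
    if (abs(object@ciLds - object@tauY / object@sigmaLds) > 1e-6 * object@ciLds)
      msg <- c(msg, "ciLds must equal tauY / sigmaLds")
    if (length(msg)) msg else TRUE
  })
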
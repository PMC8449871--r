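#' Create a micrograph specification
#'
#' Defaults emulate a 100x bright-field micrograph of a homogenised
#' oil-in-water emulsion: a 1000 px image spanning 250 um (0.25 um/px), 50
#' droplets per image with log-normal diameters centred near 10 um, dark
#' droplets on a light background and mild sensor noise.
#'
#' @param widthPx image width in pixels.
#' @param widthUm physical image width in micrometres.
#' @param nDroplets number of droplets.
#' @param meanlog,sdlog log-normal diameter parameters (log-micrometres).
#' @param allowOverlap allow droplets to overlap (default \code{FALSE}).
#' @param noiseSd additive Gaussian intensity noise (intensity units on
#'   the [0, 1] scale).
#' @param polarity \code{"dark"} or \code{"bright"} droplets.
#' @param seed integer seed.
#' @return a [MicrographSpec-class].
#' @examples
#' spec <- micrographSpec(nDroplets = 10, seed = 1)
#' img <- generateMicrograph(spec)
#' nrow(img$truth)
#' @export
micrographSpec <- function(widthPx = 1000L, widthUm = 250, nDroplets = 50L,
                           meanlog = log(10), sdlog = 0.25,
                           allowOverlap = FALSE, noiseSd = 0.05,
                           polarity = c("dark", "bright"), seed = 1L) {
  new("MicrographSpec", widthPx = as.integer(widthPx), widthUm = widthUm,
      nDroplets = as.integer(nDroplets), meanlog = meanlog, sdlog = sdlog,
      allowOverlap = allowOverlap, noiseSd = noiseSd,
      polarity = match.arg(polarity), seed = as.integer(seed))
}

#' Render a synthetic micrograph with known ground truth
#'
#' Draws droplet diameters from the specified log-normal distribution, packs
#' the disks into the image (uniform random centres, fully inside the
#' frame), rasterises them and adds clipped Gaussian intensity noise.  The
#' returned truth table holds the exact rendered diameters in pixels and,
#' via the image-width calibration, in micrometres.
#'
#' Identical specs (including the seed) give bit-identical output.
#'
#' @param spec a [MicrographSpec-class].
#' @return a list with \code{image} (a \code{widthPx} x \code{widthPx}
#'   matrix of intensities in [0, 1]) and \code{truth} (data.frame with
#'   columns droplet_id, x_px, y_px, diameter_px, diameter_um).
#' @details When \code{allowOverlap} is \code{FALSE} each droplet gets 100
#'   placement retries; exhausting them raises an error naming the droplet.
#'   Droplets are placed fully inside the frame, so none touches the image
#'   border.  Background/foreground intensities are 0.88 and 0.25 (swapped
#'   for \code{polarity = "bright"}).
#' @export
generateMicrograph <- function(spec) {
  stopifnot(is(spec, "MicrographSpec"))
  validObject(spec)
  w <- spec@widthPx
  scale_um_px <- spec@widthUm / w
  bg <- if (spec@polarity == "dark") 0.88 else 0.25
  fg <- if (spec@polarity == "dark") 0.25 else 0.88
  img <- matrix(bg, w, w)
  n <- spec@nDroplets
  truth <- data.frame(droplet_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), diameter_px = numeric(0),
                      diameter_um = numeric(0))
  set.seed(spec@seed)
  if (n > 0L) {
    d_um <- rlnorm(n, spec@meanlog, spec@sdlog)
    d_px <- d_um / scale_um_px
    # place the big droplets first: packing is much easier that way
    ord <- order(d_px, decreasing = TRUE)
    r <- d_px[ord] / 2
    if (any(2 * r + 2 > w))
      stop("droplet larger than the image; reduce meanlog or widthUm")
    cx <- cy <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        x <- runif(1, r[i] + 1, w - r[i] - 1)
        y <- runif(1, r[i] + 1, w - r[i] - 1)
        if (spec@allowOverlap || i == 1L ||
            all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                     (cy[seq_len(i - 1)] - y)^2) >
                r[seq_len(i - 1)] + r[i] + 1)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place droplet ", i,
             " without overlap after 100 retries; ",
             "reduce nDroplets or set allowOverlap = TRUE")
    }
    for (i in seq_len(n)) {
      ix <- max(1L, floor(cx[i] - r[i])):min(w, ceiling(cx[i] + r[i]))
      iy <- max(1L, floor(cy[i] - r[i])):min(w, ceiling(cy[i] + r[i]))
      dsq <- outer((ix - cx[i])^2, (iy - cy[i])^2, "+")
      img[ix, iy][dsq <= r[i]^2] <- fg
    }
    truth <- data.frame(droplet_id = seq_len(n), x_px = cx, y_px = cy,
                        diameter_px = 2 * r,
                        diameter_um = 2 * r * scale_um_px)
  }
  if (spec@noiseSd > 0) {
    img <- img + matrix(rnorm(w * w, 0, spec@noiseSd), w, w)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, truth = truth)
}

#' Create a flow-curve specification
#'
#' Defaults follow the laboratory sweep (0.05-500 Hz, logarithmically
#' spaced) of a mildly shear-thinning plastic matrix.
#'
#' @param yieldStress yield stress tau0 in Pa.
#' @param consistency consistency K in Pa s^n.
#' @param flowIndex flow index n in (0, 1].
#' @param freqGrid strictly increasing positive frequencies (Hz).
#' @param noiseSd additive stress noise (Pa).
#' @param seed integer seed.
#' @return a [FlowCurveSpec-class].
#' @export
flowCurveSpec <- function(yieldStress = 2.35, consistency = 0.05,
                          flowIndex = 0.5,
                          freqGrid = 10^seq(log10(0.05), log10(500),
                                            length.out = 30),
                          noiseSd = 0, seed = 1L) {
  new("FlowCurveSpec", yieldStress = yieldStress, consistency = consistency,
      flowIndex = flowIndex, freqGrid = freqGrid, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Simulate a Herschel-Bulkley flow curve
#'
#' Stress is \eqn{\tau_0 + K f^n} plus Gaussian noise, truncated at zero
#' (stresses are physical).  Deterministic under a fixed seed.
#'
#' @param spec a [FlowCurveSpec-class].
#' @param sampleId identifier stored on the curve.
#' @return a [FlowCurve-class].
#' @export
generateFlowCurve <- function(spec, sampleId = "synthetic") {
  stopifnot(is(spec, "FlowCurveSpec"))
  validObject(spec)
  f <- spec@freqGrid
  s <- spec@yieldStress + spec@consistency * f^spec@flowIndex
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    s <- pmax(0, s + rnorm(length(f), 0, spec@noiseSd))
  }
  flowCurve(f, s, sampleId = sampleId)
}

#' Simulate responses from a coded-factor linear model
#'
#' Builds the model matrix for the given coded design and coefficient map,
#' adds Gaussian noise on the transformed scale and back-transforms, i.e.
#' \eqn{y = g^{-1}(X\beta + \epsilon)} where g is the named transform.
#' With \code{noiseSd = 0}, refitting the same terms with
#' [fitLinearModel()] recovers the coefficients to numerical precision.
#'
#' @param design data.frame with coded columns \code{A}..\code{E} (and a
#'   \code{block} column if block coefficients are supplied), e.g.
#'   [builtinDesign()].
#' @param coefficients named numeric vector: \code{constant}, main effects
#'   (\code{"A"}..\code{"E"}), two-letter interactions (\code{"AB"}, ...)
#'   and optionally \code{block1}, \code{block2} (sum-to-zero block
#'   contrasts).
#' @param transform one of \code{"log10"}, \code{"sqrt"},
#'   \code{"inverse-sqrt"}, \code{"identity"} (the inverse is applied here).
#' @param noiseSd noise standard deviation on the transformed scale.
#' @param seed integer seed.
#' @return numeric response vector on the original scale.
#' @export
generateDoeResponses <- function(design, coefficients,
                                 transform = c("log10", "sqrt",
                                               "inverse-sqrt", "identity"),
                                 noiseSd = 0, seed = 1L) {
  transform <- match.arg(transform)
  cf <- coefficients
  if (is.null(names(cf)) || any(!nzchar(names(cf))))
    stop("coefficients must be a fully named vector")
  eta <- rep(if ("constant" %in% names(cf)) cf[["constant"]] else 0,
             nrow(design))
  for (nm in setdiff(names(cf), "constant")) {
    if (nm %in% c("block1", "block2")) {
      if (!"block" %in% names(design))
        stop("block coefficients supplied but design has no 'block' column")
      b <- as.integer(factor(design$block))
      x <- switch(nm, block1 = (b == 1L) - (b == 3L),
                      block2 = (b == 2L) - (b == 3L))
    } else {
      x <- .codedColumn(design, nm)
    }
    eta <- eta + cf[[nm]] * x
  }
  if (noiseSd > 0) {
    set.seed(seed)
    eta <- eta + rnorm(length(eta), 0, noiseSd)
  }
  invertTransform(eta, transform)
}

# one coded column (main effect or two-letter interaction) of a design
.codedColumn <- function(design, term) {
  letters5 <- strsplit(term, "")[[1]]
  if (!all(letters5 %in% LETTERS[1:5]) || !nchar(term) %in% 1:2)
    stop("unknown model term: ", term)
  if (!all(letters5 %in% names(design)))
    stop("design lacks coded column(s) for term ", term)
  Reduce(`*`, lapply(letters5, function(l) design[[l]]))
}
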
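#' Construct a DropletSet
#'
#' @param diameters positive droplet diameters in micrometres.
#' @param sourceImage identifier of the source image(s).
#' @param timepoint \code{"T0"}, \code{"T5top"} or \code{"T5bottom"}.
#' @return a [DropletSet-class].
#' @export
dropletSet <- function(diameters, sourceImage = NA_character_,
                       timepoint = c("T0", "T5top", "T5bottom")) {
  new("DropletSet", diameters = as.numeric(diameters),
      sourceImage = sourceImage, timepoint = match.arg(timepoint))
}

#' @export
setMethod("diameters", "DropletSet", function(x) x@diameters)

#' @export
setMethod("nDroplets", "DropletSet", function(x) length(x@diameters))

setMethod("show", "DropletSet", function(object) {
  cat("DropletSet:", length(object@diameters), "droplets at",
      object@timepoint, "\n")
  if (length(object@diameters))
    cat(sprintf("  mean %.3f um, d32 %.3f um, range [%.3f, %.3f]\n",
                mean(object@diameters), sauterMean(object@diameters),
                min(object@diameters), max(object@diameters)))
})

#' Detect droplets on a grayscale micrograph
#'
#' Segments circular droplets from a bright-field micrograph: global Otsu
#' threshold, connected-component labelling, then size and circularity
#' filters.  Objects touching the image border are excluded (their
#' diameters are censored).  Returns equivalent-circle diameters
#' \eqn{2\sqrt{A/\pi}} in pixels, sorted in decreasing order.
#'
#' @param image numeric matrix of intensities in [0, 1] (or an
#'   \code{EBImage::Image}); a featureless image yields an empty result.
#' @param minDiameterPx minimum equivalent diameter to keep, in pixels.
#' @param circularityMin minimum circularity \eqn{4\pi A / P^2} in [0, 1].
#'   Digitised perimeters underestimate the true perimeter, so circular
#'   objects can score slightly above 1; the filter is a lower bound only.
#' @param polarity \code{"dark"} droplets below the Otsu threshold
#'   (default) or \code{"bright"} above it.
#' @return numeric vector of diameters in pixels (possibly empty).
#' @seealso [pxToUm()], [sizeSummary()]
#' @export
detectDroplets <- function(image, minDiameterPx = 3L, circularityMin = 0.6,
                           polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (circularityMin < 0 || circularityMin > 1)
    stop("circularityMin must be in [0, 1]")
  m <- if (is(image, "Image")) EBImage::imageData(image) else as.matrix(image)
  if (length(m) == 0L) stop("image is empty")
  if (diff(range(m)) < .Machine$double.eps) return(numeric(0))
  m <- pmin(pmax(m, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(m), range = c(0, 1))
  fgmask <- if (polarity == "dark") m < thr else m > thr
  lab <- EBImage::bwlabel(EBImage::Image(fgmask))
  labm <- EBImage::imageData(lab)
  if (max(labm) == 0) return(numeric(0))
  feats <- EBImage::computeFeatures.shape(lab)
  border <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1],
                     labm[, ncol(labm)]))
  border <- border[border > 0]
  keep <- setdiff(seq_len(nrow(feats)), border)
  if (!length(keep)) return(numeric(0))
  area <- feats[keep, "s.area"]
  per <- feats[keep, "s.perimeter"]
  deq <- 2 * sqrt(area / pi)
  circ <- ifelse(per > 0, 4 * pi * area / per^2, 1)
  deq <- deq[deq >= minDiameterPx & circ >= circularityMin]
  sort(deq, decreasing = TRUE)
}

#' Convert pixel diameters to micrometres
#'
#' The calibration is given by the full physical width of the image:
#' one pixel corresponds to \code{imageWidthUm / imageWidthPx} um.
#'
#' @param diametersPx diameters in pixels.
#' @param imageWidthPx image width in pixels (> 0).
#' @param imageWidthUm image width in micrometres (> 0).
#' @return diameters in micrometres.
#' @examples
#' pxToUm(40, 1000, 250)   # 10 um
#' @export
pxToUm <- function(diametersPx, imageWidthPx, imageWidthUm) {
  if (imageWidthPx <= 0 || imageWidthUm <= 0)
    stop("image widths must be > 0")
  diametersPx * (imageWidthUm / imageWidthPx)
}

#' @rdname sauterMean
#' @export
setMethod("sauterMean", "numeric", function(x) {
  if (length(x) == 0L) stop("need at least one diameter")
  if (any(x <= 0)) stop("all diameters must be > 0")
  sum(x^3) / sum(x^2)
})

#' @rdname sauterMean
#' @export
setMethod("sauterMean", "DropletSet", function(x) sauterMean(x@diameters))

#' Droplet size difference and variation rate over storage
#'
#' The change in mean droplet size over 5 h of storage and its rate,
#' \eqn{100 (S_{t5} - S_{t0}) / S_{t0}} in percent: the primary stability
#' readout of the screening design.
#'
#' @param sizeT0 mean droplet size after preparation (um, > 0).
#' @param sizeT5 mean droplet size after 5 h of storage (um).
#' @return list with \code{difference} (um) and \code{ratePct} (percent).
#' @examples
#' variationRate(15.87, 28.56)   # 12.69 um, 79.96 %
#' @export
variationRate <- function(sizeT0, sizeT5) {
  if (any(sizeT0 <= 0)) stop("sizeT0 must be > 0")
  d <- sizeT5 - sizeT0
  list(difference = d, ratePct = 100 * d / sizeT0)
}

#' Summary statistics of a droplet set
#'
#' @param set a [DropletSet-class] (non-empty).
#' @return data.frame with one row: \code{timepoint}, \code{n},
#'   \code{mean_um}, \code{d32_um}.
#' @export
sizeSummary <- function(set) {
  stopifnot(is(set, "DropletSet"))
  if (nDroplets(set) == 0L) stop("droplet set is empty")
  data.frame(timepoint = set@timepoint, n = nDroplets(set),
             mean_um = mean(set@diameters),
             d32_um = sauterMean(set@diameters))
}

#' Subsample a fixed number of droplets
#'
#' Routine practice counts a fixed number of droplets (50) per image; this
#' draws a seeded uniform subsample when more were detected.  Sets with at
#' most \code{n} droplets are returned unchanged.
#'
#' @param diametersUm measured diameters.
#' @param n subsample size (default 50).
#' @param seed integer seed.
#' @return numeric vector of at most \code{n} diameters.
#' @export
subsampleDroplets <- function(diametersUm, n = 50L, seed = 1L) {
  if (length(diametersUm) <= n) return(diametersUm)
  set.seed(seed)
  diametersUm[sort(sample.int(length(diametersUm), n))]
}

#' Measure droplets on a micrograph, end to end
#'
#' Convenience wrapper chaining [detectDroplets()], [pxToUm()] and
#' [dropletSet()].
#'
#' @inheritParams detectDroplets
#' @param imageWidthUm physical image width in micrometres.
#' @param timepoint stored on the resulting set.
#' @param subsample if not \code{NULL}, pass detections through
#'   [subsampleDroplets()] with this sample size.
#' @param seed seed for the subsample.
#' @param sourceImage identifier stored on the set.
#' @return a [DropletSet-class].
#' @export
measureDroplets <- function(image, imageWidthUm, minDiameterPx = 3L,
                            circularityMin = 0.6,
                            polarity = c("dark", "bright"),
                            timepoint = "T0", subsample = NULL, seed = 1L,
                            sourceImage = NA_character_) {
  dpx <- detectDroplets(image, minDiameterPx, circularityMin,
                        match.arg(polarity))
  dum <- pxToUm(dpx, nrow(as.matrix(if (is(image, "Image"))
    EBImage::imageData(image) else image)), imageWidthUm)
  if (!is.null(subsample)) dum <- subsampleDroplets(dum, subsample, seed)
  dropletSet(dum, sourceImage = sourceImage, timepoint = timepoint)
}
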
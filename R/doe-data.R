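# Factor ranges of the screening design: argan oil %, modified starch %,
# sodium caseinate %, stirring velocity (rpm), stirring time (min).
.factorRanges <- data.frame(
  factor = c("A", "B", "C", "D", "E"),
  name = c("oil_pct", "starch_pct", "caseinate_pct", "stir_rpm", "stir_min"),
  low = c(10, 0, 0, 10000, 5),
  high = c(20, 1.5, 2, 20000, 20))

#' Code a formulation to the -1..+1 scale
#'
#' Maps each natural factor value onto the coded scale used by the design:
#' \eqn{2 (x - \mathrm{mid}) / \mathrm{range}}, so the low level becomes
#' -1, the high level +1 and the midpoint 0.  Factors are A argan oil
#' (10-20 \% w/w), B starch (0-1.5 \%), C sodium caseinate (0-2 \%),
#' D stirring velocity (10000-20000 rpm), E stirring time (5-20 min).
#'
#' @param oil,starch,caseinate,rpm,time natural factor values (vectors of
#'   equal length are accepted).
#' @return data.frame with coded columns \code{A}..\code{E}.
#' @examples
#' codeFactors(15, 0.75, 1, 15000, 12.5)   # the centre point: all zero
#' @export
codeFactors <- function(oil, starch, caseinate, rpm, time) {
  nat <- list(oil, starch, caseinate, rpm, time)
  out <- lapply(seq_len(5), function(i) {
    r <- .factorRanges[i, ]
    x <- nat[[i]]
    if (any(x < r$low - 1e-9) || any(x > r$high + 1e-9))
      stop(r$name, " out of range [", r$low, ", ", r$high, "]")
    2 * (x - (r$low + r$high) / 2) / (r$high - r$low)
  })
  names(out) <- .factorRanges$factor
  as.data.frame(out)
}

#' Decode coded factors back to natural units
#'
#' Inverse of [codeFactors()]: \code{decodeFactors(codeFactors(...))}
#' returns the original formulation.
#'
#' @param coded data.frame (or named list) with columns \code{A}..\code{E}
#'   in [-1, +1].
#' @return data.frame with natural columns \code{oil_pct}, \code{starch_pct},
#'   \code{caseinate_pct}, \code{stir_rpm}, \code{stir_min}.
#' @export
decodeFactors <- function(coded) {
  out <- lapply(seq_len(5), function(i) {
    r <- .factorRanges[i, ]
    x <- coded[[r$factor]]
    if (any(abs(x) > 1 + 1e-9)) stop("coded ", r$factor, " outside [-1, +1]")
    (r$low + r$high) / 2 + x * (r$high - r$low) / 2
  })
  names(out) <- .factorRanges$name
  as.data.frame(out)
}

# m/M/a labels from a coded row, e.g. "M/M/M/M/M" for run 24
.codedLabel <- function(coded) {
  apply(as.matrix(coded[, LETTERS[1:5]]), 1, function(z)
    paste(ifelse(z < -0.5, "m", ifelse(z > 0.5, "M", "a")), collapse = "/"))
}

#' The built-in 24-run screening design
#'
#' The computer-generated (D-optimal style) plan used throughout: 21 vertex
#' runs plus 3 centre points, split over 3 blocks of 8.  Returned in coded
#' units with blocks and the conventional m/M/a level labels.
#'
#' @return data.frame with columns \code{run}, \code{block},
#'   \code{A}..\code{E} (coded) and \code{label}.
#' @seealso [designTable()] for the same runs with natural units and the
#'   measured responses.
#' @export
builtinDesign <- function() {
  d <- designTable()
  d[, c("run", "block", "A", "B", "C", "D", "E", "label")]
}

#' The screening design with its measured responses
#'
#' The bundled study table: the 24 formulations in natural and coded units,
#' the mean droplet sizes after preparation (\code{size_t0_um}) and after
#' 5 h of storage (\code{size_t5_um}), the ordinal creaming class (1 fast
#' separation .. 5 no separation), and the derived storage columns
#' \code{size_diff_um} and \code{size_var_pct} recomputed with
#' [variationRate()].
#'
#' @return data.frame with one row per run.
#' @export
designTable <- function() {
  path <- system.file("extdata", "argan_design.csv", package = "creamdex")
  d <- readDesignTable(path)
  coded <- codeFactors(d$oil_pct, d$starch_pct, d$caseinate_pct,
                       d$stir_rpm, d$stir_min)
  v <- variationRate(d$size_t0_um, d$size_t5_um)
  cbind(d, coded,
        label = .codedLabel(coded),
        size_diff_um = v$difference, size_var_pct = v$ratePct)
}

#' The bundled creaming-index table
#'
#' Yield values, average (ADS = d32) and largest (LDS) droplet sizes,
#' droplet micro-stresses ("pressures") and creaming indices of the five
#' storage-stable emulsions, as printed in the study report.  The LDS row
#' of the printed table is typeset without separators; the transcription
#' here is the unique parse under which every printed pressure and index is
#' internally consistent.  Printed pressure units are taken as Pa.
#'
#' @return data.frame with columns \code{sample}, \code{yield_pa},
#'   \code{ads_um}, \code{lds_um}, \code{ads_pressure_pa},
#'   \code{lds_pressure_pa}, \code{ci_ads}, \code{ci_lds}.
#' @export
creamingTable <- function() {
  path <- system.file("extdata", "argan_creaming.csv", package = "creamdex")
  read.csv(path)
}

#' Default model term sets per response
#'
#' The coded terms of the reported linearisation models.  The published
#' table's interaction rows are partly garbled in print; these sets are the
#' ones whose refit reproduces every printed coefficient to its printed
#' rounding (for the 5 h size model that includes a DE term whose
#' coefficient was evidently dropped in typesetting, and the variation-rate
#' model's \code{CD} appears in print mislabelled as a second DE row).
#'
#' @param response \code{"s0"} (size at T0, log10 model), \code{"s5"}
#'   (size at T5, sqrt), \code{"var"} (variation rate, sqrt) or
#'   \code{"class"} (ordinal creaming class, inverse-sqrt; the dominant
#'   stirring effects plus the starch-by-time interaction, with starch kept
#'   for hierarchy).
#' @return character vector of coded terms.
#' @export
defaultTerms <- function(response = c("s0", "s5", "var", "class")) {
  switch(match.arg(response),
    s0 = c("A", "B", "C", "D", "E", "AB", "AE", "BC", "CE", "DE"),
    s5 = c("A", "B", "C", "D", "E", "AB", "AE", "BD", "CE", "DE"),
    var = c("A", "B", "C", "D", "E", "AE", "BC", "CD", "DE"),
    class = c("B", "D", "E", "BE"))
}

#' Default response transform per response
#'
#' @inheritParams defaultTerms
#' @return transform name accepted by [fitLinearModel()].
#' @export
defaultTransform <- function(response = c("s0", "s5", "var", "class")) {
  switch(match.arg(response), s0 = "log10", s5 = "sqrt", var = "sqrt",
         class = "inverse-sqrt")
}
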
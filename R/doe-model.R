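# ---- response transforms -------------------------------------------------

#' Apply or invert a named response transform
#'
#' The canonical Box-Cox family members used for response linearisation:
#' log10 (lambda 0), square root (1/2), inverse square root (-1/2) and
#' identity (1).  \code{applyTransform} maps a response onto the model
#' scale; \code{invertTransform} maps a linear predictor back.
#'
#' @param y response values (positive where the transform requires it).
#' @param eta linear predictor on the transformed scale.
#' @param transform one of \code{"log10"}, \code{"sqrt"},
#'   \code{"inverse-sqrt"}, \code{"identity"}.
#' @return transformed response, or back-transformed prediction.
#' @export
applyTransform <- function(y, transform = c("log10", "sqrt", "inverse-sqrt",
                                            "identity")) {
  transform <- match.arg(transform)
  if (transform != "identity" && any(y <= 0))
    stop("transform '", transform, "' needs a positive response")
  switch(transform, log10 = log10(y), sqrt = sqrt(y),
         `inverse-sqrt` = 1 / sqrt(y), identity = y)
}

#' @rdname applyTransform
#' @export
invertTransform <- function(eta, transform = c("log10", "sqrt",
                                               "inverse-sqrt", "identity")) {
  transform <- match.arg(transform)
  if (transform == "sqrt" && any(eta < 0))
    stop("negative linear predictor cannot be squared back to a sqrt response")
  if (transform == "inverse-sqrt" && any(eta <= 0))
    stop("non-positive linear predictor under the inverse-sqrt transform")
  switch(transform, log10 = 10^eta, sqrt = eta^2,
         `inverse-sqrt` = eta^-2, identity = eta)
}

# ---- model matrix --------------------------------------------------------

# Coded model matrix for a term set, optionally with sum-to-zero block
# contrasts (so the intercept stays the grand constant).  Interaction terms
# automatically pull in their parent main effects (model hierarchy).
.modelMatrix <- function(design, terms, blocks = TRUE) {
  terms <- .enforceHierarchy(terms)
  cols <- lapply(terms, function(tm) .codedColumn(design, tm))
  M <- do.call(cbind, cols)
  colnames(M) <- terms
  if (blocks) {
    if (!"block" %in% names(design))
      stop("design has no 'block' column")
    b <- factor(design$block)
    if (nlevels(b) > 1L) {
      B <- model.matrix(~b, contrasts.arg = list(b = "contr.sum"))[, -1,
                                                                   drop = FALSE]
      colnames(B) <- paste0("block", seq_len(ncol(B)))
      M <- cbind(B, M)
    }
  }
  M
}

# interactions imply their parent main effects
.enforceHierarchy <- function(terms) {
  parents <- unique(unlist(strsplit(terms[nchar(terms) == 2], "")))
  unique(c(intersect(LETTERS[1:5], union(terms, parents)),
           terms[nchar(terms) == 2]))
}

# ---- Box-Cox scan --------------------------------------------------------

#' Box-Cox power-transform scan
#'
#' Scans the Box-Cox power family over a lambda grid and picks the power
#' minimising the residual sum of squares of the linear model on the
#' normalised scale
#' \eqn{y^{(\lambda)} = (y^\lambda - 1) / (\lambda \dot{g}^{\lambda - 1})}
#' (with the \eqn{\lambda = 0} limit \eqn{\dot{g} \ln y}), where
#' \eqn{\dot{g}} is the geometric mean of the response.  Normalisation
#' makes the SSE comparable across lambda, so the minimiser is the
#' maximum-likelihood lambda.  The scan model is the model that will be
#' fitted, including its block columns.
#'
#' The scan also names the canonical family member nearest the best lambda
#' among log10 (0), sqrt (1/2), inverse-sqrt (-1/2) and identity (1),
#' provided the best lambda lies within 0.25 of it; otherwise the name is
#' \code{"power"}.  A 95\% profile-likelihood interval for lambda is
#' reported alongside.
#'
#' @param y positive response vector.
#' @param X numeric model matrix (without intercept column; one is added).
#' @param lambdas lambda grid; must cover at least [-2, 2].
#' @return list with \code{lambda} (best), \code{name} (named transform),
#'   \code{ci} (95\% interval), and \code{grid} (data.frame of lambda, sse).
#' @examples
#' d <- designTable()
#' X <- doeModelMatrix(d, defaultTerms("s0"))
#' boxcoxScan(d$size_t0_um, X)$lambda
#' @export
boxcoxScan <- function(y, X, lambdas = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) stop("Box-Cox scan needs a strictly positive response")
  if (min(lambdas) > -2 || max(lambdas) < 2)
    stop("lambda grid must cover at least [-2, 2]")
  g <- exp(mean(log(y)))
  n <- length(y)
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  sse <- vapply(lambdas, function(l) {
    z <- if (abs(l) < 1e-12) g * log(y) else (y^l - 1) / (l * g^(l - 1))
    sum(qr.resid(qrX, z)^2)
  }, numeric(1))
  best <- lambdas[which.min(sse)]
  ll <- -n / 2 * log(sse)
  inCi <- lambdas[ll > max(ll) - stats::qchisq(0.95, 1) / 2]
  canon <- c(log10 = 0, sqrt = 0.5, `inverse-sqrt` = -0.5, identity = 1)
  i <- which.min(abs(canon - best))
  name <- if (abs(canon[i] - best) <= 0.25) names(canon)[i] else "power"
  list(lambda = best, name = name, ci = range(inCi),
       grid = data.frame(lambda = lambdas, sse = sse))
}

#' Coded model matrix for a design and term set
#'
#' Builds the columns of the coded linear model: optional sum-to-zero block
#' contrasts, main effects and two-factor interaction products.  Parent
#' main effects of any interaction are added automatically (model
#' hierarchy).
#'
#' @param design data.frame with coded columns \code{A}..\code{E} and a
#'   \code{block} column, e.g. [designTable()].
#' @param terms coded terms (\code{"A"}..\code{"E"}, \code{"AB"}, ...).
#' @param blocks include block indicator columns (default \code{TRUE}).
#' @return numeric model matrix without intercept.
#' @export
doeModelMatrix <- function(design, terms, blocks = TRUE) {
  .modelMatrix(design, terms, blocks)
}

# ---- OLS fit -------------------------------------------------------------

#' Fit a coded-factor linear model
#'
#' Ordinary least squares of a transformed response on coded main effects,
#' two-factor interactions and fixed block indicators (sum-to-zero
#' contrasts, so the reported constant is the grand constant of the
#' linearisation equation).  Reports coefficients with standard errors and
#' t-values, and the R-squared triple: raw \eqn{1 - SSE/SST}, adjusted,
#' and predicted \eqn{1 - PRESS/SST} where PRESS uses the closed-form
#' leave-one-out residuals \eqn{e_i / (1 - h_{ii})}.  Because the study
#' leaves open whether published R-squared values include block effects,
#' the triple is also recomputed from a refit without block columns
#' (\code{raw_noblock} etc.).
#'
#' @param design data.frame with coded columns \code{A}..\code{E} and
#'   \code{block}; see [designTable()].
#' @param y response on the original scale, or (if \code{response} is a
#'   column name) \code{NULL}.
#' @param terms coded model terms; defaults to [defaultTerms()] when
#'   \code{response} is one of the four named responses.
#' @param transform response transform applied before fitting; use
#'   \code{"scan"} to let [boxcoxScan()] choose the named family.
#' @param response optional label stored on the fit; one of \code{"s0"},
#'   \code{"s5"}, \code{"var"}, \code{"class"} selects the bundled response
#'   column, its default terms and default transform.
#' @param blocks include block columns (default \code{TRUE}).
#' @return a [DoeFit-class].
#' @examples
#' fit <- fitLinearModel(designTable(), response = "s0")
#' rSquared(fit)["raw"]   # 0.965
#' @export
fitLinearModel <- function(design, y = NULL, terms = NULL,
                           transform = NULL, response = "y", blocks = TRUE) {
  if (is.null(y)) {
    col <- switch(response, s0 = "size_t0_um", s5 = "size_t5_um",
                  var = "size_var_pct", class = "creaming_class",
                  stop("no response vector given"))
    y <- design[[col]]
    if (is.null(y)) stop("design lacks response column ", col)
  }
  if (is.null(terms) && response %in% c("s0", "s5", "var", "class"))
    terms <- defaultTerms(response)
  if (is.null(terms)) stop("no model terms given")
  X <- .modelMatrix(design, terms, blocks)
  terms <- setdiff(colnames(X), grep("^block", colnames(X), value = TRUE))
  scanned <- NA_real_
  if (is.null(transform) && response %in% c("s0", "s5", "var", "class"))
    transform <- defaultTransform(response)
  if (identical(transform, "scan")) {
    sc <- boxcoxScan(y, X)
    if (sc$name == "power")
      stop("Box-Cox scan found no canonical transform near lambda = ",
           sc$lambda, "; impose one explicitly")
    transform <- sc$name
    scanned <- sc$lambda
  }
  z <- applyTransform(y, transform)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("aliasing: model terms are collinear (",
         paste(colnames(X), collapse = ", "), ")")
  fit <- lm(z ~ X)
  s <- summary(fit)
  cf <- s$coefficients
  ctab <- data.frame(
    term = c("constant", colnames(X)),
    estimate = cf[, 1], se = cf[, 2], t = cf[, 3], row.names = NULL)
  r2 <- c(.r2Triple(fit, z), setNames(
    .r2Triple(lm(z ~ .modelMatrix(design, terms, blocks = FALSE)), z),
    c("raw_noblock", "adjusted_noblock", "predicted_noblock")))
  new("DoeFit", response = response, transform = transform,
      lambda = scanned, terms = terms, coefficients = ctab, r2 = r2,
      dfResidual = as.integer(fit$df.residual), fit = fit)
}

.r2Triple <- function(fit, z) {
  sst <- sum((z - mean(z))^2)
  press <- sum((resid(fit) / (1 - hatvalues(fit)))^2)
  c(raw = 1 - sum(resid(fit)^2) / sst,
    adjusted = 1 - (1 - (1 - sum(resid(fit)^2) / sst)) *
      (length(z) - 1) / fit$df.residual,
    predicted = 1 - press / sst)
}

#' @export
setMethod("coefTable", "DoeFit", function(x) x@coefficients)

#' @export
setMethod("rSquared", "DoeFit", function(x) x@r2)

#' @export
setMethod("modelTerms", "DoeFit", function(x) x@terms)

#' @export
setMethod("transformName", "DoeFit", function(x) x@transform)

setMethod("show", "DoeFit", function(object) {
  cat(sprintf("DoeFit '%s': %s transform, %d terms, %d residual df\n",
              object@response, object@transform, length(object@terms),
              object@dfResidual))
  cat(sprintf("  R2 raw %.3f, adjusted %.3f, predicted %.3f\n",
              object@r2[["raw"]], object@r2[["adjusted"]],
              object@r2[["predicted"]]))
})

# ---- effect screening ----------------------------------------------------

#' Pareto ranking of standardised effects
#'
#' Ranks the model effects by absolute t-value and draws the two screening
#' thresholds of an effect Pareto chart: the plain two-sided t critical
#' value at \code{alpha}, and the Bonferroni-corrected critical value at
#' \code{alpha / mEffects}.  Effects above the Bonferroni limit are flagged
#' highly significant; those between the limits, significant.
#'
#' @param fit a [DoeFit-class] with positive residual df.
#' @param alpha significance level (default 0.05).
#' @param mEffects number of effects behind the Bonferroni correction;
#'   defaults to the number of non-block model effects.
#' @return data.frame of effects sorted by decreasing |t|, with columns
#'   \code{term}, \code{estimate}, \code{t}, \code{flag}, and attributes
#'   \code{tLimit} and \code{bonferroniLimit}.
#' @export
effectPareto <- function(fit, alpha = 0.05, mEffects = NULL) {
  stopifnot(is(fit, "DoeFit"))
  if (fit@dfResidual <= 0L)
    stop("zero residual degrees of freedom: screening limits undefined")
  ct <- fit@coefficients
  eff <- ct[ct$term %in% fit@terms, ]
  if (is.null(mEffects)) mEffects <- nrow(eff)
  if (mEffects < 1L) stop("mEffects must be >= 1")
  tLimit <- qt(1 - alpha / 2, fit@dfResidual)
  bonfLimit <- qt(1 - alpha / (2 * mEffects), fit@dfResidual)
  eff <- eff[order(-abs(eff$t)), c("term", "estimate", "t")]
  eff$flag <- ifelse(abs(eff$t) >= bonfLimit, "highly-significant",
                     ifelse(abs(eff$t) >= tLimit, "significant", "none"))
  rownames(eff) <- NULL
  attr(eff, "tLimit") <- tLimit
  attr(eff, "bonferroniLimit") <- bonfLimit
  eff
}

#' Predict a response at a coded point
#'
#' Evaluates the fitted linearisation equation (grand constant plus coded
#' effects; block effects average out under the sum-to-zero coding) and
#' back-transforms onto the original response scale.
#'
#' @param fit a [DoeFit-class].
#' @param point named numeric with coordinates \code{A}..\code{E} in
#'   [-1, +1] (interaction products are formed internally).
#' @return predicted response on the original scale.
#' @examples
#' fit <- fitLinearModel(designTable(), response = "s0")
#' predictResponse(fit, c(A = 0, B = 0, C = 0, D = 0, E = 0))  # ~ 10^1.34
#' @export
predictResponse <- function(fit, point) {
  stopifnot(is(fit, "DoeFit"))
  mains <- unique(unlist(strsplit(fit@terms, "")))
  if (!all(mains %in% names(point)))
    stop("point must name coordinates ", paste(mains, collapse = ", "))
  if (any(abs(point[mains]) > 1 + 1e-9))
    stop("coded coordinates must lie in [-1, +1]")
  ct <- fit@coefficients
  eta <- ct$estimate[ct$term == "constant"]
  for (tm in fit@terms) {
    x <- prod(point[strsplit(tm, "")[[1]]])
    eta <- eta + ct$estimate[ct$term == tm] * x
  }
  invertTransform(eta, fit@transform)
}
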
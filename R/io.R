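# ---- schema-checked CSV io ----------------------------------------------

.schemas <- list(
  design = c(run = "integer", block = "integer", oil_pct = "numeric",
             starch_pct = "numeric", caseinate_pct = "numeric",
             stir_rpm = "numeric", stir_min = "numeric",
             size_t0_um = "numeric", size_t5_um = "numeric",
             creaming_class = "integer"),
  flowcurve = c(frequency_hz = "numeric", stress_pa = "numeric"),
  droplets = c(droplet_id = "integer", diameter_px = "numeric",
               diameter_um = "numeric"))

# read a CSV against a named column-type schema; errors name the offender
.readChecked <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e)))
  missing <- setdiff(names(schema), names(d))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in names(schema)) {
    x <- d[[col]]
    ok <- switch(schema[[col]],
                 integer = is.numeric(x) && all(x == round(x)),
                 numeric = is.numeric(x))
    if (!ok)
      stop("schema error in ", basename(path), ": column '", col,
           "' is not ", schema[[col]])
  }
  d
}

# write numeric columns at full precision so write -> read round-trips
.writeChecked <- function(d, path) {
  out <- d
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a design/response table
#'
#' CSV schema: \code{run}, \code{block}, \code{oil_pct}, \code{starch_pct},
#' \code{caseinate_pct}, \code{stir_rpm}, \code{stir_min},
#' \code{size_t0_um}, \code{size_t5_um}, \code{creaming_class}.
#' Comma-separated, '.' decimal, mandatory header.  Schema violations and
#' duplicated run ids raise errors naming the offending column or row.
#'
#' @param path CSV path.
#' @param design data.frame to write (extra columns are preserved).
#' @return the table (read) or the path, invisibly (write).
#' @export
readDesignTable <- function(path) {
  d <- .readChecked(path, .schemas$design)
  dup <- d$run[duplicated(d$run)]
  if (length(dup))
    stop("schema error in ", basename(path), ": duplicated run id(s) ",
         paste(unique(dup), collapse = ", "))
  if (any(!d$creaming_class %in% 1:5))
    stop("schema error in ", basename(path),
         ": creaming_class outside 1..5")
  d
}

#' @rdname readDesignTable
#' @export
writeDesignTable <- function(design, path) {
  missing <- setdiff(names(.schemas$design), names(design))
  if (length(missing))
    stop("design lacks column(s) ", paste(missing, collapse = ", "))
  .writeChecked(design, path)
}

#' Read or write a flow-curve CSV
#'
#' Schema: \code{frequency_hz}, \code{stress_pa}.
#'
#' @param path CSV path.
#' @param curve a [FlowCurve-class] to write.
#' @param sampleId,temperature metadata attached on read.
#' @return a [FlowCurve-class] (read) or the path, invisibly (write).
#' @export
readFlowCurve <- function(path, sampleId = NA_character_, temperature = 25) {
  d <- .readChecked(path, .schemas$flowcurve)
  flowCurve(d$frequency_hz, d$stress_pa, sampleId = sampleId,
            temperature = temperature)
}

#' @rdname readFlowCurve
#' @export
writeFlowCurve <- function(curve, path) {
  stopifnot(is(curve, "FlowCurve"))
  .writeChecked(data.frame(frequency_hz = curve@frequency,
                           stress_pa = curve@stress), path)
}

#' Read or write a droplet table
#'
#' Schema: \code{droplet_id}, \code{diameter_px}, \code{diameter_um}.
#'
#' @param path CSV path.
#' @param droplets data.frame to write.
#' @return data.frame (read) or the path, invisibly (write).
#' @export
readDropletTable <- function(path) .readChecked(path, .schemas$droplets)

#' @rdname readDropletTable
#' @export
writeDropletTable <- function(droplets, path) {
  missing <- setdiff(names(.schemas$droplets), names(droplets))
  if (length(missing))
    stop("droplet table lacks column(s) ", paste(missing, collapse = ", "))
  .writeChecked(droplets, path)
}

# ---- image io ------------------------------------------------------------

#' Read or write a grayscale micrograph as 8-bit PNG
#'
#' @param image numeric intensity matrix in [0, 1].
#' @param path PNG path.
#' @return the intensity matrix (read) or the path, invisibly (write).
#' @export
writeMicrograph <- function(image, path) {
  m <- pmin(pmax(as.matrix(image), 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname writeMicrograph
#' @export
readMicrograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}
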
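# Amino-acid property scales.

#' Construct a polarity scale
#'
#' @param values Named numeric vector with one finite positive value per
#'   canonical amino acid (any order; one-letter names).
#' @return A \linkS4class{PolarityScale}.
#' @export
polarityScale <- function(values) {
  if (is.null(names(values)))
    stop("values must be named by one-letter amino-acid codes")
  missing <- setdiff(.AA20, names(values))
  if (length(missing))
    stop("scale is missing amino acid(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(values), .AA20)
  if (length(extra))
    stop("unknown amino-acid symbol(s): ", paste(extra, collapse = ", "))
  obj <- new("PolarityScale", values = values[.AA20])
  validObject(obj)
  obj
}

#' The Woese polar requirement
#'
#' The bundled chromatographic polarity index of the 20 amino acids
#' (AAindex accession WOEC730101), the default p(.) of the cost function.
#' Published transcriptions of the index differ slightly for Cys, Trp and
#' Tyr; use [polarityScale()] to supply an alternative transcription when
#' probing that sensitivity.
#'
#' @return A \linkS4class{PolarityScale}.
#' @examples
#' scaleValues(woesePolarity())
#' @export
woesePolarity <- function() {
  new("PolarityScale", values = .POLARITY_WOESE)
}

#' @rdname polarityScale
#' @param x A \linkS4class{PolarityScale}.
#' @export
scaleValues <- function(x) {
  stopifnot(is(x, "PolarityScale"))
  x@values
}

setMethod("show", "PolarityScale", function(object) {
  cat("PolarityScale (20 amino acids):\n")
  print(object@values)
  invisible(object)
})
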
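#' @include AllClasses.R
NULL

#' Accessors for Lexis-surface objects
#'
#' `ages()` and `years()` return the integer axes, `surfaceValues()` the
#' age-by-year value matrix (with `NA` for missing cells), and
#' `surfaceMetadata()` the metadata list.
#'
#' @param x a [LexisSurface-class] derivative.
#' @return integer vector, numeric matrix, or list, respectively.
#' @aliases ages years surfaceValues surfaceMetadata
#' @name surface-accessors
#' @examples
#' s <- MortalitySurface(matrix(0.01, 2, 3), ages = 0:1, years = 2000:2002)
#' ages(s)
#' surfaceValues(s)
NULL

#' @rdname surface-accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname surface-accessors
#' @export
setGeneric("years", function(x) standardGeneric("years"))

#' @rdname surface-accessors
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))

#' @rdname surface-accessors
#' @export
setGeneric("surfaceMetadata", function(x) standardGeneric("surfaceMetadata"))

#' Extract draws of one parameter
#'
#' @param x a [ParameterDraws-class] object.
#' @param name parameter name, e.g. `"beta1"`, `"sigma"`.
#' @return matrix of draws (rows = retained draws pooled over chains,
#'   columns = scalar components).
#' @export
setGeneric("parameterDraws", function(x, name) {
  standardGeneric("parameterDraws")
})
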
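#' @include AllClasses.R AllGenerics.R
NULL

.newSurface <- function(class, values, ages, years, metadata = list()) {
  values <- as.matrix(values)
  ages <- as.integer(ages)
  years <- as.integer(years)
  dimnames(values) <- list(age = as.character(ages), year = as.character(years))
  new(class, values = values, ages = ages, years = years, metadata = metadata)
}

#' Construct a death-rate surface
#'
#' @param values numeric matrix of central death rates, ages in rows, years
#'   in columns; `NA` marks missing cells.
#' @param ages,years integer axes (both contiguous, step 1).
#' @param metadata named list (population, sex, source, ...).
#' @return a [MortalitySurface-class] object.
#' @examples
#' m <- MortalitySurface(matrix(c(0.01, 0.02), 2, 4), ages = 0:1,
#'                       years = 2000:2003)
#' m
#' @export
MortalitySurface <- function(values, ages, years, metadata = list()) {
  .newSurface("MortalitySurface", values, ages, years, metadata)
}

#' Construct an exposure (or death-count) surface
#'
#' @inheritParams MortalitySurface
#' @return an [ExposureSurface-class] object.
#' @export
ExposureSurface <- function(values, ages, years, metadata = list()) {
  .newSurface("ExposureSurface", values, ages, years, metadata)
}

#' Construct an improvement-rate surface
#'
#' Year labels follow the earlier-year convention: column t describes the
#' m\[x, t\] -> m\[x, t+1\] transition.
#'
#' @inheritParams MortalitySurface
#' @return a [ROMISurface-class] object.
#' @export
ROMISurface <- function(values, ages, years, metadata = list()) {
  .newSurface("ROMISurface", values, ages, years, metadata)
}

#' @rdname surface-accessors
#' @export
setMethod("ages", "LexisSurface", function(x) x@ages)

#' @rdname surface-accessors
#' @export
setMethod("years", "LexisSurface", function(x) x@years)

#' @rdname surface-accessors
#' @export
setMethod("surfaceValues", "LexisSurface", function(x) x@values)

#' @rdname surface-accessors
#' @export
setMethod("surfaceMetadata", "LexisSurface", function(x) x@metadata)

setMethod("show", "LexisSurface", function(object) {
  v <- object@values
  cat(sprintf(
    "%s: %d ages (%d-%d) x %d years (%d-%d)\n",
    class(object), length(object@ages), min(object@ages), max(object@ages),
    length(object@years), min(object@years), max(object@years)
  ))
  nmiss <- sum(is.na(v))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf(
    "  values in [%.6g, %.6g], %d missing cell%s\n",
    rng[1], rng[2], nmiss, if (nmiss == 1L) "" else "s"
  ))
  md <- object@metadata
  if (length(md)) {
    keep <- vapply(md, function(el) is.atomic(el) && length(el) == 1L, logical(1))
    if (any(keep)) {
      cat("  metadata:",
          paste(names(md)[keep], unlist(md[keep]), sep = "=", collapse = ", "),
          "\n")
    }
  }
  invisible(NULL)
})

#' Subset a surface by age and/or year
#'
#' @param x a surface object.
#' @param i,j integer AGE and YEAR values (not positions); either may be
#'   missing. The selection must remain contiguous.
#' @param ... ignored.
#' @param drop ignored; the result is always a surface.
#' @return a surface of the same class.
#' @export
setMethod("[", "LexisSurface", function(x, i, j, ..., drop = FALSE) {
  ai <- if (missing(i)) seq_along(x@ages) else match(as.integer(i), x@ages)
  yi <- if (missing(j)) seq_along(x@years) else match(as.integer(j), x@years)
  if (anyNA(ai)) stop("some requested ages are not on the surface")
  if (anyNA(yi)) stop("some requested years are not on the surface")
  .newSurface(class(x), x@values[ai, yi, drop = FALSE],
              x@ages[ai], x@years[yi], x@metadata)
})

#' Test two surfaces for equal grids and values
#'
#' @param a,b surfaces.
#' @return logical.
#' @keywords internal
sameSurface <- function(a, b) {
  identical(a@ages, b@ages) && identical(a@years, b@years) &&
    isTRUE(all.equal(a@values, b@values, tolerance = 0)) &&
    identical(is.na(a@values), is.na(b@values))
}

.checkAligned <- function(a, b, what = "surfaces") {
  if (!identical(a@ages, b@ages) || !identical(a@years, b@years)) {
    stop(what, " are misaligned: grids differ")
  }
  invisible(TRUE)
}
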
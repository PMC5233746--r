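#' @include surfaces.R
NULL

## Readers/writers for the Human Mortality Database 1x1 fixed-width layout
## (Mx_1x1 / Deaths_1x1 / Exposures_1x1) and a long-format CSV used for all
## package output. The HMD layout is: a title line, a blank line, a header
## line "Year Age Female Male Total", then whitespace-separated rows. Ages
## run 0..109 plus an open "110+" row; the missing-value token is ".".

.parseAgeToken <- function(tok) {
  open <- grepl("\\+$", tok)
  age <- suppressWarnings(as.integer(sub("\\+$", "", tok)))
  list(age = age, open = open)
}

#' Read an HMD-style 1x1 life-table input file
#'
#' Parses the fixed-width text layout used by the Human Mortality Database
#' for period death rates (`Mx_1x1`), death counts (`Deaths_1x1`) and
#' exposures (`Exposures_1x1`), returning one sex column as a rectangular
#' surface. Ages above `openAge` are aggregated into the open age group:
#' deaths and exposures are summed; for rates the value at `openAge` itself
#' is used (supply counts and exposures and use [ratesFromCounts()] for an
#' exposure-weighted open-age rate). Missing cells (token `"."`) stay
#' missing; they are never zero-filled.
#'
#' @param path path to the text file.
#' @param valueKind `"rates"`, `"deaths"` or `"exposures"`.
#' @param sex column to extract: `"Female"`, `"Male"` or `"Total"`.
#' @param openAge open-ended age group of the returned surface (default 100,
#'   so raw HMD ages 100-110+ collapse into 100+).
#' @return a [MortalitySurface-class] (`valueKind = "rates"`) or
#'   [ExposureSurface-class] (otherwise).
#' @examples
#' tf <- tempfile()
#' writeLines(c(
#'   "Demo, Death rates (period 1x1)", "",
#'   "  Year          Age             Female            Male           Total",
#'   "  2000           0             0.005000        0.006000        0.005500",
#'   "  2000         110+            0.700000        0.750000        0.720000",
#'   "  2001           0             0.004900        0.005900        0.005400",
#'   "  2001         110+            0.690000        0.740000        0.710000"
#' ), tf)
#' readHMDTable(tf, "rates", sex = "Female", openAge = 1)
#' @export
readHMDTable <- function(path, valueKind = c("rates", "deaths", "exposures"),
                         sex = c("Female", "Male", "Total"),
                         openAge = 100L) {
  valueKind <- match.arg(valueKind)
  sex <- match.arg(sex)
  openAge <- as.integer(openAge)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*Year\\s+Age\\s+Female\\s+Male\\s+Total\\s*$", lines)
  if (!length(hdr)) {
    stop("not an HMD 1x1 table: no 'Year Age Female Male Total' header in ",
         path)
  }
  body <- seq.int(hdr[1] + 1L, length(lines))
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body)) stop("HMD table has no data rows: ", path)

  toks <- strsplit(trimws(lines[body]), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 5L)) {
    bad <- body[which(nf != 5L)[1]]
    stop("malformed HMD row at line ", bad, ": expected 5 fields, got ",
         nf[which(nf != 5L)[1]])
  }
  tab <- do.call(rbind, toks)
  year <- suppressWarnings(as.integer(tab[, 1]))
  if (anyNA(year)) {
    stop("malformed HMD row at line ", body[which(is.na(year))[1]],
         ": unparseable year '", tab[which(is.na(year))[1], 1], "'")
  }
  ageTok <- .parseAgeToken(tab[, 2])
  if (anyNA(ageTok$age)) {
    stop("malformed HMD row at line ", body[which(is.na(ageTok$age))[1]],
         ": unparseable age '", tab[which(is.na(ageTok$age))[1], 2], "'")
  }
  col <- match(sex, c("Year", "Age", "Female", "Male", "Total"))
  raw <- tab[, col]
  val <- suppressWarnings(as.numeric(raw))
  badVal <- which(is.na(val) & raw != ".")
  if (length(badVal)) {
    stop("malformed HMD row at line ", body[badVal[1]],
         ": unparseable value '", raw[badVal[1]], "'")
  }

  yrs <- sort(unique(year))
  if (length(yrs) > 1L && !all(diff(yrs) == 1L)) {
    stop("non-contiguous years in ", path, ": found gap after ",
         yrs[which(diff(yrs) != 1L)[1]])
  }
  ageGrp <- pmin(ageTok$age, openAge)
  agesOut <- sort(unique(ageGrp))
  if (length(agesOut) > 1L && !all(diff(agesOut) == 1L)) {
    stop("non-contiguous ages in ", path)
  }

  acc <- matrix(0, length(agesOut), length(yrs),
                dimnames = list(agesOut, yrs))
  nobs <- matrix(0L, length(agesOut), length(yrs))
  anyNAcell <- matrix(FALSE, length(agesOut), length(yrs))
  ri <- match(ageGrp, agesOut)
  ci <- match(year, yrs)
  idx <- cbind(ri, ci)
  if (valueKind %in% c("deaths", "exposures")) {
    for (k in seq_along(val)) {
      if (is.na(val[k])) anyNAcell[ri[k], ci[k]] <- TRUE
      else acc[ri[k], ci[k]] <- acc[ri[k], ci[k]] + val[k]
      nobs[ri[k], ci[k]] <- nobs[ri[k], ci[k]] + 1L
    }
    out <- acc
    out[anyNAcell] <- NA_real_
  } else {
    ## rates: within each aggregated cell keep the value at the group's
    ## smallest raw age (the rate observed AT the open age); assign in
    ## decreasing raw-age order so the smallest age wins
    out <- matrix(NA_real_, length(agesOut), length(yrs))
    ord <- order(ageTok$age, decreasing = TRUE)
    out[idx[ord, , drop = FALSE]] <- val[ord]
    nobs[idx] <- 1L
    out[!is.na(out) & out <= 0] <- NA_real_
  }
  if (any(nobs == 0L)) {
    stop("HMD table is not rectangular: some (age, year) cells absent in ",
         path)
  }

  md <- list(source = path, sex = sex, kind = valueKind)
  if (valueKind == "rates") {
    MortalitySurface(out, agesOut, yrs, md)
  } else {
    ExposureSurface(out, agesOut, yrs, md)
  }
}

#' Death rates from death counts and exposures
#'
#' m\[x, t\] = D\[x, t\] / E\[x, t\]. Cells with zero exposure are flagged
#' missing, and so are cells with zero deaths: a zero rate cannot feed the
#' improvement-rate transform, which divides by m\[x, t\].
#'
#' @param deaths [ExposureSurface-class] of death counts.
#' @param exposures [ExposureSurface-class] of person-years, same grid.
#' @return a [MortalitySurface-class].
#' @examples
#' d <- ExposureSurface(matrix(10, 1, 2), 0, 2000:2001)
#' e <- ExposureSurface(matrix(1000, 1, 2), 0, 2000:2001)
#' surfaceValues(ratesFromCounts(d, e))
#' @export
ratesFromCounts <- function(deaths, exposures) {
  stopifnot(is(deaths, "ExposureSurface"), is(exposures, "ExposureSurface"))
  .checkAligned(deaths, exposures, "deaths and exposures")
  m <- deaths@values / exposures@values
  m[!is.finite(m) | m <= 0] <- NA_real_
  md <- deaths@metadata
  md$kind <- "rates"
  MortalitySurface(m, deaths@ages, deaths@years, md)
}

#' Write a surface as long-format CSV
#'
#' Columns `age, year, value, missing`; missing cells have an empty value
#' field and `missing = 1`. Values are printed with 17 significant digits so
#' that [readSurfaceCSV()] reproduces the surface bit-exactly.
#'
#' @param surface any [LexisSurface-class] derivative.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSurfaceCSV <- function(surface, path) {
  v <- surface@values
  df <- data.frame(
    age = rep(surface@ages, times = length(surface@years)),
    year = rep(surface@years, each = length(surface@ages)),
    value = ifelse(is.na(as.vector(v)), "", sprintf("%.17g", as.vector(v))),
    missing = as.integer(is.na(as.vector(v)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format surface CSV written by [writeSurfaceCSV()]
#'
#' @param path input file.
#' @param kind class of the result: `"rates"`, `"romi"` or `"exposures"`.
#' @return the surface object.
#' @export
readSurfaceCSV <- function(path, kind = c("rates", "romi", "exposures")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, colClasses = c(
    age = "integer", year = "integer", value = "character",
    missing = "integer"
  ))
  if (!all(c("age", "year", "value", "missing") %in% names(df))) {
    stop("not a surface CSV: ", path)
  }
  agesOut <- sort(unique(df$age))
  yrs <- sort(unique(df$year))
  v <- matrix(NA_real_, length(agesOut), length(yrs))
  vals <- suppressWarnings(as.numeric(df$value))
  vals[df$missing == 1L] <- NA_real_
  v[cbind(match(df$age, agesOut), match(df$year, yrs))] <- vals
  ctor <- switch(kind, rates = MortalitySurface, romi = ROMISurface,
                 exposures = ExposureSurface)
  ctor(v, agesOut, yrs, list(source = path))
}
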
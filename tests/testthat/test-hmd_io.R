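test_that("HMD reader parses a small fixture and maps the open age", {
  rows <- rbind(
    c("2000", "0",    "0.005", "0.006", "0.0055"),
    c("2000", "1",    "0.001", "0.001", "0.0010"),
    c("2000", "110+", "0.700", "0.750", "0.7200"),
    c("2001", "0",    "0.004", "0.005", "0.0045"),
    c("2001", "1",    "0.001", "0.001", "0.0010"),
    c("2001", "110+", "0.690", "0.740", "0.7100")
  )
  p <- writeHMDFixture(rows)
  ## open age 2: the 110+ row collapses into age 2 so the grid stays
  ## contiguous (0, 1, 2)
  s <- readHMDTable(p, "rates", sex = "Female", openAge = 2)
  expect_s4_class(s, "MortalitySurface")
  expect_identical(ages(s), 0:2)
  expect_identical(years(s), 2000:2001)
  expect_equal(surfaceValues(s)["2", "2000"], 0.700)
  expect_equal(surfaceValues(s)["0", "2001"], 0.004)
  ## Male column selectable
  sm <- readHMDTable(p, "rates", sex = "Male", openAge = 2)
  expect_equal(surfaceValues(sm)["2", "2001"], 0.740)
})

test_that("missing token '.' gives a flagged missing cell, not zero", {
  rows <- rbind(
    c("2000", "0", ".",     "0.006", "0.0055"),
    c("2000", "1", "0.001", "0.001", "0.0010"),
    c("2001", "0", "0.004", "0.005", "0.0045"),
    c("2001", "1", "0.001", "0.001", "0.0010")
  )
  p <- writeHMDFixture(rows)
  s <- readHMDTable(p, "rates", sex = "Female", openAge = 1)
  expect_true(is.na(surfaceValues(s)["0", "2000"]))
  expect_false(any(surfaceValues(s) == 0, na.rm = TRUE))
})

test_that("deaths are summed into the open age group", {
  rows <- rbind(
    c("2000", "99",   "10", "11", "21"),
    c("2000", "100",  "20", "21", "41"),
    c("2000", "101",  "5",  "6",  "11"),
    c("2000", "102",  "2",  "3",  "5")
  )
  p <- writeHMDFixture(rows)
  s <- readHMDTable(p, "deaths", sex = "Female", openAge = 100)
  expect_identical(ages(s), 99:100)
  expect_equal(surfaceValues(s)["100", "2000"], 20 + 5 + 2)
})

test_that("structural problems are reported with context", {
  rows <- rbind(
    c("1990", "0", "0.005", "0.006", "0.0055"),
    c("1992", "0", "0.004", "0.005", "0.0045")
  )
  expect_error(readHMDTable(writeHMDFixture(rows), "rates", openAge = 0),
               "non-contiguous years")
  bad <- writeHMDFixture(rbind(c("2000", "0", "0.005", "0.006", "0.0055")))
  lines <- readLines(bad)
  lines <- c(lines, "  2000 1 0.001")  # 3 fields only
  writeLines(lines, bad)
  expect_error(readHMDTable(bad, "rates", openAge = 1), "line 5")
})

test_that("rates from counts follow the missing conventions", {
  yrs <- 2000:2001
  d <- ExposureSurface(rbind(c(10, 0), c(5, 7)), 0:1, yrs)
  e <- ExposureSurface(rbind(c(1000, 500), c(0, 700)), 0:1, yrs)
  m <- ratesFromCounts(d, e)
  expect_equal(surfaceValues(m)["0", "2000"], 0.01)   # 10 / 1000
  expect_true(is.na(surfaceValues(m)["0", "2001"]))   # D = 0 -> missing
  expect_true(is.na(surfaceValues(m)["1", "2000"]))   # E = 0 -> missing
  expect_equal(surfaceValues(m)["1", "2001"], 0.01)
  ## misaligned grids refuse
  e2 <- ExposureSurface(rbind(c(1000, 500), c(1, 700)), 1:2, yrs)
  expect_error(ratesFromCounts(d, e2), "misaligned")
})

test_that("surface CSV round-trips bit-exactly including missing cells", {
  s <- randomRateSurface(4, 6, seed = 11)
  v <- surfaceValues(s)
  v[2, 3] <- NA
  s <- MortalitySurface(v, ages(s), years(s))
  p <- tempfile(fileext = ".csv")
  writeSurfaceCSV(s, p)
  back <- readSurfaceCSV(p, "rates")
  expect_identical(surfaceValues(back), surfaceValues(s))
  expect_identical(ages(back), ages(s))
  expect_identical(years(back), years(s))
  ## missing serialized as empty value field
  ln <- readLines(p)
  expect_true(any(grepl("^1,2002,,1$", ln)))
  ## 1x1 surface -> header + 1 data row
  p2 <- tempfile(fileext = ".csv")
  writeSurfaceCSV(MortalitySurface(matrix(0.5, 1, 1), 0, 1999), p2)
  expect_length(readLines(p2), 2L)
})
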
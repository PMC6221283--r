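test_that("era shift is an exact per-layer translation preserving nodata", {
  m1 <- matrix(c(10, 12, NA, 14), 2, 2)
  m2 <- matrix(c(500, 520, 480, NA), 2, 2)
  st <- stack_from(bio1 = m1, bio12 = m2)

  zero <- apply_era_shift(st, c(bio1 = 0, bio12 = 0))
  expect_identical(zero$layers, st$layers)

  up <- apply_era_shift(st, c(bio1 = 5, bio12 = 0))
  expect_equal(mean(stack_layer(up, "bio1"), na.rm = TRUE),
               mean(m1, na.rm = TRUE) + 5)
  expect_identical(is.na(stack_layer(up, "bio1")), is.na(m1))
  expect_identical(is.na(stack_layer(up, "bio12")), is.na(m2))

  expect_error(apply_era_shift(st, c(bio1 = 1)), "offsets")
})

test_that("points map to the containing cell; outside/nodata are flagged", {
  m <- matrix(1:12, 3, 4)  # row 1 = north
  st <- stack_from(v = m, xmin = 10, ymin = 40, cellsize = 1)
  pts <- tibble::tibble(
    lon = c(10.5, 13.5, 10.0, 9.99, 14.01),
    lat = c(42.5, 40.5, 40.0, 41.0, 41.0))
  ext <- extract_at_points(st, pts)
  expect_equal(ext$v[1], m[1, 1])   # NW cell center
  expect_equal(ext$v[2], m[3, 4])   # SE cell center
  expect_equal(ext$v[3], m[3, 1])   # lower-left corner belongs to cell (3,1)
  expect_false(ext$inside[4])
  expect_false(ext$inside[5])
  expect_true(all(is.na(ext$v[!ext$inside])))

  mna <- m; mna[2, 2] <- NA
  stna <- stack_from(v = mna, xmin = 10, ymin = 40, cellsize = 1)
  extna <- extract_at_points(stna, tibble::tibble(lon = 11.5, lat = 41.5))
  expect_true(extna$inside)
  expect_true(extna$on_nodata)

  expect_error(extract_at_points(st, tibble::tibble(lon = double(),
                                                    lat = double())),
               "empty")
})

test_that("extraction commutes with era shift", {
  sc <- scen60()
  occ <- head(sc$occurrences, 20)
  off <- sc$config$era_shifts$lgm
  before <- extract_at_points(sc$stacks$present, occ)
  after <- extract_at_points(apply_era_shift(sc$stacks$present, off), occ)
  for (nm in names(off)) {
    expect_equal(after[[nm]], before[[nm]] + off[[nm]], tolerance = 1e-12)
  }
})

test_that("per-pixel dedupe keeps first-seen record per occupied cell", {
  st <- stack_from(v = matrix(0, 10, 10), cellsize = 1)
  # 5 points in one cell collapse to 1; 3 distinct cells stay 3
  one_cell <- tibble::tibble(taxon = "t", lon = runif(5, 2.0, 2.9),
                             lat = runif(5, 3.0, 3.9), id = 1:5)
  expect_equal(nrow(dedupe_per_pixel(one_cell, st)), 1)
  expect_equal(dedupe_per_pixel(one_cell, st)$id, 1)

  three <- tibble::tibble(taxon = "t", lon = c(0.5, 1.5, 2.5),
                          lat = c(0.5, 0.5, 0.5))
  expect_equal(nrow(dedupe_per_pixel(three, st)), 3)

  # brute-force oracle: distinct occupied cells of 1,000 random points
  set.seed(42)
  pts <- tibble::tibble(taxon = "t", lon = runif(1000, 0, 10),
                        lat = runif(1000, 0, 10))
  expect_equal(nrow(dedupe_per_pixel(pts, st)),
               nrow(unique(cbind(floor(pts$lon), floor(pts$lat)))))

  # idempotence
  once <- dedupe_per_pixel(pts, st)
  expect_identical(dedupe_per_pixel(once, st), once)
})

test_that("occurrence CSV reader filters bad rows and groups taxa", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,lon,lat", "a,1,2", "b,3,4", "a,5,", "a,2,3", "b,x,1"),
             path)
  expect_warning(occ <- read_occurrences(path), "2 row")
  expect_equal(table(occ$taxon), table(c("a", "a", "b")))

  writeLines(c("taxon,lon,lat", "a,,", "b,x,y"), path)
  expect_warning(expect_error(read_occurrences(path), "no valid"))

  writeLines(c("taxon,lon", "a,1"), path)
  expect_error(read_occurrences(path), "lat")

  # exact duplicates are retained until the geometry-aware dedupe
  writeLines(c("taxon,lon,lat", "a,1,2", "a,1,2"), path)
  expect_equal(nrow(read_occurrences(path)), 2)
})
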
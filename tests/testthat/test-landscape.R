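write_asc_fixture <- function(path, body,
                              header = c("ncols 3", "nrows 3", "xllcorner 0",
                                         "yllcorner 0", "cellsize 25",
                                         "NODATA_value -9999")) {
  writeLines(c(header, body), path)
  path
}

test_that("ESRI ASCII grids read back with their geometry intact", {
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc_fixture(f, c("1 3 4", "11 17 6", "24 25 1"))
  g <- read_grid(f)
  expect_s3_class(g, "land_grid")
  expect_equal(g$n_rows * g$n_cols, 9)
  expect_equal(g$cell_size, 25)
  expect_equal(g$cells[2, 2], 17L)
  expect_equal(g$origin_x, 0)
  # write/read round trip
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f2)
  expect_equal(read_grid(f2)$cells, g$cells)
})

test_that("malformed headers are format errors and nodata cells are excluded", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "NODATA_value -9999", "1 1 1", "1 1 1", "1 1 1"), f)
  expect_error(read_grid(f), "cellsize")
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 25", "1 1 1", "1 1 1", "1 1 1"), f2)
  expect_error(read_grid(f2), "NODATA")
  f3 <- withr::local_tempfile(fileext = ".asc")
  write_asc_fixture(f3, c("1 1 1", "1 1.5 1", "1 1 1"))
  expect_error(read_grid(f3), "non-integer")
  expect_error(read_grid(f3, format = "geotiff"), "not supported")
  # a nodata cell contributes no area
  f4 <- withr::local_tempfile(fileext = ".asc")
  write_asc_fixture(f4, c("1 1 1", "1 -9999 1", "1 1 1"))
  g <- read_grid(f4)
  comp <- buffer_composition(g, 37.5, 37.5, 1000)
  expect_equal(attr(comp, "total_area_ha"), 8 * 0.0625)
})

test_that("raw land-use codes merge into the expected classes, idempotently", {
  g <- land_grid(matrix(c(6L, 17L, 1L, 25L), 2, 2), 0, 0, 25)
  m <- merge_classes(g)
  label <- function(mm, i, j) mm$classes[mm$cells[i, j]]
  expect_equal(label(m, 1, 1), "Y birch")
  expect_equal(label(m, 2, 1), "Mo spruce")
  expect_equal(label(m, 1, 2), "Clear cut")
  expect_equal(label(m, 2, 2), "Field")
  expect_identical(merge_classes(m), m)
  # nodata preserved, non-nodata cell count preserved
  g2 <- land_grid(matrix(c(6L, -9999L, 1L, 14L), 2, 2), 0, 0, 25)
  m2 <- merge_classes(g2)
  expect_equal(sum(m2$cells == -9999L), 1)
  expect_equal(sum(m2$cells != -9999L), sum(g2$cells != -9999L))
  g3 <- land_grid(matrix(c(6L, 99L, 1L, 14L), 2, 2), 0, 0, 25)
  expect_error(merge_classes(g3), "99")
})

test_that("buffer areas match the analytic circle and the single-cell case", {
  g <- uniform_grid(n = 40, cell = 25, code = 11L)
  centre <- 40 * 25 / 2
  comp <- buffer_composition(g, centre, centre, 300)
  expect_lt(abs(attr(comp, "total_area_ha") - pi * 300^2 / 1e4),
            0.02 * pi * 300^2 / 1e4)
  # radius under half a cell on a cell centre: exactly one cell
  comp1 <- buffer_composition(g, 12.5, 12.5, 10)
  expect_equal(attr(comp1, "total_area_ha"), 0.0625)
  # entirely outside the grid: all zero with a warning
  expect_warning(out <- buffer_composition(g, 1e6, 1e6, 300), "outside")
  expect_equal(attr(out, "total_area_ha"), 0)
  expect_true(all(out$area_ha == 0))
})

test_that("composition is additive over classes and monotone in radius", {
  set.seed(42)
  g <- merge_classes(land_grid(
    matrix(sample(c(1L, 4L, 11L, 25L), 60 * 60, replace = TRUE), 60, 60),
    0, 0, 25))
  p <- c(700, 800)
  for (r in c(120, 300, 500)) {
    comp <- buffer_composition(g, p[1], p[2], r)
    expect_equal(sum(comp$area_ha), attr(comp, "total_area_ha"))
    # every counted cell centre lies in the buffer, so the cell sits inside
    # the circle enlarged by half a cell diagonal
    expect_lte(attr(comp, "total_area_ha"), pi * (r + 25 / sqrt(2))^2 / 1e4)
  }
  c1 <- buffer_composition(g, p[1], p[2], 200)
  c2 <- buffer_composition(g, p[1], p[2], 400)
  expect_true(all(c2$area_ha[match(c1$class, c2$class)] >= c1$area_ha))
})

test_that("buffer composition equals the brute-force cell-centre oracle", {
  set.seed(7)
  for (k in 1:8) {
    n <- sample(10:60, 1)
    cell <- sample(c(10, 25, 50), 1)
    g <- land_grid(matrix(sample(c(1L, 4L, 11L), n * n, replace = TRUE), n, n),
                   0, 0, cell)
    x <- runif(1, 0, n * cell)
    y <- runif(1, 0, n * cell)
    r <- runif(1, cell, n * cell / 2)
    comp <- buffer_composition(g, x, y, r)
    oracle <- brute_composition(g, x, y, r)
    got <- comp$area_ha[match(names(oracle), comp$class)]
    expect_equal(got, unname(oracle), tolerance = 0)
  }
})

test_that("habitat_wide reshapes the long composition faithfully", {
  g <- merge_classes(uniform_grid(20, 25, 11L))
  boxes <- data.frame(box_id = c("a", "b"), x = c(250, 260), y = c(250, 260))
  long <- habitat_composition(g, boxes, 150)
  wide <- habitat_wide(long)
  expect_equal(nrow(wide), 2)
  expect_equal(wide$`Mo spruce`,
               long$area_ha[long$class == "Mo spruce"][match(wide$box_id,
                 long$box_id[long$class == "Mo spruce"])])
})
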
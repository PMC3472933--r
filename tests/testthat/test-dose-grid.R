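test_that("grid CSV dialect round-trips bit-exact and parses masked cells", {
  set.seed(7)
  y <- seq(0.25, 2, 0.25)
  z <- seq(-1, 1, 0.2)
  v <- matrix(rexp(length(z) * length(y)), length(z), length(y))
  v[3, 5] <- NA
  g <- dose_grid(y, z, v)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_grid(g, p1)
  g2 <- read_grid(p1)
  expect_identical(g2$values, g$values)
  expect_identical(g2$y_axis, g$y_axis)
  expect_identical(g2$z_axis, g$z_axis)
  expect_identical(g2$mask, g$mask)
  expect_identical(g2$unit, g$unit)
  # write-read-write byte identity
  write_grid(g2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # "-" and "" both load as masked; descending z is normalized
  lines <- c("# gzp6dose-grid v1 unit=Gy",
             "z_cm\\y_cm,0,1",
             "1,-,3.5", "0,2.0,", "-1,4,5")
  pf <- tempfile(fileext = ".csv")
  writeLines(lines, pf)
  gm <- read_grid(pf)
  expect_identical(gm$z_axis, c(-1, 0, 1))
  expect_identical(gm$unit, "Gy")
  expect_identical(sum(gm$mask), 2L)
  expect_true(gm$mask[3, 1] && gm$mask[2, 2])
  expect_identical(gm$values[1, ], c(4, 5))
})

test_that("malformed grid files are rejected with specific errors", {
  bad <- function(lines) {
    p <- tempfile()
    writeLines(lines, p)
    p
  }
  expect_error(read_grid(bad(c("nope", "z,0", "0,1"))), "not a gzp6dose-grid")
  expect_error(read_grid(bad(c("# gzp6dose-grid v1 unit=furlong",
                               "z_cm\\y_cm,0", "0,1"))), "unit")
  expect_error(read_grid(bad(c("# gzp6dose-grid v1 unit=Gy",
                               "z_cm\\y_cm,0,1", "0,1,2,3", "1,1,2"))),
               "ragged")
  expect_error(read_grid(bad(c("# gzp6dose-grid v1 unit=Gy",
                               "z_cm\\y_cm,0,1", "0,1,2", "2,1,2", "1,1,2"))),
               "monotone")
  expect_error(dose_grid(c(1, 1, 2), 1:2, matrix(1, 2, 3)), "increasing")
  expect_error(dose_grid(1:3, 1:2, matrix(-1, 2, 3)), "non-negative")
})

test_that("cartesian to polar conversion covers the axes and diagonals", {
  expect_equal(cart_to_polar(1, 0), data.frame(r = 1, theta = 90))
  expect_equal(cart_to_polar(0, 2), data.frame(r = 2, theta = 0))
  expect_equal(cart_to_polar(0, -2), data.frame(r = 2, theta = 180))
  expect_equal(cart_to_polar(1, 1), data.frame(r = sqrt(2), theta = 45))
  # cylindrical symmetry: negative y mirrors
  expect_equal(cart_to_polar(-1, 1), cart_to_polar(1, 1))
  expect_error(cart_to_polar(0, 0), "origin")
})

test_that("polar resampling is exact at grid nodes and convex between them", {
  f <- function(y, z) 2 + y + 0.5 * z + 0.1 * y * z
  y <- seq(0.2, 3, 0.2)
  z <- seq(-2, 2, 0.2)
  v <- outer(z, y, function(zz, yy) f(yy, zz))
  g <- dose_grid(y, z, v, unit = "Gy")

  # nodes coinciding with grid points reproduce the function exactly
  s <- grid_to_polar_samples(g, r = 1, theta = 90)  # (y, z) = (1, 0)
  expect_identical(s$dose_rate, f(1, 0))

  # a bilinear function is reproduced exactly everywhere in the box
  set.seed(11)
  ys <- runif(40, 0.25, 2.9)
  zs <- runif(40, -1.9, 1.9)
  pol <- cart_to_polar(ys, zs)
  for (k in seq_along(ys)) {
    s <- grid_to_polar_samples(g, pol$r[k], pol$theta[k])
    yy <- pol$r[k] * sin(pol$theta[k] * pi / 180)
    zz <- pol$r[k] * cos(pol$theta[k] * pi / 180)
    expect_equal(s$dose_rate, f(yy, zz), tolerance = 1e-12)
    # convex-combination property: result lies within the 4 stencil values
    j <- findInterval(yy, y)
    i <- findInterval(zz, z)
    corners <- v[i:(i + 1), j:(j + 1)]
    expect_gte(s$dose_rate, min(corners) - 1e-12)
    expect_lte(s$dose_rate, max(corners) + 1e-12)
  }

  # commutes with scalar multiplication of the grid
  g3 <- dose_grid(y, z, 3 * v, unit = "Gy")
  s1 <- grid_to_polar_samples(g, c(0.5, 1, 1.5), c(30, 90, 150))
  s3 <- grid_to_polar_samples(g3, c(0.5, 1, 1.5), c(30, 90, 150))
  expect_equal(s3$dose_rate, 3 * s1$dose_rate, tolerance = 1e-14)

  # out-of-box nodes are named in the error
  expect_error(grid_to_polar_samples(g, 10, 90), "r=10")
})

test_that("masked cells are never interpolation stencil nodes", {
  y <- seq(0, 1, 0.5)
  z <- seq(0, 1, 0.5)
  v <- matrix(1:9, 3, 3)
  v[1, 1] <- NA
  g <- dose_grid(y, z, v, unit = "Gy")
  # point inside the masked corner cell falls back to nearest unmasked node
  w <- capture_warnings(s <- grid_to_polar_samples(g, 0.2, 45))
  expect_true(any(grepl("masked", w)))
  expect_true(s$dose_rate %in% v[!is.na(v)])
})

test_that("isodose contours land on the level set of the interpolant", {
  spec <- kernel_preset("gzp6-no3")
  g <- generate_grid(spec, seq(0.25, 4, 0.05), seq(-4, 4, 0.05))
  levels <- c(0.05, 0.2, 1)
  cs <- extract_isodose_contours(g, levels)
  n_checked <- 0
  for (lv in cs) {
    for (pl in lv$polylines) {
      for (k in seq_len(nrow(pl))) {
        val <- oracle_bilinear(g, pl[k, "y"], pl[k, "z"])
        expect_lt(abs(val - lv$level), 1e-6 * lv$level)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("contour edge cases: constant grids, out-of-range levels, level validation", {
  g <- dose_grid(1:5, 1:5, matrix(3, 5, 5), unit = "Gy")
  cs <- extract_isodose_contours(g, c(1, 2, 5))
  expect_true(all(vapply(cs, function(lv) length(lv$polylines) == 0L, TRUE)))
  expect_error(extract_isodose_contours(g, c(-1, 2)), "positive")
  expect_error(extract_isodose_contours(g, c(2, 1)), "increasing")
})

test_that("contour JSON export writes one object per level", {
  g <- dose_grid(seq(0, 2, 0.1), seq(-2, 2, 0.1),
                 outer(seq(-2, 2, 0.1), seq(0, 2, 0.1),
                       function(z, y) 10 - y^2 - z^2), unit = "Gy")
  cs <- extract_isodose_contours(g, c(5, 8))
  path <- tempfile(fileext = ".json")
  write_contours(cs, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$level, c(5, 8))
  expect_equal(doc$unit, c("Gy", "Gy"))
})
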
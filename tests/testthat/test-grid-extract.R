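# Target-mask construction, TIFF/CSV/GPR I/O, pixel extraction.

test_that("a single rectangular cell clips to the image", {
  g <- GridSpec(cbind(x = 5, y = 4), pitch = 20, imageShape = c(9, 11),
                gridType = "rect")
  ms <- suppressWarnings(buildMasks(g))
  expect_equal(nrow(maskIndices(ms)[[1]]), 9 * 11)
  expect_true(isClipped(ms)[1])
})

test_that("mask assignment equals the brute-force nearest-center scan", {
  set.seed(30)
  for (rep in 1:8) {
    shape <- c(sample(20:40, 1), sample(20:40, 1))
    n <- sample(3:6, 1)
    centers <- cbind(x = runif(n, 2, shape[2] - 3),
                     y = runif(n, 2, shape[1] - 3))
    pitch <- runif(1, 5, 12)
    g <- GridSpec(centers, pitch = pitch, imageShape = shape)
    ms <- suppressWarnings(buildMasks(g))
    expect_identical(maskSetToIdx(ms, shape),
                     bruteAssign(centers, shape, pitch))
  }
})

test_that("hexagonally packed centers produce six-neighbor cells", {
  pitch <- 14
  centers <- hexCenters(5, 5, pitch, x0 = 14, y0 = 14)
  shape <- c(90, 100)
  g <- GridSpec(centers, pitch = pitch, imageShape = shape)
  ms <- buildMasks(g)
  idx <- maskSetToIdx(ms, shape)
  # center spot of the 5x5 lattice (row 3, col 3)
  mid <- 13L
  sel <- which(idx == mid, arr.ind = TRUE)
  nbr <- integer(0)
  for (i in seq_len(nrow(sel))) {
    r <- sel[i, 1]; cc <- sel[i, 2]
    nbr <- union(nbr, c(idx[r - 1, cc], idx[r + 1, cc],
                        idx[r, cc - 1], idx[r, cc + 1]))
  }
  nbr <- setdiff(nbr, c(0L, mid))
  expect_length(nbr, 6)
})

test_that("mask construction is translation-equivariant and disjoint", {
  pitch <- 10
  centers <- hexCenters(3, 3, pitch, x0 = 12, y0 = 12)
  g1 <- GridSpec(centers, pitch, c(60, 60))
  g2 <- GridSpec(centers + matrix(rep(c(3, 2), each = nrow(centers)),
                                  ncol = 2),
                 pitch, c(60, 60))
  m1 <- maskIndices(buildMasks(g1))
  m2 <- maskIndices(buildMasks(g2))
  # interior spot: same pixel set shifted by (dy, dx) = (2, 3)
  shifted <- m1[[5]]
  shifted[, 1] <- shifted[, 1] + 2L
  shifted[, 2] <- shifted[, 2] + 3L
  o1 <- shifted[order(shifted[, 1], shifted[, 2]), ]
  o2 <- m2[[5]][order(m2[[5]][, 1], m2[[5]][, 2]), ]
  expect_identical(unname(o1), unname(o2))

  # random center sets keep masks disjoint and in bounds (class validity
  # enforces both; construction must never violate it)
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    shape <- c(30, 30)
    centers <- cbind(runif(n, 1, 28), runif(n, 1, 28))
    if (anyDuplicated(round(centers, 6))) next
    ms <- suppressWarnings(buildMasks(GridSpec(centers, runif(1, 4, 9),
                                               shape)))
    expect_true(validObject(ms))
  }
})

test_that("center-pixel ownership and duplicate centers are enforced", {
  centers <- cbind(x = c(10, 20), y = c(10, 10))
  ms <- buildMasks(GridSpec(centers, 10, c(21, 31)))
  for (j in 1:2) {
    m <- maskIndices(ms)[[j]]
    expect_true(any(m[, 1] == 10 & m[, 2] == centers[j, 1]))
  }
  expect_error(GridSpec(rbind(c(5, 5), c(5, 5)), 4, c(20, 20)),
               "duplicate")
  expect_error(GridSpec(cbind(50, 5), 4, c(20, 20)), "bounds")
  expect_warning(buildMasks(GridSpec(rbind(c(5, 5), c(25, 5)), 4,
                                     c(40, 40))),
                 "pitch")
})

test_that("pixel extraction preserves values, coordinates and clamping", {
  img <- matrix(1234L, 15, 15)
  g <- GridSpec(rbind(c(4, 7), c(11, 7)), pitch = 6, imageShape = c(15, 15))
  ms <- buildMasks(g)
  pix <- extractPixels(img, ms)
  expect_length(pix, 2)
  for (p in pix) expect_true(all(pixelValues(p) == 1234))

  # a bright disk at the first center lands entirely in that spot's mask
  img2 <- matrix(1000L, 15, 15)
  for (r in 0:14) for (cc in 0:14)
    if ((r - 7)^2 + (cc - 4)^2 <= 4) img2[r + 1, cc + 1] <- 60000L
  pix2 <- extractPixels(img2, ms)
  expect_equal(sum(pixelValues(pix2[[1]]) == 60000), sum(img2 == 60000))
  expect_equal(sum(pixelValues(pix2[[2]]) == 60000), 0)

  # an S below the data acts as an artificial ceiling
  pix3 <- extractPixels(img2, ms, S = 1000)
  expect_true(all(pixelValues(pix3[[1]]) <= 1000))
  expect_equal(nSaturated(pix3[[1]]), sum(pixelValues(pix2[[1]]) >= 1000))
})

test_that("16-bit TIFF images round-trip through the reader", {
  set.seed(32)
  img <- matrix(sample.int(65536, 100, replace = TRUE) - 1L, 10, 10)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img / 65535, f, bits.per.sample = 16)
  back <- readImage(f)
  expect_identical(dim(back), c(10L, 10L))
  expect_identical(back, img)

  # multi-channel input is refused
  f2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(5, 5, 3)), f2, bits.per.sample = 16)
  expect_error(readImage(f2), "multi-channel")
  # and so is non-16-bit depth
  f3 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 5, 5), f3, bits.per.sample = 8)
  expect_error(readImage(f3), "16-bit")
})

test_that("centers files are parsed and validated", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(spot_id = c("a", "b", "c"), x = c(5, 15, 25),
                       y = c(10, 10, 10)),
            f, row.names = FALSE)
  g <- readCenters(f, imageShape = c(30, 40), pitch = 10)
  expect_equal(nrow(g@centers), 3)
  expect_equal(g@spotIds, c("a", "b", "c"))

  # a center outside the image fails validation
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(spot_id = "a", x = 100, y = 10), f2,
            row.names = FALSE)
  expect_error(readCenters(f2, imageShape = c(30, 40), pitch = 10),
               "bounds")
  # missing columns are reported
  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", col = 1, row = 2), f3, row.names = FALSE)
  expect_error(readCenters(f3, imageShape = c(30, 40), pitch = 10),
               "spot_id")

  # GenePix-style table: micron coordinates scaled by the resolution
  f4 <- tempfile(fileext = ".gpr")
  writeLines(c("ATF\t1.0", "2\t6",
               "\"Type=GenePix Results 3\"", "\"PixelSize=10\"",
               paste("Block", "Column", "Row", "X", "Y", "Dia.",
                     sep = "\t"),
               paste(1, 1, 1, 100, 200, 90, sep = "\t"),
               paste(1, 2, 1, 300, 200, 90, sep = "\t")), f4)
  gg <- readCenters(f4, imageShape = c(50, 60), pitch = 20,
                    micronsPerPixel = 10)
  expect_equal(unname(gg@centers[, "x"]), c(10, 30))
  expect_equal(unname(gg@centers[, "y"]), c(20, 20))
  expect_error(readCenters(f4, imageShape = c(50, 60), pitch = 20),
               "micronsPerPixel")
})

test_that("results tables round-trip through the TSV writer", {
  tab <- data.frame(
    spot_id = c("a", "b", "c"), K = c(1L, 2L, 3L),
    bg = c(2000, 2100, 1900), fg = c(NA, 30000, 70000),
    corrected = c(NA, 27900, 68100), n_pixels = c(400L, 410L, 390L),
    n_fg = c(0L, 80L, 60L), n_intermediate = c(0L, 0L, 30L),
    n_saturated = c(0L, 0L, 45L),
    fg_empirical_median = c(NA, 29500, 65535),
    flags = c("blank", "", ""), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeResults(f, tab, manifest = list(seed = 7, sat = 65535))
  back <- readResults(f)
  expect_equal(back, tab)
  mf <- jsonlite::read_json(paste0(f, ".manifest.json"))
  expect_equal(mf$seed, 7)
  expect_equal(mf$package, "censpot")
})
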
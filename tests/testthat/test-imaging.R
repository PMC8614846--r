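test_that("16-bit PNG round trip preserves intensities and bit depth", {
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L, seed = 2))
  f <- tempfile(fileext = ".png")
  write_radiograph_png16(ph$radiograph, f)
  r <- load_radiograph(f)
  expect_s3_class(r, "kj_radiograph")
  expect_identical(r$bit_depth, 16L)
  expect_equal(dim(r$pixels), dim(ph$radiograph$pixels))
  # reader (png package) is independent of the package's writer
  expect_lt(max(abs(r$pixels / 65535 - ph$radiograph$pixels)), 1 / 65535)
})

test_that("mask PNG round trip is lossless", {
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L,
                                  with_fibula = TRUE))
  f <- tempfile(fileext = ".png")
  write_mask_png(ph$mask, f)
  expect_identical(unclass(read_mask_png(f)), unclass(ph$mask))
})

test_that("DICOM loading recovers pixels and pixel spacing", {
  f <- tempfile(fileext = ".dcm")
  write_dicom_fixture(f, rows = 8L, cols = 10L, spacing = c(0.2, 0.2))
  r <- load_radiograph(f)
  expect_identical(r$bit_depth, 16L)
  expect_equal(dim(r$pixels), c(8L, 10L))
  expect_equal(unname(r$mm_per_pixel), c(0.2, 0.2))
  # row-major values 0..79
  expect_equal(r$pixels[1, ], as.numeric(0:9))
  expect_equal(r$pixels[2, 1], 10)
})

test_that("unreadable files raise a format error naming the path", {
  f <- tempfile(fileext = ".txt")
  writeLines("not an image", f)
  expect_error(load_radiograph(f), "unrecognized image format")
  expect_error(load_radiograph(f), basename(f))
  expect_error(load_radiograph(tempfile()), "not found")
})

test_that("percentile normalization maps the truncated range onto [0, 1]", {
  set.seed(1)
  r <- radiograph(matrix(runif(10000, 0, 1000), 100, 100))
  n <- normalize_intensity(r)
  expect_equal(min(n$pixels), 0)
  expect_equal(max(n$pixels), 1)
  expect_true(n$normalized)
})

test_that("normalization is monotone within the clip range", {
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L, seed = 4))
  raw <- radiograph(ph$radiograph$pixels * 4096)
  n <- normalize_intensity(raw)
  qs <- quantile(raw$pixels, c(0.05, 0.99), type = 1)
  un <- raw$pixels > qs[1] & raw$pixels < qs[2]
  expect_equal(cor(rank(raw$pixels[un]), rank(n$pixels[un])), 1)
})

test_that("normalization degenerate cases: constant image, empty image", {
  r <- radiograph(matrix(7, 10, 10))
  expect_true(all(normalize_intensity(r)$pixels == 0))
  expect_error(normalize_intensity(radiograph(matrix(numeric(0), 0, 0))),
               "empty image")
  expect_error(normalize_intensity(r, p_low = 99, p_high = 5), "p_low")
})

test_that("normalization is exactly idempotent", {
  set.seed(2)
  r <- radiograph(matrix(rnorm(256 * 256, 500, 120), 256, 256))
  n1 <- normalize_intensity(r)
  n2 <- normalize_intensity(n1)
  expect_lt(max(abs(n2$pixels - n1$pixels)), 1e-12)
})

test_that("resizing rescales pixel spacing and preserves mask labels", {
  ph <- make_phantom(phantom_spec(height = 256L, width = 256L,
                                  mm_per_pixel = 0.1))
  small <- resize_square(ph$radiograph, 128L)
  expect_equal(dim(small$pixels), c(128L, 128L))
  expect_equal(unname(small$mm_per_pixel), c(0.2, 0.2))
  sm <- resize_square(ph$mask, 128L)
  expect_true(all(unclass(sm) %in% c(0L, 1L, 2L)))
  expect_true(all(sort(unique(as.vector(unclass(sm)))) ==
                    sort(unique(as.vector(unclass(ph$mask))))))
})

test_that("resizing to the current size is the identity", {
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L))
  expect_identical(unclass(resize_square(ph$mask, 64L)), unclass(ph$mask))
  expect_identical(resize_square(ph$radiograph, 64L)$pixels,
                   ph$radiograph$pixels)
  expect_error(resize_square(ph$radiograph, 16L), ">= 32")
})

test_that("double horizontal flip restores the raster bit-exactly", {
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L, seed = 6))
  expect_identical(
    flip_horizontal(flip_horizontal(ph$radiograph))$pixels,
    ph$radiograph$pixels)
  expect_identical(unclass(flip_horizontal(flip_horizontal(ph$mask))),
                   unclass(ph$mask))
  expect_identical(flip_horizontal(ph$radiograph)$laterality, "left")
})

test_that("label masks reject out-of-range values", {
  expect_error(label_mask(matrix(c(0, 5), 1, 2)), "0, 1, 2, 3")
  expect_error(radiograph(matrix(1, 2, 2), mm_per_pixel = -0.1), "positive")
})
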
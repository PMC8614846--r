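test_that("sampling sites reproduce the canonical point counts and intervals", {
  for (n in c(8L, 16L, 32L, 64L)) {
    g <- sampling_grid(n)
    s <- sample_sites(g)
    expect_length(s, n)
    expect_equal(g$spacing, 0.4 / n)
    expect_true(all(s >= 0 & s <= 1))
  }
  s16 <- sample_sites(sampling_grid(16L))
  expect_equal(s16[9:16], seq(0.700, 0.875, by = 0.025), tolerance = 1e-12)
  expect_equal(sample_sites(sampling_grid(2L)), c(0.10, 0.70))
  expect_error(sampling_grid(7L), "even")
  expect_error(sampling_grid(8L, lateral_range = c(0.4, 0.8),
                             medial_range = c(0.7, 0.9)), "disjoint")
})

measured_phantom <- function(spec) {
  ph <- make_phantom(spec)
  m <- extract_margins(ph$mask)
  fr <- build_frame(m$tibia, spec$laterality, row_mm = spec$mm_per_pixel,
                    col_mm = spec$mm_per_pixel)
  list(ph = ph, m = m, fr = fr)
}

test_that("widths at sites recover a constant gap to within one pixel", {
  mp <- measured_phantom(phantom_spec(gap = 4.0, mm_per_pixel = 0.2))
  for (x in sample_sites(sampling_grid(16L)))
    expect_lt(abs(width_at(x, mp$m$femur, mp$m$tibia, mp$fr) - 4.0),
              0.2 + 1e-12)
})

test_that("64-site profiles track an analytic gap within 1.5 pixels", {
  mp <- measured_phantom(phantom_spec(gap = function(x) 2 + 8 * (x - 0.8)^2,
                                      mm_per_pixel = 0.2))
  prof <- multi_jsw(mp$m$femur, mp$m$tibia, mp$fr, sampling_grid(64L))
  expect_equal(nrow(prof), 64L)
  expect_identical(attr(prof, "n_imputed"), 0L)
  g <- mp$ph$truth$gap_fun
  expect_lt(max(abs(prof$width_mm - g(prof$x))), 1.5 * 0.2)
})

test_that("sites outside the margin overlap raise a missing-site error", {
  mp <- measured_phantom(phantom_spec(seed = 4))
  # erode the femur where x > 0.82 so the last medial site (0.85) is lost
  mk <- unclass(mp$ph$mask)
  gone <- mp$ph$truth$columns[mp$ph$truth$x_of_col > 0.82]
  mk[, gone][mk[, gone] == 1L] <- 0L
  m2 <- extract_margins(label_mask(mk))
  fr2 <- build_frame(m2$tibia, "right", 0.2, 0.2)
  expect_error(width_at(0.95, m2$femur, m2$tibia, mp$fr),
               class = "kj_missing_site")
  prof <- multi_jsw(m2$femur, m2$tibia, mp$fr, sampling_grid(8L))
  expect_gte(attr(prof, "n_imputed"), 1L)
  expect_true(any(prof$imputed))
  # imputed widths copy the nearest valid site
  last_valid <- max(which(!prof$imputed))
  expect_equal(prof$width_mm[prof$imputed],
               rep(prof$width_mm[last_valid], sum(prof$imputed)))
})

test_that("profiles with over a quarter of sites missing are rejected", {
  mp <- measured_phantom(phantom_spec(seed = 5))
  mk <- unclass(mp$ph$mask)
  gone <- mp$ph$truth$columns[mp$ph$truth$x_of_col > 0.55]
  mk[, gone][mk[, gone] == 1L] <- 0L
  m2 <- extract_margins(label_mask(mk))
  expect_error(multi_jsw(m2$femur, m2$tibia, mp$fr, sampling_grid(16L)),
               "invalid profile")
})

test_that("dyadic grids nest with exactly equal widths at shared sites", {
  mp <- measured_phantom(phantom_spec(seed = 6))
  p64 <- multi_jsw(mp$m$femur, mp$m$tibia, mp$fr, sampling_grid(64L))
  for (n in c(8L, 16L, 32L)) {
    pn <- multi_jsw(mp$m$femur, mp$m$tibia, mp$fr, sampling_grid(n))
    idx <- match(round(pn$x, 9), round(p64$x, 9))
    expect_false(anyNA(idx))
    expect_identical(pn$width_mm, p64$width_mm[idx])
  }
})

test_that("minimum JSW equals the exhaustive double-loop oracle exactly", {
  for (seed in 1:3) {
    mp <- measured_phantom(phantom_spec(
      seed = seed, gap = function(x) 2.5 + 3 * (x - 0.6 - 0.05 * seed)^2))
    got <- min_jsw(mp$m$femur, mp$m$tibia, mp$fr)
    expect_identical(got$width,
                     naive_min_jsw(mp$m$femur, mp$m$tibia, mp$fr))
  }
})

test_that("minimum JSW recovers flat and parabolic phantom gaps", {
  flat <- measured_phantom(phantom_spec(gap = 4.0, mm_per_pixel = 0.2,
                                        tibia_coef = 0.55))
  mj <- min_jsw(flat$m$femur, flat$m$tibia, flat$fr)
  expect_lt(abs(mj$width - 4.0), 0.2 + 1e-12)
  par <- measured_phantom(phantom_spec(gap = function(x) 2 + 8 * (x - 0.8)^2,
                                       mm_per_pixel = 0.2,
                                       tibia_coef = 0.55))
  mj2 <- min_jsw(par$m$femur, par$m$tibia, par$fr)
  expect_lt(abs(mj2$width - 2.0), 1.5 * 0.2)
  expect_lt(abs(mean(mj2$at) - 0.8), 0.02)
})

test_that("minimum JSW is bounded by every medial vertical width", {
  mp <- measured_phantom(phantom_spec(seed = 8))
  mj <- min_jsw(mp$m$femur, mp$m$tibia, mp$fr)
  for (x in seq(0.7, 0.9, by = 0.02)) {
    w <- tryCatch(width_at(x, mp$m$femur, mp$m$tibia, mp$fr),
                  kj_missing_site = function(e) NA_real_)
    if (!is.na(w)) expect_lte(mj$width, w + 1e-12)
  }
  expect_error(min_jsw(mp$m$femur, mp$m$tibia, mp$fr, window = c(1.5, 1.6)),
               "search window")
})

test_that("narrowing the gap uniformly lowers every width by that amount", {
  g0 <- function(x) 3.5 + 2 * (x - 0.75)^2
  d <- 0.5
  a <- measured_phantom(phantom_spec(gap = g0, seed = 9))
  b <- measured_phantom(phantom_spec(gap = function(x) g0(x) - d, seed = 9))
  pa <- multi_jsw(a$m$femur, a$m$tibia, a$fr, sampling_grid(32L))
  pb <- multi_jsw(b$m$femur, b$m$tibia, b$fr, sampling_grid(32L))
  expect_lt(max(abs((pa$width_mm - pb$width_mm) - d)), 0.2 + 1e-12)
  expect_lt(min_jsw(b$m$femur, b$m$tibia, b$fr)$width,
            min_jsw(a$m$femur, a$m$tibia, a$fr)$width)
})

test_that("mirrored masks with swapped laterality measure identically", {
  sp <- phantom_spec(seed = 10, gap = function(x) 2.2 + 4 * (x - 0.72)^2)
  ph <- make_phantom(sp)
  a <- measure_mask(ph$mask, "right", sp$mm_per_pixel, n_points = 16L)
  b <- measure_mask(flip_horizontal(ph$mask), "left", sp$mm_per_pixel,
                    n_points = 16L)
  expect_lt(max(abs(a$profile$width_mm - b$profile$width_mm)), 1e-9)
  expect_lt(abs(a$min$width - b$min$width), 1e-9)
})

test_that("calibration is an exact scale factor", {
  expect_equal(calibrate(20, 0.2), 4.0)
  expect_equal(calibrate(0, 0.7), 0.0)
  w <- 3.217; s <- 0.143
  expect_equal(calibrate(w / s, s), w)
  expect_error(calibrate(10, 0), "> 0")
})
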
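#' Multi-point JSW sampling grid
#'
#' Fixed normalized sampling sites in the lateral and medial
#' compartments. With the default equal-width compartment ranges
#' `[0.10, 0.30)` and `[0.70, 0.90)` and half-open sampling, the spacing
#' is `0.4 / n_points`, which reproduces the canonical intervals 0.05,
#' 0.025, 0.0125 and 0.00625 for 8-, 16-, 32- and 64-point grids.
#' Dyadic grids nest: every n-point site set is a subset of the 2n-point
#' set.
#'
#' @param n_points total number of sites (positive even count, split
#'   equally between compartments).
#' @param lateral_range,medial_range half-open normalized ranges
#'   `[a, b)`; must be disjoint and inside `[0, 1]`.
#' @return An object of class `kj_grid` with fields `n_points`,
#'   `lateral_range`, `medial_range`, `spacing` (per-compartment spacing;
#'   a single value when the ranges have equal width).
#' @export
sampling_grid <- function(n_points = 16L, lateral_range = c(0.10, 0.30),
                          medial_range = c(0.70, 0.90)) {
  n_points <- as.integer(n_points)
  if (n_points < 2L || n_points %% 2L != 0L)
    stop("n_points must be a positive even count")
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] >= r[2] || r[1] < 0 || r[2] > 1)
      stop(nm, " must be an increasing range inside [0, 1]")
  }
  chk(lateral_range, "lateral_range"); chk(medial_range, "medial_range")
  if (lateral_range[2] > medial_range[1])
    stop("lateral and medial ranges must be disjoint (lateral first)")
  m <- n_points / 2L
  sp <- c(lateral = diff(lateral_range) / m, medial = diff(medial_range) / m)
  spacing <- if (abs(sp[1] - sp[2]) < 1e-12) unname(sp[1]) else sp
  structure(list(n_points = n_points, lateral_range = lateral_range,
                 medial_range = medial_range, spacing = spacing),
            class = "kj_grid")
}

#' Normalized sampling sites of a grid
#'
#' Half-open sampling: per compartment the sites are
#' `a + k * spacing, k = 0 .. n/2 - 1`, concatenated lateral-then-medial.
#'
#' @param grid a [sampling_grid()].
#' @return Numeric vector of length `grid$n_points`.
#' @export
sample_sites <- function(grid) {
  stopifnot(inherits(grid, "kj_grid"))
  m <- grid$n_points / 2L
  sp <- grid$spacing
  if (length(sp) == 1L) sp <- c(sp, sp)
  c(grid$lateral_range[1] + (0:(m - 1)) * sp[1],
    grid$medial_range[1] + (0:(m - 1)) * sp[2])
}

missing_site_error <- function(x) {
  stop(structure(class = c("kj_missing_site", "error", "condition"),
                 list(message = sprintf(
                   "site x = %.5g falls outside the margin overlap", x),
                   call = sys.call(-1), x = x)))
}

#' Vertical joint-space width at a normalized site
#'
#' The width is the vertical (row-direction) distance between the femoral
#' and tibial margins at the pixel column nearest to
#' `frame_to_column(frame, x)`, scaled by the row spacing. Negative gaps
#' (crossing margins, plausible for bone-on-bone grade-4 joints) are
#' clamped to 0 with a warning.
#'
#' @param x normalized site in `[0, 1]`.
#' @param femur,tibia `kj_margin` objects from [extract_margins()].
#' @param frame a [build_frame()] result.
#' @return Width in mm.
#' @export
width_at <- function(x, femur, tibia, frame) {
  stopifnot(inherits(frame, "kj_frame"))
  c_ <- nearest_column(frame, x)
  fi <- match(c_, femur$columns)
  ti <- match(c_, tibia$columns)
  if (is.na(fi) || is.na(ti)) missing_site_error(x)
  w <- (tibia$rows[ti] - femur$rows[fi]) * frame$row_mm
  if (w < 0) {
    warning(sprintf("margins cross at x = %.3g; width clamped to 0", x))
    w <- 0
  }
  w
}

#' Multi-point JSW profile
#'
#' Measures [width_at()] at every site of the grid. Sites falling outside
#' the margin overlap are imputed with the width of the nearest valid
#' site and flagged; a profile with more than 25% missing sites is
#' rejected.
#'
#' @inheritParams width_at
#' @param grid a [sampling_grid()].
#' @return An object of class `kj_jsw_profile`: a data frame with columns
#'   `site`, `x`, `width_mm`, `imputed`, and attributes `calibration`
#'   (`c(row_mm, col_mm)`) and `n_imputed`.
#' @export
multi_jsw <- function(femur, tibia, frame, grid) {
  sites <- sample_sites(grid)
  widths <- numeric(length(sites))
  missing <- logical(length(sites))
  for (i in seq_along(sites)) {
    w <- tryCatch(width_at(sites[i], femur, tibia, frame),
                  kj_missing_site = function(e) NA_real_)
    widths[i] <- w
    missing[i] <- is.na(w)
  }
  if (sum(missing) > 0.25 * length(sites))
    stop("invalid profile: more than 25% of sites fall outside the margins")
  if (any(missing)) {
    valid <- which(!missing)
    for (i in which(missing)) {
      widths[i] <- widths[valid[which.min(abs(sites[valid] - sites[i]))]]
    }
  }
  out <- data.frame(site = seq_along(sites), x = sites, width_mm = widths,
                    imputed = missing)
  attr(out, "calibration") <- c(row_mm = frame$row_mm, col_mm = frame$col_mm)
  attr(out, "n_imputed") <- sum(missing)
  class(out) <- c("kj_jsw_profile", "data.frame")
  out
}

#' Minimum JSW by exhaustive pair search in the medial window
#'
#' Considers every pair of margin points whose normalized coordinate lies
#' in the search window (default `[0.7, 0.9]`, the medial compartment)
#' and returns the minimum Euclidean distance
#' `sqrt((drow * row_mm)^2 + (dcol * col_mm)^2)`. The search is exact
#' brute force over all pairs.
#'
#' @inheritParams width_at
#' @param window normalized search window.
#' @return An object of class `kj_min_jsw`: list with `width` (mm), `at`
#'   (`c(x_femur, x_tibia)` of the minimizing pair) and `search_window`.
#' @export
min_jsw <- function(femur, tibia, frame, window = c(0.7, 0.9)) {
  fx <- frame_to_x(frame, femur$columns)
  tx <- frame_to_x(frame, tibia$columns)
  fin <- which(fx >= window[1] & fx <= window[2])
  tin <- which(tx >= window[1] & tx <= window[2])
  if (length(fin) == 0L || length(tin) == 0L)
    stop("no margin points inside the search window [",
         window[1], ", ", window[2], "]")
  dr <- outer(femur$rows[fin], tibia$rows[tin], "-") * frame$row_mm
  dc <- outer(femur$columns[fin], tibia$columns[tin], "-") * frame$col_mm
  d2 <- dr * dr + dc * dc
  # pixel quantization flattens the minimum into a tie set; report the
  # central (median-x) minimizing pair rather than an edge-biased one
  ties <- which(d2 <= min(d2) + 1e-12)
  ki <- arrayInd(ties, dim(d2))
  xmid <- (fx[fin[ki[, 1]]] + tx[tin[ki[, 2]]]) / 2
  k <- ki[order(xmid)[(length(ties) + 1L) %/% 2L], , drop = FALSE]
  structure(list(width = sqrt(d2[k]),
                 at = c(x_femur = fx[fin[k[1]]], x_tibia = tx[tin[k[2]]]),
                 search_window = window),
            class = "kj_min_jsw")
}

#' @export
print.kj_min_jsw <- function(x, ...) {
  cat(sprintf("<kj_min_jsw> %.3f mm at x_f=%.3f, x_t=%.3f (window %g-%g)\n",
              x$width, x$at[1], x$at[2],
              x$search_window[1], x$search_window[2]))
  invisible(x)
}

#' Pixel-to-millimetre calibration
#'
#' @param width_pixels width in pixels.
#' @param mm_per_pixel calibration factor (> 0), e.g. from DICOM pixel
#'   spacing or a radiographic scale object.
#' @return Width in mm.
#' @export
calibrate <- function(width_pixels, mm_per_pixel) {
  stopifnot(mm_per_pixel > 0)
  width_pixels * mm_per_pixel
}

#' Measure a mask end-to-end
#'
#' Convenience wrapper: extracts margins, builds the plateau frame and
#' returns the multi-point profile plus the minimum JSW.
#'
#' @param mask a [label_mask()].
#' @param laterality,medial_side passed to [build_frame()].
#' @param mm_per_pixel scalar or `c(row_mm, col_mm)`.
#' @param n_points grid size.
#' @return List with `profile`, `min`, `frame`, `margins`.
#' @export
measure_mask <- function(mask, laterality = "unknown", mm_per_pixel,
                         n_points = 16L, medial_side = NULL) {
  mm <- if (length(mm_per_pixel) == 1L) rep(mm_per_pixel, 2L) else mm_per_pixel
  margins <- extract_margins(mask)
  frame <- build_frame(margins$tibia, laterality, row_mm = mm[1],
                       col_mm = mm[2], medial_side = medial_side)
  list(profile = multi_jsw(margins$femur, margins$tibia, frame,
                           sampling_grid(n_points)),
       min = min_jsw(margins$femur, margins$tibia, frame),
       frame = frame, margins = margins)
}
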
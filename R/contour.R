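#' Extract continuous articular margins from a bone mask
#'
#' For every pixel column shared by femur and tibia, the femoral articular
#' margin is the lower edge of the bottommost femur pixel and the tibial
#' margin is the upper edge of the topmost tibia pixel. Margin rows are
#' sub-pixel: pixel `(r, c)` occupies `[r - 0.5, r + 0.5]` in each axis,
#' so margins sit on pixel edges (femur row `+ 0.5`, tibia row `- 0.5`).
#' On a binary mask this boundary tracing coincides with what an edge
#' filter would return, but is deterministic and parameter-free.
#'
#' Margins are restricted to the longest contiguous run of columns in
#' which both bones are present, so the returned curves are continuous
#' (one row per column, no gaps).
#'
#' @param mask a [label_mask()] containing femur (1) and tibia (2) pixels.
#' @return A list with two `kj_margin` objects, `femur` and `tibia`, each
#'   with fields `bone`, `columns`, `rows`, `column_range`.
#' @export
extract_margins <- function(mask) {
  stopifnot(inherits(mask, "kj_mask"))
  m <- unclass(mask)
  H <- nrow(m)
  f_any <- colSums(m == 1L) > 0L
  t_any <- colSums(m == 2L) > 0L
  if (!any(f_any) || !any(t_any))
    stop("no joint overlap: mask must contain both femur and tibia pixels")
  shared <- which(f_any & t_any)
  if (length(shared) == 0L)
    stop("no joint overlap: femur and tibia share no columns")
  # longest contiguous run of shared columns
  runs <- split(shared, cumsum(c(1L, diff(shared) != 1L)))
  cols <- runs[[which.max(lengths(runs))]]

  rowidx <- seq_len(H)
  f_bottom <- vapply(cols, function(c_) max(rowidx[m[, c_] == 1L]), 0L)
  t_top <- vapply(cols, function(c_) min(rowidx[m[, c_] == 2L]), 0L)
  f_rows <- f_bottom + 0.5
  t_rows <- t_top - 0.5
  if (median(f_rows) > median(t_rows))
    stop("orientation error: femur lies below tibia (image upside-down?)")

  margin <- function(bone, rows)
    structure(list(bone = bone, columns = as.integer(cols), rows = rows,
                   column_range = range(cols)), class = "kj_margin")
  list(femur = margin("femur", f_rows), tibia = margin("tibia", t_rows))
}

#' @export
print.kj_margin <- function(x, ...) {
  cat(sprintf("<kj_margin> %s, columns %d..%d (%d points)\n", x$bone,
              x$column_range[1], x$column_range[2], length(x$columns)))
  invisible(x)
}

#' Normalized tibial-plateau coordinate frame
#'
#' Maps pixel columns affinely to the normalized coordinate
#' `x` in `[0, 1]` spanned by the tibial articular margin, with the
#' convention that the medial compartment always lies at high `x`.
#' Whether the medial side sits at high or low image columns is resolved
#' from laterality metadata: in this package's orientation convention a
#' right knee has its medial compartment at high columns and a left knee
#' at low columns (so left-knee frames are mirrored, `x -> 1 - x`).
#' When laterality is unknown an explicit `medial_side` override
#' (`"high"` or `"low"`, in image-column terms) is required, since a
#' mask alone cannot disambiguate the compartments.
#'
#' @param tibia the tibial `kj_margin` (spanning at least 10 columns).
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param row_mm,col_mm pixel spacing in mm per pixel.
#' @param medial_side optional override: `"high"` or `"low"`.
#' @return An object of class `kj_frame` with fields `c0`, `c1`,
#'   `mirror`, `row_mm`, `col_mm`.
#' @export
build_frame <- function(tibia, laterality = "unknown", row_mm, col_mm,
                        medial_side = NULL) {
  stopifnot(inherits(tibia, "kj_margin"), row_mm > 0, col_mm > 0)
  if (length(tibia$columns) < 10L)
    stop("degenerate plateau: tibial margin spans fewer than 10 columns")
  laterality <- match.arg(laterality, c("left", "right", "unknown"))
  if (is.null(medial_side)) {
    if (laterality == "unknown")
      stop("laterality unknown: supply medial_side = \"high\" or \"low\"")
    medial_side <- if (laterality == "right") "high" else "low"
  }
  medial_side <- match.arg(medial_side, c("high", "low"))
  structure(list(c0 = tibia$column_range[1], c1 = tibia$column_range[2],
                 mirror = medial_side == "low",
                 row_mm = row_mm, col_mm = col_mm),
            class = "kj_frame")
}

#' Convert between pixel columns and normalized plateau coordinate
#'
#' `frame_to_x` maps a column to `x`; `frame_to_column` is its exact
#' inverse (a fractional column). The map is affine and strictly
#' monotone; mirrored frames reverse the direction so that medial is
#' always at high `x`.
#'
#' @param frame a [build_frame()] result.
#' @param column,x values to convert (vectorized).
#' @return Numeric vector.
#' @export
frame_to_x <- function(frame, column) {
  u <- (column - frame$c0) / (frame$c1 - frame$c0)
  if (frame$mirror) 1 - u else u
}

#' @rdname frame_to_x
#' @export
frame_to_column <- function(frame, x) {
  u <- if (frame$mirror) 1 - x else x
  frame$c0 + u * (frame$c1 - frame$c0)
}

# Nearest integer column to normalized position x. Exact half-column ties
# are broken toward the medial side (higher x), which makes the choice
# equivariant under horizontal mirroring.
nearest_column <- function(frame, x) {
  c_exact <- frame_to_column(frame, x)
  lo <- floor(c_exact); hi <- ceiling(c_exact)
  frac <- c_exact - lo
  tie <- abs(frac - 0.5) < 1e-9
  out <- ifelse(frac < 0.5, lo, hi)
  if (any(tie)) {
    medial_is_hi <- frame_to_x(frame, hi) > frame_to_x(frame, lo)
    out[tie] <- if (medial_is_hi) hi[tie] else lo[tie]
  }
  as.integer(round(out))
}

#' @export
print.kj_frame <- function(x, ...) {
  cat(sprintf(
    "<kj_frame> columns %d..%d -> x in [0,1]%s; spacing %.4g x %.4g mm/px\n",
    x$c0, x$c1, if (x$mirror) " (mirrored: medial at low columns)" else "",
    x$row_mm, x$col_mm))
  invisible(x)
}
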
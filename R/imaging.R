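#' Radiograph container
#'
#' A radiograph is a 2-D intensity matrix (rows increase downward) with
#' optional physical calibration. Pixel spacing is carried per axis as
#' `c(row_mm, col_mm)` so that anisotropic resampling stays consistent:
#' vertical JSW measurements use `row_mm`, Euclidean distances use both.
#'
#' @param pixels numeric matrix of intensities. Freshly loaded images keep
#'   their native scale; [normalize_intensity()] maps them to `[0, 1]`.
#' @param bit_depth integer, bit depth of the source file.
#' @param mm_per_pixel `NULL`, a positive scalar (isotropic), or
#'   `c(row_mm, col_mm)`.
#' @param laterality one of `"left"`, `"right"`, `"bilateral"`, `"unknown"`.
#' @param source_id character tag identifying the source.
#' @param normalized logical, whether `pixels` are already in `[0, 1]`
#'   via [normalize_intensity()].
#' @return An object of class `kj_radiograph`.
#' @export
radiograph <- function(pixels, bit_depth = 16L, mm_per_pixel = NULL,
                       laterality = "unknown", source_id = "",
                       normalized = FALSE) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  laterality <- match.arg(laterality,
                          c("left", "right", "bilateral", "unknown"))
  if (!is.null(mm_per_pixel)) {
    mm_per_pixel <- as.numeric(mm_per_pixel)
    if (length(mm_per_pixel) == 1L) mm_per_pixel <- rep(mm_per_pixel, 2L)
    if (length(mm_per_pixel) != 2L || any(!is.finite(mm_per_pixel)) ||
        any(mm_per_pixel <= 0))
      stop("mm_per_pixel must be positive (row_mm, col_mm)")
    names(mm_per_pixel) <- c("row", "col")
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 mm_per_pixel = mm_per_pixel, laterality = laterality,
                 source_id = source_id, normalized = isTRUE(normalized)),
            class = "kj_radiograph")
}

#' @export
print.kj_radiograph <- function(x, ...) {
  d <- dim(x$pixels)
  sp <- if (is.null(x$mm_per_pixel)) "uncalibrated"
        else sprintf("%.4g x %.4g mm/px", x$mm_per_pixel[1], x$mm_per_pixel[2])
  cat(sprintf("<kj_radiograph> %d x %d, %d-bit, %s, laterality=%s%s\n",
              d[1], d[2], x$bit_depth, sp, x$laterality,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Bone label mask
#'
#' Integer raster with the four-class coding 0 = background, 1 = femur,
#' 2 = tibia, 3 = fibula.
#'
#' @param labels integer matrix with values in `{0, 1, 2, 3}`.
#' @return An object of class `kj_mask` (an integer matrix).
#' @export
label_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  m <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(is.na(m)) || any(!(m %in% 0:3)))
    stop("mask labels must all be in {0, 1, 2, 3}")
  structure(m, class = c("kj_mask", "matrix", "array"))
}

#' @export
print.kj_mask <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:3))
  cat(sprintf("<kj_mask> %d x %d; bg=%d femur=%d tibia=%d fibula=%d\n",
              nrow(x), ncol(x), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

mask_classes <- c(background = 0L, femur = 1L, tibia = 2L, fibula = 3L)

#' Load a radiograph from DICOM or PNG
#'
#' PNG files (8- or 16-bit greyscale) are read with the png package;
#' DICOM part-10 files (single-frame, uncompressed, little-endian) are
#' parsed directly. Pixel spacing is taken from the DICOM PixelSpacing
#' (0028,0030) or ImagerPixelSpacing (0018,1164) element when present.
#' No intensity normalization is applied at load time.
#'
#' @param path file path.
#' @param laterality optional laterality tag to attach.
#' @return A [radiograph()].
#' @export
load_radiograph <- function(path, laterality = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8L && identical(magic, png_sig))
    return(load_radiograph_png(path, laterality))
  hdr <- readBin(path, "raw", n = 132L)
  if (length(hdr) >= 132L &&
      identical(rawToChar(hdr[129:132]), "DICM"))
    return(load_radiograph_dicom(path, laterality))
  stop("unrecognized image format (expected PNG or DICOM): ", path)
}

load_radiograph_png <- function(path, laterality) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of grey+alpha
  bd <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  # readPNG scales to [0,1]; restore native integer scale (no normalization)
  pix <- img * (2^bd - 1)
  radiograph(pix, bit_depth = bd, mm_per_pixel = NULL,
             laterality = laterality, source_id = basename(path))
}

# Minimal single-frame DICOM part-10 reader: implicit/explicit VR little
# endian, uncompressed monochrome pixel data.
load_radiograph_dicom <- function(path, laterality) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L) stop("truncated DICOM file: ", path)
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))

  pos <- 133L  # first byte after "DICM"
  transfer_syntax <- "1.2.840.10008.1.2.1"
  els <- list()
  explicit <- TRUE      # file meta group is always explicit VR LE
  meta_end <- Inf
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    tag <- sprintf("%04x,%04x", group, elem)
    if (group != 0x0002L && pos < meta_end) {
      # shouldn't happen, but guard
    }
    if (group != 0x0002L && is.infinite(meta_end)) {
      meta_end <- pos
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!transfer_syntax %in%
          c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax ", transfer_syntax,
             " in ", path)
    }
    if (explicit || group == 0x0002L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr_len <- 12L
      } else {
        len <- u16(pos + 6L); hdr_len <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr_len <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM element in ", path)
    val_at <- pos + hdr_len
    if (val_at + len - 1L > length(raw))
      stop("corrupt DICOM element ", tag, " in ", path)
    val <- if (len > 0L) raw[val_at:(val_at + len - 1L)] else raw(0)
    els[[tag]] <- list(vr = vr, val = val)
    raw_str <- function(v) sub("\\s+$", "", rawToChar(v[v != as.raw(0)]))
    if (tag == "0002,0010") transfer_syntax <- raw_str(val)
    pos <- val_at + len
    if (tag == "7fe0,0010") break
  }
  get_str <- function(tag) {
    e <- els[[tag]]
    if (is.null(e)) return(NULL)
    sub("\\s+$", "", rawToChar(e$val[e$val != as.raw(0)]))
  }
  get_us <- function(tag) {
    e <- els[[tag]]
    if (is.null(e)) return(NULL)
    as.integer(e$val[1]) + 256L * as.integer(e$val[2])
  }
  nframes <- get_str("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop("multi-frame DICOM not supported: ", path)
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  if (is.null(rows) || is.null(cols) || is.null(bits) ||
      is.null(els[["7fe0,0010"]]))
    stop("DICOM file lacks image elements: ", path)
  pd <- els[["7fe0,0010"]]$val
  if (bits == 16L) {
    v <- readBin(pd, "integer", n = rows * cols, size = 2L,
                 signed = FALSE, endian = "little")
  } else if (bits == 8L) {
    v <- as.integer(pd[seq_len(rows * cols)])
  } else stop("unsupported DICOM bit depth ", bits, " in ", path)
  pix <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  spacing <- get_str("0028,0030")
  if (is.null(spacing)) spacing <- get_str("0018,1164")
  mmpp <- NULL
  if (!is.null(spacing)) {
    parts <- as.numeric(strsplit(spacing, "\\\\")[[1]])
    if (length(parts) >= 2L && all(is.finite(parts[1:2])) &&
        all(parts[1:2] > 0))
      mmpp <- c(parts[1], parts[2])  # DICOM order: row spacing, col spacing
  }
  radiograph(pix, bit_depth = bits, mm_per_pixel = mmpp,
             laterality = laterality, source_id = basename(path))
}

#' Percentile-truncated global contrast normalization
#'
#' Clips intensities to the `[p_low, p_high]` percentile range of the
#' image histogram and affinely maps the clipped range to `[0, 1]`.
#' Percentiles are order statistics (inverse-ECDF, `quantile` type 1),
#' which makes the operation exactly idempotent: re-normalizing a
#' normalized image returns it unchanged. Constant images map to all
#' zeros.
#'
#' @param r a [radiograph()].
#' @param p_low,p_high truncation percentiles, `0 < p_low < p_high < 100`.
#' @return The normalized radiograph (`normalized = TRUE`).
#' @export
normalize_intensity <- function(r, p_low = 5, p_high = 99) {
  stopifnot(inherits(r, "kj_radiograph"))
  if (!(p_low > 0 && p_high < 100 && p_low < p_high))
    stop("need 0 < p_low < p_high < 100")
  px <- r$pixels
  if (length(px) == 0L) stop("empty image")
  qs <- quantile(px, c(p_low, p_high) / 100, names = FALSE, type = 1)
  if (qs[2] <= qs[1]) {
    # flat (or near-flat) histogram: fall back to min-max
    qs <- range(px)
    if (qs[2] <= qs[1]) {
      r$pixels <- matrix(0, nrow(px), ncol(px))
      r$normalized <- TRUE
      return(r)
    }
  }
  px <- pmin(pmax(px, qs[1]), qs[2])
  r$pixels <- (px - qs[1]) / (qs[2] - qs[1])
  r$normalized <- TRUE
  r
}

#' Resize a radiograph or mask to a square raster
#'
#' Radiographs are resampled bilinearly; masks use nearest-neighbour so
#' labels stay in `{0, 1, 2, 3}`. Pixel spacing is rescaled per axis, so
#' an anisotropic resize yields distinct row/column spacings that are
#' respected downstream. Resizing to the current size is the identity.
#'
#' @param x a [radiograph()] or [label_mask()].
#' @param size output side length in pixels (`>= 32`).
#' @return The resized object.
#' @export
resize_square <- function(x, size = 1024L) {
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32")
  UseMethod("resize_square")
}

#' @export
resize_square.kj_radiograph <- function(x, size = 1024L) {
  size <- as.integer(size)
  d <- dim(x$pixels)
  if (all(d == size)) return(x)
  # EBImage stores images x-major; transpose in and out
  img <- EBImage::Image(t(x$pixels))
  out <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  x$pixels <- t(EBImage::imageData(out))
  if (!is.null(x$mm_per_pixel))
    x$mm_per_pixel <- x$mm_per_pixel * c(d[1] / size, d[2] / size)
  x
}

#' @export
resize_square.kj_mask <- function(x, size = 1024L) {
  size <- as.integer(size)
  d <- dim(x)
  if (all(d == size)) return(x)
  img <- EBImage::Image(t(unclass(x)))
  out <- EBImage::resize(img, w = size, h = size, filter = "none")
  label_mask(t(EBImage::imageData(out)))
}

#' Horizontal flip
#'
#' Reverses the column order (left-right mirror). Flipping twice restores
#' the original raster bit-exactly.
#'
#' @param x a [radiograph()], [label_mask()] or plain matrix.
#' @return The flipped object.
#' @export
flip_horizontal <- function(x) UseMethod("flip_horizontal")

#' @export
flip_horizontal.kj_radiograph <- function(x) {
  x$pixels <- x$pixels[, rev(seq_len(ncol(x$pixels))), drop = FALSE]
  if (x$laterality %in% c("left", "right"))
    x$laterality <- if (x$laterality == "left") "right" else "left"
  x
}

#' @export
flip_horizontal.kj_mask <- function(x)
  label_mask(unclass(x)[, rev(seq_len(ncol(x))), drop = FALSE])

#' @export
flip_horizontal.matrix <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

#' Read / write a label mask as 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit PNG with literal label values
#' 0-3 (not color-coded), which round-trips losslessly.
#'
#' @param mask a [label_mask()].
#' @param path file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a [label_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "kj_mask"))
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  label_mask(round(img * 255))
}

#' Write a radiograph as 16-bit greyscale PNG
#'
#' Intensities are mapped from their current range to the full 16-bit
#' scale: normalized images (in `[0, 1]`) are scaled by 65535; unscaled
#' integer images are written as-is (clamped).
#'
#' @param r a [radiograph()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_radiograph_png16 <- function(r, path) {
  stopifnot(inherits(r, "kj_radiograph"))
  px <- r$pixels
  if (r$normalized || max(px) <= 1) px <- px * 65535
  kj_write_png16(path, matrix(as.integer(round(px)), nrow(px), ncol(px)))
  invisible(path)
}
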
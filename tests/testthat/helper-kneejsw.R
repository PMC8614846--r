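# Shared fixtures and independent oracles for the test suite.

# Pin BLAS to one thread: the training tensors are small enough that
# thread fan-out only adds overhead, and single-threaded reductions keep
# training histories bit-reproducible across runs.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# Small phantom suitable for network training runs (128 x 128).
training_phantom <- function(seed) {
  sp <- phantom_spec(height = 128L, width = 128L, mm_per_pixel = 0.4,
                     tibia_coef = c(0.5 + 0.01 * (seed %% 5), 0.02, 0.05),
                     gap = function(x) 3 + 2.5 * (x - 0.55 - 0.03 * (seed %% 4))^2,
                     noise_sd = 0.03, seed = seed)
  ph <- make_phantom(sp)
  list(image = ph$radiograph$pixels, mask = unclass(ph$mask))
}

# Independent exhaustive minimum-distance oracle: plain double loop over
# margin points (no vectorized trick shared with the implementation).
naive_min_jsw <- function(femur, tibia, frame, window = c(0.7, 0.9)) {
  best <- Inf
  for (i in seq_along(femur$columns)) {
    xf <- frame_to_x(frame, femur$columns[i])
    if (xf < window[1] || xf > window[2]) next
    for (j in seq_along(tibia$columns)) {
      xt <- frame_to_x(frame, tibia$columns[j])
      if (xt < window[1] || xt > window[2]) next
      d <- sqrt(((femur$rows[i] - tibia$rows[j]) * frame$row_mm)^2 +
                  ((femur$columns[i] - tibia$columns[j]) * frame$col_mm)^2)
      if (d < best) best <- d
    }
  }
  best
}

# ICC(2,1) from a two-way ANOVA fitted with stats::aov (independent of
# the closed-form implementation).
icc21_aov <- function(a, b) {
  n <- length(a); k <- 2
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Write a 16-bit DICOM file through pydicom (independent writer/oracle).
write_dicom_fixture <- function(path, rows = 8L, cols = 10L,
                                spacing = c(0.2, 0.2)) {
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

fm = FileMetaDataset()
fm.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.7"
fm.MediaStorageSOPInstanceUID = generate_uid()
fm.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset()
ds.file_meta = fm
ds.SOPClassUID = fm.MediaStorageSOPClassUID
ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID
ds.Rows = %d
ds.Columns = %d
ds.BitsAllocated = 16
ds.BitsStored = 16
ds.HighBit = 15
ds.PixelRepresentation = 0
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.PixelSpacing = [%g, %g]
arr = np.arange(%d, dtype=np.uint16).reshape(%d, %d)
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', rows, cols, spacing[1], spacing[2], rows * cols, rows, cols, path)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path))
    stop("pydicom fixture generation failed: ",
         paste(status, collapse = "\n"))
  invisible(path)
}

# Per-column pixel gap (background rows between femur and tibia).
mask_column_gaps <- function(mask) {
  m <- unclass(mask)
  cols <- which(colSums(m == 1L) > 0 & colSums(m == 2L) > 0)
  vapply(cols, function(c_) {
    min(which(m[, c_] == 2L)) - max(which(m[, c_] == 1L)) - 1L
  }, 0L)
}
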
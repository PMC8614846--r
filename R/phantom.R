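#' Specification of a knee joint phantom
#'
#' A phantom is a synthetic radiograph/mask pair whose joint gap is known
#' analytically, used to validate contour extraction and JSW measurement
#' against ground truth. The superior tibial margin is a smooth (shallow
#' polynomial) curve; the inferior femoral margin is derived from it by
#' subtracting the requested gap profile, so the per-column pixel gap
#' equals the (pixel-quantized) gap by construction, with no
#' interpolation error. Rows increase downward, so "femur above tibia"
#' means smaller row values.
#'
#' The gap profile `g(x)` is given in millimetres over the normalized
#' plateau coordinate `x` in `[0, 1]`, with the medial compartment at
#' high `x`. The default profile has a medial minimum of 2.0 mm at
#' `x = 0.8` and widens laterally, emulating medial-dominant narrowing.
#'
#' @param height,width image size in pixels.
#' @param mm_per_pixel isotropic pixel spacing in mm (> 0).
#' @param gap gap profile: a function `g(x)` in mm over `x` in `[0, 1]`,
#'   or a single non-negative number for a constant gap.
#' @param plateau_span integer `c(c_min, c_max)` pixel columns covered by
#'   the joint; defaults to the central 70% of the image.
#' @param tibia_coef polynomial coefficients (intercept first) of the
#'   tibial margin row as a function of the normalized column
#'   `u = (c - c_min)/(c_max - c_min)`, in units of image height.
#' @param bone_thickness bone depth in pixels rendered above/below the
#'   margins.
#' @param noise_sd additive Gaussian intensity noise (image only; masks
#'   are always noise-free).
#' @param with_fibula render a small disjoint fibula region (class 3).
#' @param laterality `"right"` (medial at high columns, the phantom's
#'   native orientation) or `"left"` (mirrored).
#' @param seed integer seed; all randomness flows through it.
#' @return An object of class `kj_phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, mm_per_pixel = 0.2,
                         gap = function(x) 4.5 - 2.5 * exp(-((x - 0.8) / 0.15)^2),
                         plateau_span = NULL,
                         tibia_coef = c(0.55, 0.02, 0.06),
                         bone_thickness = NULL, noise_sd = 0.02,
                         with_fibula = FALSE, laterality = "right",
                         seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 32L, width >= 32L, mm_per_pixel > 0, noise_sd >= 0)
  laterality <- match.arg(laterality, c("right", "left"))
  if (is.null(plateau_span))
    plateau_span <- c(round(0.15 * width), round(0.85 * width))
  plateau_span <- as.integer(plateau_span)
  if (plateau_span[1] >= plateau_span[2])
    stop("plateau_span must satisfy c_min < c_max")
  if (plateau_span[1] < 1L || plateau_span[2] > width)
    stop("plateau_span outside image")
  if (is.numeric(gap)) {
    g0 <- gap[1]
    if (g0 < 0) stop("constant gap must be >= 0")
    gap <- function(x) rep(g0, length(x))
  }
  if (is.null(bone_thickness)) bone_thickness <- max(4L, round(0.18 * height))
  structure(list(height = height, width = width, mm_per_pixel = mm_per_pixel,
                 gap = gap, plateau_span = plateau_span,
                 tibia_coef = tibia_coef,
                 bone_thickness = as.integer(bone_thickness),
                 noise_sd = noise_sd, with_fibula = isTRUE(with_fibula),
                 laterality = laterality, seed = as.integer(seed)),
            class = "kj_phantom_spec")
}

#' Render a phantom radiograph, mask and ground truth
#'
#' Bones are rendered bright on a dark background with seeded additive
#' Gaussian noise; the mask is noise-free. The returned truth records the
#' exact (half-integer, pixel-edge) margin curves, the achieved
#' pixel-quantized gap and the analytic medial minimum, all in the final
#' image orientation.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `radiograph` ([radiograph()]), `mask`
#'   ([label_mask()]) and `truth` (class `kj_phantom_truth`) with fields
#'   `columns`, `x_of_col`, `margin_femur`, `margin_tibia` (rows, in
#'   pixel-edge units), `gap_mm` (achieved), `gap_fun` (analytic),
#'   `min_gap_medial` (mm, analytic minimum over the medial window
#'   `x` in `[0.7, 0.9]`) and `mm_per_pixel`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "kj_phantom_spec"))
  H <- spec$height; W <- spec$width; mmpp <- spec$mm_per_pixel
  cs <- spec$plateau_span[1]:spec$plateau_span[2]
  u <- (cs - cs[1]) / (cs[length(cs)] - cs[1])
  # native orientation: medial at high columns, x == u
  x <- u
  y_t <- H * vapply(u, function(ui)
    sum(spec$tibia_coef * ui^(seq_along(spec$tibia_coef) - 1)), 0.0)
  g <- spec$gap(x)
  if (any(!is.finite(g))) stop("gap profile must be finite on [0, 1]")
  gap_px <- round(g / mmpp)
  if (any(gap_px < 0))
    stop("invalid phantom spec: margins intersect within plateau_span")
  T_row <- round(y_t + 0.5)          # topmost tibia pixel row
  F_row <- T_row - 1L - gap_px       # bottommost femur pixel row
  if (any(F_row < 1L) || any(T_row + 1L > H))
    stop("phantom curves leave the image; adjust tibia_coef or size")

  mask <- matrix(0L, H, W)
  img <- matrix(0.12, H, W)
  thick <- spec$bone_thickness
  for (i in seq_along(cs)) {
    c_ <- cs[i]
    fr <- max(1L, F_row[i] - thick + 1L):F_row[i]
    tr <- T_row[i]:min(H, T_row[i] + thick - 1L)
    mask[fr, c_] <- 1L
    mask[tr, c_] <- 2L
    img[fr, c_] <- 0.78
    img[tr, c_] <- 0.74
  }
  if (spec$with_fibula) {
    # small disjoint lateral region below the tibia
    fc <- round(0.2 * W) + seq_len(max(3L, round(0.05 * W)))
    frows <- min(H, max(T_row) + thick + 2L):min(H, max(T_row) + thick +
                                                   2L + max(3L, round(0.04 * H)))
    fc <- fc[fc >= 1 & fc <= W]
    if (length(frows) && length(fc)) {
      mask[frows, fc] <- 3L
      img[frows, fc] <- 0.70
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)

  margin_f <- F_row + 0.5
  margin_t <- T_row - 0.5
  columns <- cs
  if (spec$laterality == "left") {
    img <- img[, rev(seq_len(W)), drop = FALSE]
    mask <- mask[, rev(seq_len(W)), drop = FALSE]
    columns <- W + 1L - cs
    ord <- order(columns)
    columns <- columns[ord]
    margin_f <- margin_f[ord]; margin_t <- margin_t[ord]
    x <- x[ord]; g <- g[ord]; gap_px <- gap_px[ord]
  }
  medial <- x >= 0.7 & x <= 0.9
  truth <- structure(list(
    columns = columns, x_of_col = x,
    margin_femur = margin_f, margin_tibia = margin_t,
    gap_mm = gap_px * mmpp, gap_fun = spec$gap,
    min_gap_medial = if (any(medial)) min(spec$gap(x[medial])) else NA_real_,
    mm_per_pixel = mmpp), class = "kj_phantom_truth")
  list(radiograph = radiograph(img, bit_depth = 16L, mm_per_pixel = mmpp,
                               laterality = spec$laterality,
                               source_id = "phantom", normalized = TRUE),
       mask = label_mask(mask), truth = truth)
}

#' Synthetic paired observer measurements
#'
#' Generates `n` measurement pairs `(a_i, b_i)` with
#' `b_i = a_i + bias + e_i`, `e ~ N(0, sd^2)`, as a fixture for agreement
#' statistics. Base measurements `a` emulate minimum-JSW values
#' (mean 3.5 mm, SD 1.3 mm, floored at 0).
#'
#' @param n number of pairs (`>= 3`).
#' @param bias systematic offset of observer b relative to a, in mm.
#' @param sd SD of the pair difference noise, in mm (`>= 0`).
#' @param seed integer seed.
#' @return A data frame with columns `a` and `b`.
#' @export
make_observer_pairs <- function(n, bias = 0, sd = 0.5, seed = 1L) {
  if (n < 3L) stop("need n >= 3 pairs; agreement statistics are undefined")
  stopifnot(sd >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  a <- pmax(0, rnorm(n, 3.5, 1.3))
  b <- a + bias + rnorm(n, 0, sd)
  data.frame(a = a, b = b)
}

#' Synthetic knee cohort with JSW features and KL grades
#'
#' Emulates the monotone relationship between joint-space narrowing and
#' Kellgren-Lawrence (KL) grade. Each knee carries a 64-point JSW profile
#' (32 lateral sites on `[0.10, 0.30)`, 32 medial sites on
#' `[0.70, 0.90)`), a derived minimum-JSW, a baseline KL grade, a
#' 48-month KL grade (missing for dropouts) and a subject id (two knees
#' per subject, sharing a subject-level width offset).
#'
#' A latent severity `u ~ U(0, 1)` drives narrowing of the chosen
#' compartment (3 mm at full severity, Gaussian-shaped along `x`). With
#' probability `signal_strength` the KL grade is the deterministic grade
#' implied by `u` (cut at the marginal KL distribution of a typical
#' baseline cohort: 38.6/18.1/26.4/13.7/3.2%); otherwise it is drawn
#' independently from that marginal, so `signal_strength = 1` ties KL to
#' the features and `0` makes them independent.
#'
#' @param n_knees number of knees (`>= 50`).
#' @param signal_strength in `[0, 1]`.
#' @param seed integer seed.
#' @param compartment which compartment narrows with severity:
#'   `"medial"` (default; medial-dominant disease), `"lateral"`, or
#'   `"whole"`.
#' @param dropout_rate probability that the 48-month grade is missing.
#' @return A data frame with columns `knee_id`, `subject_id`,
#'   `w_1 ... w_64` (mm), `min_jsw` (mm), `kl_baseline`, `kl_48mo`
#'   (`NA` = dropout) and `source`; the site coordinates are attached as
#'   attribute `sites`.
#' @export
make_cohort <- function(n_knees, signal_strength = 1, seed = 1L,
                        compartment = c("medial", "lateral", "whole"),
                        dropout_rate = 0.1) {
  if (n_knees < 50L) stop("need n_knees >= 50")
  stopifnot(signal_strength >= 0, signal_strength <= 1)
  compartment <- match.arg(compartment)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sites <- sample_sites(sampling_grid(64L))
  kl_marginal <- c(0.386, 0.181, 0.264, 0.137, 0.032)
  cuts <- cumsum(kl_marginal)[1:4]
  n_sub <- ceiling(n_knees / 2)
  subj_off <- rnorm(n_sub, 0, 0.3)

  narrow_w <- switch(compartment,
    medial  = exp(-((sites - 0.80) / 0.10)^2),
    lateral = exp(-((sites - 0.20) / 0.10)^2),
    whole   = rep(1, length(sites)))
  base <- 5.5 - 1.5 * sites  # wider laterally, in mm

  u <- runif(n_knees)
  grade_of_u <- findInterval(u, cuts)  # deterministic grade from severity
  use_det <- runif(n_knees) < signal_strength
  kl <- ifelse(use_det, grade_of_u,
               sample(0:4, n_knees, replace = TRUE, prob = kl_marginal))

  subject_id <- rep(seq_len(n_sub), each = 2L)[seq_len(n_knees)]
  w <- matrix(0, n_knees, length(sites))
  for (i in seq_len(n_knees)) {
    w[i, ] <- pmax(0, base + subj_off[subject_id[i]] -
                        3 * u[i] * narrow_w + rnorm(length(sites), 0, 0.15))
  }
  colnames(w) <- paste0("w_", seq_along(sites))
  medial_idx <- which(sites >= 0.7)
  min_jsw <- apply(w[, medial_idx, drop = FALSE], 1, min)

  # 48-month follow-up: progression risk increases with latent severity
  p_prog <- signal_strength * plogis(-1.5 + 3 * u) +
    (1 - signal_strength) * 0.3
  kl48 <- integer(n_knees)
  for (i in seq_len(n_knees)) {
    if (kl[i] <= 1L) {
      kl48[i] <- if (runif(1) < p_prog[i]) sample(2:4, 1) else kl[i]
    } else {
      kl48[i] <- min(4L, kl[i] + rbinom(1, 1, 0.2))
    }
  }
  kl48[runif(n_knees) < dropout_rate] <- NA_integer_

  out <- data.frame(knee_id = sprintf("K%04d", seq_len(n_knees)),
                    subject_id = sprintf("S%04d", subject_id),
                    w, min_jsw = min_jsw,
                    kl_baseline = as.integer(kl),
                    kl_48mo = kl48, source = "synthetic",
                    stringsAsFactors = FALSE)
  attr(out, "sites") <- sites
  out
}
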
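#' Synthetic-cell specification
#'
#' Describes a synthetic fluorescence image triplet with known geometry:
#' stress fibers as straight segments with Gaussian cross-profile (FWHM equal
#' to the nominal width, emulating diffraction-limited imaging), an optional
#' circular actin belt, a uniform dendritic-background level inside an
#' elliptical cell support, disk-shaped focal-adhesion sites, and an
#' elliptical nucleus. Gaussian intensity noise (clipped to `[0, 1]`) is
#' applied inside the cell support.
#'
#' All coordinates are in micrometers relative to the canvas center.
#'
#' @param canvas_px `c(height, width)` in pixels.
#' @param pixel_pitch um/pixel (default 0.29).
#' @param fibers data frame with columns `x0, y0, x1, y1, width, peak`
#'   (peak intensity in `]0, 1]`).
#' @param belt `NULL` or a list `(cx, cy, radius, width, intensity)`.
#' @param background_intensity dendritic background level in `[0, 1)`.
#' @param nucleus list `(cx, cy, rx, ry)` — ellipse semi-axes in um.
#' @param fa_sites data frame with columns `x, y, area` (um^2).
#' @param support `NULL` (ellipse inscribed in the canvas with a 1-pixel
#'   margin) or a list `(cx, cy, rx, ry)`.
#' @param noise_sd intensity noise standard deviation.
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(canvas_px, pixel_pitch = 0.29, fibers,
                           belt = NULL, background_intensity = 0.08,
                           nucleus = list(cx = 0, cy = 0, rx = 6, ry = 4),
                           fa_sites, support = NULL, noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(length(canvas_px) == 2L, all(canvas_px >= 4L), pixel_pitch > 0,
            all(fibers$width > 0), all(fibers$peak > 0 & fibers$peak <= 1),
            all(fa_sites$area > 0),
            background_intensity >= 0, background_intensity < 1, noise_sd >= 0)
  structure(list(canvas_px = as.integer(canvas_px), pixel_pitch = pixel_pitch,
                 fibers = fibers, belt = belt,
                 background_intensity = background_intensity,
                 nucleus = nucleus, fa_sites = fa_sites, support = support,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cell image triplet with ground truth
#'
#' Renders the actin channel (max-composited fibers, belt and background, so
#' overlaps never exceed gray value 1), the binary FA-marker mask (disks of
#' the requested areas; overlapping disks are merged with a warning and their
#' areas recomputed from the merged mask), and the binary nucleus mask.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_cell`: `images` (a [cell_image_set()]
#'   whose cell mask is the true support), `truth` — a list with `fibers`
#'   (width, peak, analytic mean cross gray value `c_mean`, and midline probe
#'   endpoints in absolute um) and `adhesions` (center, requested area, and
#'   the 5.5 nN/um^2 force) — and the raw `actin` channel.
#' @export
generate_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$canvas_px[1]; w <- spec$canvas_px[2]; p <- spec$pixel_pitch
  cx0 <- w * p / 2; cy0 <- h * p / 2  # canvas center in absolute um
  xs <- (seq_len(w) - 0.5) * p - cx0  # pixel centers, center-relative
  ys <- (seq_len(h) - 0.5) * p - cy0
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)

  sup <- spec$support
  if (is.null(sup))
    sup <- list(cx = 0, cy = 0, rx = cx0 - p, ry = cy0 - p)
  support <- ((X - sup$cx) / sup$rx)^2 + ((Y - sup$cy) / sup$ry)^2 <= 1

  actin <- matrix(0, h, w)
  actin[support] <- spec$background_intensity
  for (i in seq_len(nrow(spec$fibers))) {
    f <- spec$fibers[i, ]
    sigma <- f$width / 2.355
    d <- dist_to_segment(X, Y, f$x0, f$y0, f$x1, f$y1)
    actin <- pmax(actin, f$peak * exp(-d^2 / (2 * sigma^2)) * support)
  }
  if (!is.null(spec$belt)) {
    b <- spec$belt
    sigma <- b$width / 2.355
    r <- sqrt((X - b$cx)^2 + (Y - b$cy)^2)
    actin <- pmax(actin, b$intensity * exp(-(r - b$radius)^2 / (2 * sigma^2)) * support)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    actin[support] <- actin[support] + noise[support]
    actin <- pmin(pmax(actin, 0), 1)
  }
  actin[!support] <- 0

  vinc <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(spec$fa_sites))) {
    s <- spec$fa_sites[i, ]
    r <- sqrt(s$area / pi)
    vinc <- vinc | ((X - s$x)^2 + (Y - s$y)^2 <= r^2)
  }
  ncomp <- max(label_mask(vinc, 8L))
  fa_truth <- data.frame(x = spec$fa_sites$x + cx0, y = spec$fa_sites$y + cy0,
                         area_um2 = spec$fa_sites$area,
                         force_nN = 5.5 * spec$fa_sites$area)
  if (ncomp < nrow(spec$fa_sites)) {
    warning(sprintf("%d FA disks merged into %d components; areas recomputed from the mask",
                    nrow(spec$fa_sites), ncomp))
    det <- detect_adhesions(vinc, p)
    fa_truth <- data.frame(x = det$centroid_x_um, y = det$centroid_y_um,
                           area_um2 = det$area_um2,
                           force_nN = 5.5 * det$area_um2)
  }

  nuc <- ((X - spec$nucleus$cx) / spec$nucleus$rx)^2 +
         ((Y - spec$nucleus$cy) / spec$nucleus$ry)^2 <= 1

  fib <- spec$fibers
  fib$c_mean <- mapply(gaussian_cross_mean, fib$peak, fib$width,
                       MoreArgs = list(background = spec$background_intensity))
  # probe cross-section at fraction probe_t along the fiber (0.5 = midline;
  # crossing fibers place it off-center to keep the section clean)
  pt <- if (is.null(fib$probe_t)) rep(0.5, nrow(fib)) else fib$probe_t
  mx <- fib$x0 + pt * (fib$x1 - fib$x0); my <- fib$y0 + pt * (fib$y1 - fib$y0)
  L <- sqrt((fib$x1 - fib$x0)^2 + (fib$y1 - fib$y0)^2)
  ux <- -(fib$y1 - fib$y0) / L; uy <- (fib$x1 - fib$x0) / L  # unit normal
  fib$px0 <- mx - ux * fib$width / 2 + cx0
  fib$py0 <- my - uy * fib$width / 2 + cy0
  fib$px1 <- mx + ux * fib$width / 2 + cx0
  fib$py1 <- my + uy * fib$width / 2 + cy0

  images <- cell_image_set(channel_image(actin, p), vinc, nuc,
                           cell_mask = support)
  structure(list(images = images,
                 truth = list(fibers = fib, adhesions = fa_truth),
                 actin = images$actin, spec = spec),
            class = "synthetic_cell")
}

#' Analytic mean gray value across a Gaussian-profile fiber
#'
#' Mean of `max(background, peak * exp(-t^2 / (2 sigma^2)))` for `t` spanning
#' the fiber width (`sigma = width / 2.355`, so the FWHM equals the width):
#' the ground-truth `c_mean` a midline probe should recover.
#'
#' @param peak fiber peak intensity.
#' @param width fiber width (um); also the probe length.
#' @param background composited background level.
#' @return The analytic mean gray value.
#' @export
gaussian_cross_mean <- function(peak, width, background = 0) {
  sigma <- width / 2.355
  half <- width / 2
  tstar <- if (background > 0 && background < peak)
    min(half, sigma * sqrt(2 * log(peak / background))) else half
  gauss <- peak * sigma * sqrt(2 * pi) * (2 * stats::pnorm(tstar / sigma) - 1)
  (gauss + background * 2 * (half - tstar)) / width
}

#' Reference synthetic cell
#'
#' A fixed specification used throughout the test-suite: a 62 x 35 um canvas
#' at 0.29 um pitch holding an elliptical cell with five straight stress
#' fibers (widths 0.85-1.75 um), a circumferential actin belt, eight FA disks
#' of 1.5-3 um^2 at the fiber termini, and a 12 x 8 um nucleus. After 2x2
#' binning the node count stays below the 10000-node cap.
#'
#' @param noise_sd,seed overrides for the noise level and RNG seed.
#' @return A [synthetic_spec()].
#' @export
reference_cell <- function(noise_sd = 0.02, seed = 1L) {
  # stress fibers criss-cross the spread area and terminate in FA disks near
  # the cell boundary (as in well-spread adherent cells), so the pre-stressed
  # network hangs on its periphery and node displacements stay slight
  fibers <- data.frame(
    x0 = c(-22.5, -22.5, -28.5, -22.5, -22.5),
    y0 = c(-10.0, 10.0, -3.5, 10.0, -10.0),
    x1 = c(22.5, 22.5, 28.5, 22.5, 22.5),
    y1 = c(-10.0, 10.0, -0.5, -10.0, 10.0),
    width = c(1.75, 1.58, 1.20, 0.89, 0.85),
    peak = c(1.00, 0.95, 0.90, 0.85, 0.80),
    probe_t = c(0.5, 0.5, 0.5, 0.28, 0.72))
  fa_sites <- data.frame(
    x = c(-22.5, 22.5, -22.5, 22.5, -28.5, 28.5, 0.0, 0.0),
    y = c(-10.0, -10.0, 10.0, 10.0, -3.5, -0.5, 13.0, -13.0),
    area = c(1.5, 1.5, 1.5, 1.5, 1.2, 1.2, 1.2, 1.2))
  synthetic_spec(canvas_px = c(120L, 214L), pixel_pitch = 0.29,
                 fibers = fibers,
                 belt = list(cx = 0, cy = 0, radius = 7, width = 0.9,
                             intensity = 0.65),
                 background_intensity = 0.08,
                 nucleus = list(cx = 0, cy = 0, rx = 6, ry = 4),
                 fa_sites = fa_sites,
                 support = list(cx = 0, cy = 0, rx = 30, ry = 16.5),
                 noise_sd = noise_sd, seed = seed)
}

#' Write a synthetic cell as TIFF files plus a ground-truth CSV
#'
#' @param cell a `synthetic_cell` from [generate_cell()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written: actin/vinculin/nucleus TIFFs and the
#'   fiber and adhesion ground-truth CSVs.
#' @export
write_cell_images <- function(cell, dir) {
  stopifnot(inherits(cell, "synthetic_cell"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("actin.tif", "vinculin.tif", "nucleus.tif",
                            "truth_fibers.csv", "truth_adhesions.csv"))
  tiff::writeTIFF(cell$images$actin$intensities, paths[1], bits.per.sample = 16L)
  write_mask(cell$images$vinculin_mask, paths[2])
  write_mask(cell$images$nucleus_mask, paths[3])
  utils::write.csv(cell$truth$fibers, paths[4], row.names = FALSE)
  utils::write.csv(cell$truth$adhesions, paths[5], row.names = FALSE)
  invisible(paths)
}

# Distance from grid points to a segment (endpoints included).
dist_to_segment <- function(X, Y, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((X - x0) * vx + (Y - y0) * vy) / L2, 0), 1)
  sqrt((X - (x0 + t * vx))^2 + (Y - (y0 + t * vy))^2)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
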
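#' Channel image
#'
#' A single fluorescence channel held as a matrix of normalized gray values in
#' `[0, 1]` together with its pixel pitch. The coordinate convention used
#' throughout the package is: pixel `(row, col)` with origin at the top-left
#' corner, row increasing downward; the physical position of a pixel center is
#' `x = (col - 0.5) * pixel_pitch`, `y = (row - 0.5) * pixel_pitch` (micrometers).
#'
#' @param intensities numeric matrix with values in `[0, 1]`.
#' @param pixel_pitch pixel size in micrometers (> 0).
#' @return An object of class `channel_image`: a list with elements
#'   `intensities`, `pixel_pitch`.
#' @export
channel_image <- function(intensities, pixel_pitch) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (length(intensities) == 0L) stop("image is empty")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("'pixel_pitch' must be a single positive number (micrometers/pixel)")
  rng <- range(intensities)
  if (is.na(rng[1])) stop("image contains missing values")
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]")
  structure(list(intensities = intensities, pixel_pitch = pixel_pitch),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<channel_image> %d x %d px (%.2f x %.2f um), pitch %.3g um/px, range [%.3g, %.3g]\n",
              d[1], d[2], d[1] * x$pixel_pitch, d[2] * x$pixel_pitch,
              x$pixel_pitch, min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Load a grayscale TIFF channel
#'
#' Reads an 8- or 16-bit TIFF and scales intensities to `[0, 1]` by the
#' bit-depth maximum. RGB images require an explicit channel selector (the
#' usual acquisition puts actin / FA marker / DNA stain on separate color
#' channels of one microscope frame).
#'
#' @param path path to a TIFF file.
#' @param pixel_pitch pixel size in micrometers.
#' @param channel for multi-channel images, one of `"R"`, `"G"`, `"B"` or a
#'   channel index; `NULL` (default) accepts only single-channel input.
#' @return A [channel_image].
#' @export
load_channel <- function(path, pixel_pitch, channel = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read TIFF: file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("cannot read TIFF '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("multi-channel TIFF: select a channel (\"R\", \"G\", \"B\" or an index)")
    idx <- if (is.character(channel)) match(toupper(channel), c("R", "G", "B"))
           else as.integer(channel)
    if (is.na(idx) || idx < 1L || idx > dim(img)[3])
      stop("invalid channel selector")
    img <- img[, , idx]
  }
  channel_image(img, pixel_pitch)
}

#' Normalize an actin channel
#'
#' Subtracts a background level (a low percentile of the in-frame intensities),
#' clips negatives to zero, and rescales so the brightest pixel equals 1.
#' After normalization a gray value of 0 means "no actin" and 1 the highest
#' actin density in the frame.
#'
#' @param image a [channel_image].
#' @param background_percentile fraction in `[0, 1)`; default `0.01` (the 1st
#'   percentile), robust to hot pixels.
#' @return A normalized [channel_image].
#' @export
normalize_actin <- function(image, background_percentile = 0.01) {
  stopifnot(inherits(image, "channel_image"))
  v <- image$intensities
  if (max(v) == min(v))
    stop("constant image: normalization undefined")
  bg <- stats::quantile(v, background_percentile, names = FALSE)
  v <- pmax(v - bg, 0)
  channel_image(v / max(v), image$pixel_pitch)
}

#' Binarize a channel
#'
#' Thresholds an image into a logical mask (`intensity > threshold`). The
#' threshold is either chosen by Otsu's criterion or supplied.
#'
#' @param image a [channel_image].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold in `[0, 1]`, required for
#'   `method = "fixed"`.
#' @return A logical matrix of the same dimensions.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(image, "channel_image"))
  method <- match.arg(method)
  v <- image$intensities
  if (method == "otsu") {
    if (max(v) == min(v))
      stop("constant image: Otsu threshold undefined")
    thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  } else {
    if (is.null(threshold)) stop("'threshold' required for method = \"fixed\"")
    thr <- threshold
  }
  v > thr
}

#' Cell footprint from the normalized actin channel
#'
#' The footprint is the set of pixels with any actin signal (`c > 0` after
#' normalization), morphologically closed with a disk of one node-spacing
#' radius, hole-filled, and reduced to its largest connected component.
#'
#' @param actin a normalized [channel_image].
#' @param node_spacing closing radius in micrometers; defaults to
#'   `2 * pixel_pitch` (the model's node spacing after 2x2 binning).
#' @return A logical matrix.
#' @export
cell_footprint <- function(actin, node_spacing = 2 * actin$pixel_pitch) {
  stopifnot(inherits(actin, "channel_image"))
  m <- actin$intensities > 0
  if (!any(m)) stop("empty footprint: no positive actin signal")
  r <- max(1L, round(node_spacing / actin$pixel_pitch))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(m * 1), brush)
  filled <- EBImage::fillHull(closed)
  lab <- label_mask(EBImage::imageData(filled) > 0.5, connectivity = 8L)
  if (max(lab) == 0L) stop("empty footprint")
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Assemble a registered image set
#'
#' Bundles the normalized actin channel with the binary focal-adhesion
#' (vinculin), nucleus, and cell-footprint masks. Channels are assumed
#' pre-registered (one microscope frame); no alignment is performed. The
#' nucleus mask is intersected with the footprint so that nucleus pixels are
#' always part of the cell.
#'
#' @param actin a [channel_image] (normalized).
#' @param vinculin_mask,nucleus_mask,cell_mask logical matrices matching the
#'   actin dimensions; `cell_mask = NULL` derives the footprint with
#'   [cell_footprint()].
#' @return An object of class `cell_image_set`.
#' @export
cell_image_set <- function(actin, vinculin_mask, nucleus_mask, cell_mask = NULL) {
  stopifnot(inherits(actin, "channel_image"))
  d <- dim(actin$intensities)
  if (is.null(cell_mask)) cell_mask <- cell_footprint(actin)
  for (m in list(vinculin_mask, nucleus_mask, cell_mask)) {
    if (!is.logical(m) || !identical(dim(m), d))
      stop("all masks must be logical matrices with the actin dimensions")
  }
  structure(list(actin = actin,
                 vinculin_mask = vinculin_mask,
                 nucleus_mask = nucleus_mask & cell_mask,
                 cell_mask = cell_mask,
                 pixel_pitch = actin$pixel_pitch),
            class = "cell_image_set")
}

#' @export
print.cell_image_set <- function(x, ...) {
  d <- dim(x$actin$intensities)
  cat(sprintf("<cell_image_set> %d x %d px, pitch %.3g um/px\n", d[1], d[2], x$pixel_pitch))
  cat(sprintf("  footprint %d px (%.1f um^2), FA marker %d px, nucleus %d px\n",
              sum(x$cell_mask), sum(x$cell_mask) * x$pixel_pitch^2,
              sum(x$vinculin_mask), sum(x$nucleus_mask)))
  invisible(x)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

# Connected-component labelling of a logical mask with 4- or 8-connectivity,
# done on the pixel adjacency graph.
label_mask <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 <= w
    j <- (c2[ok] - 1L) * h + r2[ok]
    keep <- mask[j]
    from <- c(from, idx[ok][keep]); to <- c(to, j[keep])
  }
  kf <- match(from, idx); kt <- match(to, idx)
  g <- igraph::make_graph(as.vector(rbind(kf, kt)),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
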
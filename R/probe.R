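#' Sample a gray-value profile along a segment
#'
#' Bilinearly interpolates the image at uniform arc-length samples along the
#' segment from `p0` to `p1` (both endpoints included). Probes are drawn
#' across a stress fiber: the segment length is the fiber width and the
#' profile the fiber's cross-section.
#'
#' @param image a [channel_image] (normally the normalized actin channel:
#'   probes use the full 256-level image, not the 10-label quantization).
#' @param p0,p1 numeric length-2 endpoints `(x, y)` in micrometers.
#' @param spacing sample spacing in micrometers; default `pixel_pitch / 2`.
#' @return Numeric vector of interpolated gray values.
#' @export
sample_profile <- function(image, p0, p1, spacing = image$pixel_pitch / 2) {
  stopifnot(inherits(image, "channel_image"),
            length(p0) == 2L, length(p1) == 2L, spacing > 0)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length segment")
  p <- image$pixel_pitch
  h <- nrow(image$intensities); w <- ncol(image$intensities)
  xc <- (seq_len(w) - 0.5) * p  # pixel-center coordinates
  yc <- (seq_len(h) - 0.5) * p
  n <- max(2L, ceiling(len / spacing) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  if (any(xs < xc[1] | xs > xc[w] | ys < yc[1] | ys > yc[h]))
    stop("probe endpoints outside the image interior")
  pracma::interp2(xc, yc, image$intensities, xs, ys)
}

#' Tension crossing a probe segment
#'
#' The cross-linear tension relation converts an image profile directly into
#' force: `T = T_cl_max * mean(profile) * width`, where `T_cl_max` (nN/um) is
#' the cross-linear tension at maximal actin density and `width` the segment
#' length (the fiber width). Widths below the model definition of 0.6 um are
#' computed but flagged: diffraction and resolution average gray values there
#' and the estimate may be low.
#'
#' @param profile gray-value profile from [sample_profile()].
#' @param width segment length in micrometers.
#' @param T_cl_max cross-linear tension scale in nN/um.
#' @return Tension in nN.
#' @export
probe_tension <- function(profile, width, T_cl_max) {
  if (length(profile) == 0L) stop("empty profile")
  if (width < 0) stop("negative width")
  if (width < 0.6)
    warning(sprintf("probe width %.2f um is below the 0.6 um model definition; tension may be under-resolved", width))
  T_cl_max * mean(profile) * width
}

#' Equivalent Young's modulus of a stress fiber
#'
#' Treating the fiber as a circular rod of the given diameter under the given
#' tensile strain, `E = T / (pi * (d/2)^2 * strain)`. In the package units
#' (nN, um) the result is directly in kPa.
#'
#' @param tension fiber tension in nN.
#' @param diameter fiber diameter in micrometers.
#' @param strain dimensionless tensile strain (the model pre-strain, 0.2, for
#'   a fiber at rest length).
#' @return Young's modulus in kPa.
#' @export
equivalent_young_modulus <- function(tension, diameter, strain) {
  if (diameter <= 0) stop("'diameter' must be positive")
  if (strain <= 0) stop("'strain' must be positive")
  tension / (pi * (diameter / 2)^2 * strain)
}

#' Whole-cell tonus across a section
#'
#' Measures the total tension transiting a cell-spanning segment (the
#' intracellular tonus) and relates it to the measured FA force sum.
#'
#' @param image normalized actin [channel_image].
#' @param p0,p1 segment endpoints (um) spanning the cell footprint.
#' @param T_cl_max cross-linear tension scale (nN/um).
#' @param F_measured FA force sum (nN).
#' @param spacing sample spacing, as in [sample_profile()].
#' @return A list: `tension` (nN), `ratio_pct` (tension as a percentage of
#'   `F_measured`; 0 when `F_measured` is 0).
#' @export
tonus <- function(image, p0, p1, T_cl_max, F_measured,
                  spacing = image$pixel_pitch / 2) {
  prof <- sample_profile(image, p0, p1, spacing)
  width <- sqrt(sum((p1 - p0)^2))
  tens <- T_cl_max * mean(prof) * width
  list(tension = tens,
       ratio_pct = if (F_measured > 0) 100 * tens / F_measured else 0)
}

#' Measure a table of probes
#'
#' Applies [sample_profile()] + [probe_tension()] to each row of a probe
#' table.
#'
#' @param image normalized actin [channel_image].
#' @param probes data frame with columns `x0`, `y0`, `x1`, `y1`; micrometers
#'   by default, pixels if `units = "px"`.
#' @param T_cl_max cross-linear tension scale (nN/um).
#' @param units `"um"` or `"px"`.
#' @return The probe table plus `width_um`, `c_mean`, `tension_nN`.
#' @export
measure_probes <- function(image, probes, T_cl_max, units = c("um", "px")) {
  units <- match.arg(units)
  f <- if (units == "px") image$pixel_pitch else 1
  out <- probes
  out$width_um <- sqrt((probes$x1 - probes$x0)^2 + (probes$y1 - probes$y0)^2) * f
  res <- lapply(seq_len(nrow(probes)), function(i) {
    prof <- sample_profile(image, c(probes$x0[i], probes$y0[i]) * f,
                           c(probes$x1[i], probes$y1[i]) * f)
    c(mean(prof), probe_tension(prof, out$width_um[i], T_cl_max))
  })
  out$c_mean <- vapply(res, `[`, numeric(1), 1L)
  out$tension_nN <- vapply(res, `[`, numeric(1), 2L)
  out
}
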
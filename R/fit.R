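#' Fit an image-based cell tension model
#'
#' The package's central estimator. From the three fluorescence channels of
#' one adherent cell it (1) normalizes the actin channel and derives the cell
#' footprint, (2) detects focal adhesions in the FA-marker (vinculin) mask and
#' converts their areas into a measured force sum `F_measured` (5.5 nN/um^2,
#' adhesions >= 1 um^2), (3) converts 2x2 pixel blocks into labelled
#' mechanical nodes joined by pre-strained tensile interactions whose
#' stiffness is proportional to actin density through an unknown coefficient
#' `a`, (4) relaxes the network over a sweep of `a` values and solves the
#' inverse problem `sum of model FA forces = F_measured` by linear
#' interpolation, and (5) relaxes the calibrated model and summarizes
#' intracellular tensions, including the cross-linear scale `T_cl_max` that
#' converts image gray profiles into forces.
#'
#' @param actin path to the actin TIFF, or a [channel_image], or a
#'   [cell_image_set()] / `synthetic_cell` (in which case `vinculin` and
#'   `nucleus` are ignored).
#' @param vinculin,nucleus paths to the FA-marker and nucleus TIFFs, or
#'   [channel_image]s, or logical masks.
#' @param pixel_pitch um/pixel (required for path/channel input).
#' @param scenario `"MT+"` (sphere-sphere compression contacts enabled,
#'   microtubule-like compression bearing) or `"MT-"` (tension only).
#' @param a_values calibration sweep grid (nN).
#' @param adhesion an [adhesion_config()].
#' @param solver a [solver_config()]; its `contact_enabled` is overridden by
#'   `scenario`.
#' @param background_percentile see [normalize_actin()].
#' @param ... passed to [build_cell_model()] (e.g. `epsilon0`, `gv_factor`,
#'   `mass_pg`).
#' @return An object of class `cell_tension` with components `images`,
#'   `adhesions`, `F_measured`, `curve`, `a`, `model`, `state`, `summary`,
#'   `scenario`, `call`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`, `fitted`.
#' @seealso [predict.cell_tension()] to measure probe tensions on the image.
#' @export
#' @examples
#' \donttest{
#' cell <- generate_cell(reference_cell())
#' fit <- fit_cell_tension(cell)
#' fit
#' coef(fit)
#' }
fit_cell_tension <- function(actin, vinculin = NULL, nucleus = NULL,
                             pixel_pitch = NULL, scenario = c("MT+", "MT-"),
                             a_values = c(1, 4, 8, 15),
                             adhesion = adhesion_config(),
                             solver = solver_config(),
                             background_percentile = 0.01, ...) {
  scenario <- match.arg(scenario)
  cl <- match.call()
  images <- as_image_set(actin, vinculin, nucleus, pixel_pitch,
                         background_percentile)
  fas <- detect_adhesions(images$vinculin_mask, images$pixel_pitch, adhesion)
  if (nrow(fas) == 0L) stop("FA stage: no focal adhesions in the vinculin mask")
  est <- estimate_forces(fas, adhesion)
  if (est$F_measured <= 0)
    stop("FA stage: no adhesion reaches the minimum area; cannot calibrate")
  model0 <- build_cell_model(images, a = a_values[1], ...)
  solver$contact_enabled <- scenario == "MT+"
  cal <- calibrate(model0, est$F_measured, a_values, solver)
  structure(list(images = images, adhesions = est$adhesions,
                 F_measured = est$F_measured,
                 curve = cal$curve, a = cal$curve$a_solved,
                 model = cal$model, state = cal$state, summary = cal$summary,
                 scenario = scenario, solver = solver, call = cl),
            class = "cell_tension")
}

# Accept the various actin/vinculin/nucleus input forms.
as_image_set <- function(actin, vinculin, nucleus, pixel_pitch,
                         background_percentile) {
  if (inherits(actin, "synthetic_cell")) return(actin$images)
  if (inherits(actin, "cell_image_set")) return(actin)
  grab <- function(x, what, binar = TRUE) {
    if (is.character(x)) {
      if (!file.exists(x)) stop(what, " stage: file not found: ", x)
      x <- load_channel(x, pixel_pitch)
    }
    if (inherits(x, "channel_image") && binar) x <- binarize(x, "otsu")
    x
  }
  if (is.null(vinculin) || is.null(nucleus))
    stop("vinculin and nucleus inputs are required")
  if (is.character(actin)) {
    if (is.null(pixel_pitch)) stop("'pixel_pitch' is required for file input")
    actin <- load_channel(actin, pixel_pitch)
  }
  actin <- normalize_actin(actin, background_percentile)
  cell_image_set(actin, grab(vinculin, "FA"), grab(nucleus, "nucleus"))
}

#' @export
print.cell_tension <- function(x, ...) {
  cat(sprintf("Image-based cell tension model (scenario %s)\n", x$scenario))
  cat(sprintf("  %d focal adhesions >= %.2g um^2, F_measured = %.4g nN\n",
              sum(x$adhesions$force_nN > 0), min(x$adhesions$area_um2[x$adhesions$force_nN > 0]),
              x$F_measured))
  cat(sprintf("  %d nodes, %d interactions, d0 = %.3g um\n",
              nrow(x$model$nodes), nrow(x$model$interactions), x$model$d0))
  cat(sprintf("  calibration: F = %.4g * a %s %.4g (R^2 = %.4f) => a = %.4g nN\n",
              x$curve$alpha, if (x$curve$beta >= 0) "-" else "+",
              abs(x$curve$beta), x$curve$r2, x$a))
  cat(sprintf("  T_mean = %.4g nN, T_mean_cl = %.4g nN/um, T_cl_max = %.4g nN/um\n",
              x$summary$T_mean, x$summary$T_mean_cl, x$summary$T_cl_max))
  invisible(x)
}

#' @export
summary.cell_tension <- function(object, ...) {
  tc <- tension_compression_summary(object$state)
  out <- list(fit = object, tc = tc,
              residual = object$state$residual,
              free_run_length = utils::tail(object$state$free_run_length, 1L),
              penetration_max = object$state$penetration_max)
  class(out) <- "summary.cell_tension"
  out
}

#' @export
print.summary.cell_tension <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  tension sum %.4g nN (%d taut), compression sum %.4g nN (%d contacts), ratio %.3g\n",
              x$tc$tension_sum, x$tc$n_tension, x$tc$compression_sum,
              x$tc$n_compression, x$tc$ratio))
  cat(sprintf("  residual %.3g nN, final free run length %.3g um/step, max penetration %.3g um\n",
              x$residual, x$free_run_length, x$penetration_max))
  cat("  per-label stiffness and cross-linear tension range:\n")
  print(x$fit$summary$per_label, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.cell_tension <- function(object, ...) {
  c(a = object$a, alpha = object$curve$alpha, beta = object$curve$beta,
    r2 = object$curve$r2, F_measured = object$F_measured,
    T_mean = object$summary$T_mean, T_mean_cl = object$summary$T_mean_cl,
    T_cl_max = object$summary$T_cl_max)
}

#' Predict probe tensions from a fitted cell tension model
#'
#' Measures the tension transiting user-drawn segments (typically drawn across
#' stress fibers) on the normalized actin image, using the fitted cross-linear
#' tension scale.
#'
#' @param object a `cell_tension` fit.
#' @param probes data frame with `x0, y0, x1, y1` (um by default).
#' @param units `"um"` or `"px"`.
#' @param ... unused.
#' @return The probe table with `width_um`, `c_mean`, `tension_nN`.
#' @export
predict.cell_tension <- function(object, probes, units = "um", ...) {
  measure_probes(object$images$actin, probes, object$summary$T_cl_max,
                 units = units)
}

#' @export
residuals.cell_tension <- function(object, ...) {
  with(object$curve, fa_sums - (alpha * a_values - beta))
}

#' @export
fitted.cell_tension <- function(object, ...) {
  with(object$curve, alpha * a_values - beta)
}

#' Plot a fitted cell tension model
#'
#' Two panels: the calibration sweep with its linear fit and the solved
#' coefficient, and the relaxed node network with interactions shaded by
#' tension.
#'
#' @param x a `cell_tension` fit.
#' @param which subset of `1:2`.
#' @param ... unused.
#' @export
plot.cell_tension <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(x$curve$a_values, x$curve$fa_sums, pch = 19,
                   xlab = "stiffness coefficient a (nN)",
                   ylab = "sum of FA forces (nN)",
                   main = sprintf("calibration (R^2 = %.3f)", x$curve$r2))
    graphics::abline(-x$curve$beta, x$curve$alpha, col = "gray40")
    graphics::abline(h = x$F_measured, lty = 2, col = "red3")
    graphics::points(x$a, x$F_measured, col = "red3", pch = 4, cex = 1.5)
  }
  if (2 %in% which) {
    pos <- x$state$positions
    tns <- x$state$tensions
    graphics::plot(pos[, 1], -pos[, 2], cex = 0.2, pch = 16, asp = 1,
                   col = ifelse(x$model$nodes$fixed, "red3", "gray60"),
                   xlab = "x (um)", ylab = "-y (um)", main = "tension network")
    act <- tns$tension > 0
    if (any(act)) {
      q <- tns$tension[act] / max(tns$tension[act])
      graphics::segments(pos[tns$a[act], 1], -pos[tns$a[act], 2],
                         pos[tns$b[act], 1], -pos[tns$b[act], 2],
                         col = grDevices::gray(1 - 0.9 * q))
    }
  }
  invisible(x)
}
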
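#' Parametric sweep of the stiffness coefficient
#'
#' Rebuilds the model at each candidate stiffness coefficient `a`, relaxes it,
#' and records the resulting sum of focal-adhesion reaction forces. The force
#' sum is almost linearly proportional to `a`, which is what the inverse
#' calibration exploits.
#'
#' @param model_builder function of one argument `a` returning a `cell_model`.
#' @param a_values candidate coefficients in nN; default `c(1, 4, 8, 15)`
#'   spans the working 1-15 range with four points.
#' @param config a [solver_config()].
#' @return An object of class `calibration_curve`: list with `a_values`,
#'   `fa_sums`, and (after [fit_linear()]) `alpha`, `beta`, `r2`, and (after
#'   [solve_a()]) `a_solved`.
#' @export
sweep_stiffness <- function(model_builder, a_values = c(1, 4, 8, 15),
                            config = solver_config()) {
  if (length(a_values) < 2L) stop("need at least 2 sweep points")
  fa_sums <- vapply(a_values, function(a) {
    st <- tryCatch(relax(model_builder(a), config),
                   error = function(e) stop("sweep failed at a = ", a, ": ",
                                            conditionMessage(e)))
    sum_fa_forces(st)
  }, numeric(1))
  structure(list(a_values = a_values, fa_sums = fa_sums,
                 alpha = NA_real_, beta = NA_real_, r2 = NA_real_,
                 a_solved = NA_real_),
            class = "calibration_curve")
}

#' Fit the linear force-stiffness relation
#'
#' Ordinary least squares of the FA force sums on the swept coefficients,
#' parameterized as `F = alpha * a - beta` (`beta` stores the positive
#' constant). A warning is emitted when R^2 < 0.9: the relation should be
#' close to linear for any contractile model.
#'
#' @param curve a `calibration_curve` from [sweep_stiffness()].
#' @return The curve with `alpha`, `beta`, `r2` filled in.
#' @export
fit_linear <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(unique(curve$a_values)) < 2L)
    stop("zero variance in swept 'a' values")
  fit <- stats::lm(fa_sums ~ a_values,
                   data = data.frame(a_values = curve$a_values,
                                     fa_sums = curve$fa_sums))
  curve$alpha <- unname(stats::coef(fit)[2])
  curve$beta <- -unname(stats::coef(fit)[1])
  # exactly collinear sweeps are legitimate here; silence lm's perfect-fit note
  curve$r2 <- if (stats::var(curve$fa_sums) > 0)
    suppressWarnings(summary(fit)$r.squared) else 1
  if (length(curve$a_values) == 2L) curve$r2 <- 1
  if (curve$r2 < 0.9)
    warning(sprintf("calibration fit is weakly linear (R^2 = %.3f)", curve$r2))
  curve
}

#' Solve the inverse calibration for the stiffness coefficient
#'
#' Inverts the fitted line: `a_solved = (F_measured + beta) / alpha`. Warns
#' when the solution falls outside the swept range (extrapolation).
#'
#' @param curve a fitted `calibration_curve`.
#' @param F_measured experimentally estimated FA force sum (nN), from
#'   [estimate_forces()].
#' @return The solved coefficient `a` in nN.
#' @export
solve_a <- function(curve, F_measured) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.na(curve$alpha)) curve <- fit_linear(curve)
  if (curve$alpha <= 0)
    stop("non-positive calibration slope: model is not contractile")
  a <- (F_measured + curve$beta) / curve$alpha
  if (a < min(curve$a_values) || a > max(curve$a_values))
    warning(sprintf("solved a = %.3g lies outside the swept range [%.3g, %.3g] (extrapolation)",
                    a, min(curve$a_values), max(curve$a_values)))
  a
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  print(data.frame(a = x$a_values, fa_sum_nN = x$fa_sums), row.names = FALSE)
  if (!is.na(x$alpha))
    cat(sprintf("  fit: F = %.4g * a - %.4g (R^2 = %.4f)\n", x$alpha, x$beta, x$r2))
  if (!is.na(x$a_solved)) cat(sprintf("  a_solved = %.4g nN\n", x$a_solved))
  invisible(x)
}

#' Tension summary of a calibrated, relaxed model
#'
#' Summarizes intracellular tensions at the solved stiffness coefficient.
#' `T_mean` is the mean force magnitude over taut interactions (slack members
#' excluded). Cross-linear (per unit transverse length) quantities divide by
#' the node spacing `d0`, making them resolution-independent:
#' `T_mean_cl = T_mean / d0` and `T_cl_max = a * epsilon0 / d0` (the tension
#' density at maximal actin density, gray value 1). Because the pre-stressed
#' network relaxes very little, `a / d0` is an equivalent scale without the
#' pre-strain factor; both are reported.
#'
#' @param state a relaxed `model_state`.
#' @param model the matching `cell_model` (carrying the calibrated `a`).
#' @return A list of class `tension_summary`: `T_mean`, `T_mean_cl`,
#'   `T_cl_max` (`= a * epsilon0 / d0`), `T_cl_max_stiffness` (`= a / d0`),
#'   `per_label` (data frame: label, `K_nN`, `Tcl_min`, `Tcl_max` over the
#'   gray-value bin), `d0`, `a`, `epsilon0`, `n_active`.
#' @export
tension_summary <- function(state, model) {
  tns <- state$tensions$tension
  act <- tns > 0
  if (!any(act)) stop("no active tensile interactions")
  a <- model$a; d0 <- model$d0; e0 <- model$epsilon0
  i <- 1:10
  per_label <- data.frame(label = i,
                          K_nN = a * 0.1 * i,
                          Tcl_min = a * 0.1 * (i - 1) * e0 / d0,
                          Tcl_max = a * 0.1 * i * e0 / d0)
  structure(list(T_mean = mean(tns[act]),
                 T_mean_cl = mean(tns[act]) / d0,
                 T_cl_max = a * e0 / d0,
                 T_cl_max_stiffness = a / d0,
                 per_label = per_label,
                 d0 = d0, a = a, epsilon0 = e0, n_active = sum(act)),
            class = "tension_summary")
}

#' @export
print.tension_summary <- function(x, ...) {
  cat(sprintf("<tension_summary> a = %.4g nN, d0 = %.3g um, epsilon0 = %.2g\n",
              x$a, x$d0, x$epsilon0))
  cat(sprintf("  T_mean = %.4g nN over %d taut interactions; T_mean_cl = %.4g nN/um\n",
              x$T_mean, x$n_active, x$T_mean_cl))
  cat(sprintf("  T_cl_max = %.4g nN/um (a*eps0/d0); a/d0 = %.4g nN/um\n",
              x$T_cl_max, x$T_cl_max_stiffness))
  invisible(x)
}

#' Calibrate a cell model against measured FA forces
#'
#' Convenience wrapper: sweeps `a`, fits the line, solves for the coefficient
#' matching `F_measured`, and returns the curve together with the relaxed
#' state and tension summary at the solution.
#'
#' @param model a `cell_model` (any positive `a`; geometry is reused).
#' @param F_measured measured FA force sum (nN).
#' @param a_values sweep grid.
#' @param config a [solver_config()].
#' @return A list: `curve` (fitted, with `a_solved`), `model` (at the solved
#'   a), `state`, `summary`.
#' @export
calibrate <- function(model, F_measured, a_values = c(1, 4, 8, 15),
                      config = solver_config()) {
  if (F_measured <= 0)
    stop("F_measured must be positive: no focal adhesion forces to match")
  curve <- sweep_stiffness(function(a) set_stiffness(model, a), a_values, config)
  curve <- fit_linear(curve)
  curve$a_solved <- solve_a(curve, F_measured)
  model <- set_stiffness(model, curve$a_solved)
  state <- relax(model, config)
  list(curve = curve, model = model, state = state,
       summary = tension_summary(state, model))
}
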
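#' Run the full tension-mapping pipeline and write a report bundle
#'
#' Executes load -> FA detection -> network build -> calibration sweep ->
#' relaxation at the solved coefficient -> tension summary, and writes the FA
#' table (CSV), the model (JSON), the calibration report (JSON), the relaxed
#' state (CSV: node positions, per-interaction tensions, per-contact
#' reactions), the per-label table (CSV), the summary (JSON), and an overlay
#' PNG of retained adhesions. Re-running with identical inputs reproduces
#' identical numbers (the solver is deterministic).
#'
#' @inheritParams fit_cell_tension
#' @param out_dir output directory (created if needed).
#' @param probes optional probe table (`x0, y0, x1, y1` in um) measured on the
#'   actin image and written as `probes.csv`.
#' @param quiet suppress per-stage messages.
#' @return The `cell_tension` fit, invisibly; the report paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(actin, vinculin = NULL, nucleus = NULL,
                         pixel_pitch = NULL, out_dir = ".",
                         scenario = "MT+", a_values = c(1, 4, 8, 15),
                         adhesion = adhesion_config(),
                         solver = solver_config(), probes = NULL,
                         quiet = FALSE, ...) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- fit_cell_tension(actin, vinculin, nucleus, pixel_pitch,
                          scenario = scenario, a_values = a_values,
                          adhesion = adhesion, solver = solver, ...)
  say("calibrated a = %.4g nN (R^2 = %.4f) in %.1f s", fit$a, fit$curve$r2,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  paths <- c(fa = file.path(out_dir, "fa_table.csv"),
             model = file.path(out_dir, "model.json"),
             calibration = file.path(out_dir, "calibration.json"),
             nodes = file.path(out_dir, "state_nodes.csv"),
             tensions = file.path(out_dir, "state_tensions.csv"),
             contacts = file.path(out_dir, "state_contacts.csv"),
             labels = file.path(out_dir, "per_label.csv"),
             summary = file.path(out_dir, "summary.json"),
             overlay = file.path(out_dir, "fa_overlay.png"))
  utils::write.csv(fit$adhesions, paths["fa"], row.names = FALSE)
  write_model_json(fit$model, paths["model"])
  jsonlite::write_json(
    list(a_values = fit$curve$a_values, fa_sums = fit$curve$fa_sums,
         alpha = fit$curve$alpha, beta = fit$curve$beta, r2 = fit$curve$r2,
         a_solved = fit$a, F_measured = fit$F_measured,
         scenario = fit$scenario),
    paths["calibration"], auto_unbox = TRUE, digits = NA)
  st <- fit$state
  utils::write.csv(data.frame(id = fit$model$nodes$id,
                              kind = fit$model$nodes$kind,
                              x_um = st$positions[, 1], y_um = st$positions[, 2]),
                   paths["nodes"], row.names = FALSE)
  utils::write.csv(st$tensions, paths["tensions"], row.names = FALSE)
  utils::write.csv(st$contacts, paths["contacts"], row.names = FALSE)
  utils::write.csv(fit$summary$per_label, paths["labels"], row.names = FALSE)
  tc <- tension_compression_summary(st)
  jsonlite::write_json(
    list(T_mean = fit$summary$T_mean, T_mean_cl = fit$summary$T_mean_cl,
         T_cl_max = fit$summary$T_cl_max,
         T_cl_max_stiffness = fit$summary$T_cl_max_stiffness,
         d0 = fit$model$d0, epsilon0 = fit$model$epsilon0, a = fit$a,
         scenario = fit$scenario, tension_sum = tc$tension_sum,
         compression_sum = tc$compression_sum, ratio = tc$ratio,
         residual = st$residual, converged = st$converged,
         free_run_length_final = utils::tail(st$free_run_length, 1L),
         penetration_max = st$penetration_max),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  fa_overlay_png(fit, paths["overlay"])
  if (!is.null(probes)) {
    paths <- c(paths, probes = file.path(out_dir, "probes.csv"))
    utils::write.csv(predict(fit, probes), paths["probes"], row.names = FALSE)
  }
  say("report written to %s", out_dir)
  attr(fit, "paths") <- paths
  invisible(fit)
}

# Overlay of retained focal adhesions on the actin image.
fa_overlay_png <- function(fit, path) {
  img <- fit$images$actin$intensities
  p <- fit$images$pixel_pitch
  grDevices::png(path, width = ncol(img), height = nrow(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(0, type = "n", xlim = c(0, ncol(img) * p),
                 ylim = c(nrow(img) * p, 0), xaxs = "i", yaxs = "i",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(img, 0, nrow(img) * p, ncol(img) * p, 0)
  kept <- fit$adhesions[fit$adhesions$force_nN > 0, ]
  if (nrow(kept)) {
    r <- sqrt(kept$area_um2 / pi)
    graphics::symbols(kept$centroid_x_um, kept$centroid_y_um, circles = r,
                      inches = FALSE, add = TRUE, fg = "red")
  }
  invisible(path)
}
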
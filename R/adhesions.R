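#' Focal-adhesion analysis configuration
#'
#' Focal-adhesion (FA) areas are converted into traction-force magnitudes with
#' the linear area-force relation of 5.5 nN/um^2, applied to adhesions of at
#' least 1 um^2 (below that size, area no longer predicts force). Sub-micrometer
#' adhesions in the 0.5-1 um^2 class can optionally be assigned a fixed force
#' (15 nN each, the reported average for that class); this is off by default.
#'
#' @param force_coefficient nN per um^2 of FA area (default 5.5).
#' @param min_area smallest FA area (um^2) entering the force budget; the bound
#'   is inclusive (default 1.0).
#' @param connectivity pixel connectivity for FA labelling, 4 or 8 (default 8,
#'   the usual particle-analysis convention).
#' @param submicron_force nN assigned to each FA in the 0.5-1 um^2 class when
#'   `submicron_enabled = TRUE`.
#' @param submicron_enabled logical; include the sub-micrometer class?
#' @return A list of class `adhesion_config`.
#' @export
adhesion_config <- function(force_coefficient = 5.5, min_area = 1.0,
                            connectivity = 8L, submicron_force = 15,
                            submicron_enabled = FALSE) {
  if (force_coefficient <= 0) stop("'force_coefficient' must be positive")
  if (min_area <= 0) stop("'min_area' must be positive")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  structure(list(force_coefficient = force_coefficient, min_area = min_area,
                 connectivity = connectivity, submicron_force = submicron_force,
                 submicron_enabled = isTRUE(submicron_enabled)),
            class = "adhesion_config")
}

#' Detect focal adhesions in a binary FA-marker mask
#'
#' Labels connected components of the vinculin mask as focal adhesions and
#' reports pixel counts, physical areas and centroids. No area filter is
#' applied here; see [filter_by_area()].
#'
#' @param mask logical matrix (vinculin mask).
#' @param pixel_pitch pixel size in micrometers.
#' @param config an [adhesion_config()].
#' @return A data frame with columns `id`, `pixel_count`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, sorted by decreasing area. Empty mask
#'   gives a zero-row data frame.
#' @export
detect_adhesions <- function(mask, pixel_pitch, config = adhesion_config()) {
  stopifnot(is.logical(mask), pixel_pitch > 0)
  lab <- label_mask(mask, connectivity = config$connectivity)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0)))
  idx <- which(lab > 0L)
  comp <- lab[idx]
  row <- ((idx - 1L) %% nrow(mask)) + 1L
  col <- ((idx - 1L) %/% nrow(mask)) + 1L
  px <- tabulate(comp, n)
  cx <- as.vector(rowsum(col - 0.5, comp)) / px * pixel_pitch
  cy <- as.vector(rowsum(row - 0.5, comp)) / px * pixel_pitch
  fas <- data.frame(id = seq_len(n), pixel_count = px,
                    area_um2 = px * pixel_pitch^2,
                    centroid_x_um = cx, centroid_y_um = cy)
  fas <- fas[order(-fas$area_um2), , drop = FALSE]
  rownames(fas) <- NULL
  fas
}

#' Filter focal adhesions by area
#'
#' Retains adhesions with `area_um2 >= min_area` (inclusive bound), preserving
#' order. Idempotent.
#'
#' @param fas data frame from [detect_adhesions()].
#' @param min_area minimum area in um^2.
#' @return The filtered data frame.
#' @export
filter_by_area <- function(fas, min_area = 1.0) {
  out <- fas[fas$area_um2 >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate traction forces from FA areas
#'
#' Applies the linear area-to-force relation: `force = force_coefficient *
#' area` for adhesions at or above `min_area`. When the sub-micrometer option
#' is enabled, adhesions in the 0.5-1 um^2 class each contribute
#' `submicron_force` instead. Adhesions below both cut-offs carry zero force.
#'
#' @param fas data frame from [detect_adhesions()] (filtered or not).
#' @param config an [adhesion_config()].
#' @return A list with `adhesions` (the input plus a `force_nN` column) and
#'   `F_measured` (sum of force magnitudes, nN).
#' @export
estimate_forces <- function(fas, config = adhesion_config()) {
  if (config$force_coefficient <= 0) stop("negative or zero force coefficient")
  area <- fas$area_um2
  force <- numeric(length(area))
  main <- area >= config$min_area
  force[main] <- config$force_coefficient * area[main]
  if (config$submicron_enabled) {
    sub <- area >= 0.5 & area < config$min_area
    force[sub] <- config$submicron_force
  }
  fas$force_nN <- force
  list(adhesions = fas, F_measured = sum(force))
}
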
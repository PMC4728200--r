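#' Actin density label of a normalized gray value
#'
#' Gray values in `]0, 1]` are partitioned into 10 right-closed bins
#' `C_i = ]0.1*(i-1), 0.1*i]`; the label index i in 1..10 encodes local actin
#' density (l10 = densest). A gray value of exactly 0 carries no actin and
#' yields `NA` (no node).
#'
#' @param c numeric vector of normalized gray values in `[0, 1]`.
#' @return Integer vector of labels in 1..10, `NA` where `c == 0`.
#' @export
label_of <- function(c) {
  if (any(c < 0 | c > 1, na.rm = TRUE)) stop("gray values must lie in [0, 1]")
  i <- pmax(1L, as.integer(ceiling(c * 10 - 1e-9)))
  i[c == 0] <- NA_integer_
  i
}

#' Convert image pixels to mechanical nodes
#'
#' Partitions the frame into `binning` x `binning` pixel blocks (2x2 by
#' default), one candidate node per block (node spacing `d0 = binning *
#' pixel_pitch`; at the reference pitch of 0.29 um the default gives d0 =
#' 0.58 um). Within a block the node kind is decided by priority
#' vinculin > nucleus > actin: an FA-marker block makes an immobile vinculin
#' anchor; else a nucleus block makes a nucleus node; else a block whose mean
#' actin gray value is positive inside the cell footprint makes an actin node
#' labelled by [label_of()] on the block mean. Node positions sit at block
#' centers. Marker (vinculin, nucleus) components are rasterized
#' area-conservingly: each connected component claims its area-equivalent
#' number of blocks (at least one), those it covers most, so the effective
#' anchor size does not depend on the model resolution. Trailing partial
#' rows/columns are ignored.
#'
#' @param images a [cell_image_set()].
#' @param binning block edge in pixels (default 2); controls the model
#'   resolution d0.
#' @param mass_pg node mass in picograms (default 0.8, the mass of the
#'   water volume enclosed by a contactor sphere).
#' @param contactor_radius_factor contactor sphere radius as a fraction of d0
#'   (default 0.4; spheres only touch after ~20% mutual approach).
#' @param max_nodes node-count cap (default 10000).
#' @return A data frame of nodes: `id`, `kind` (actin/nucleus/vinculin),
#'   `label` (1..10, `NA` for non-actin), `x_um`, `y_um`, `fixed`, `mass_pg`,
#'   `radius_um`.
#' @export
pixels_to_nodes <- function(images, binning = 2L, mass_pg = 0.8,
                            contactor_radius_factor = 0.4,
                            max_nodes = 10000L) {
  stopifnot(inherits(images, "cell_image_set"))
  b <- as.integer(binning)
  stopifnot(b >= 1L)
  p <- images$pixel_pitch
  d0 <- b * p
  act <- images$actin$intensities
  act[!images$cell_mask] <- 0
  hb <- nrow(act) %/% b
  wb <- ncol(act) %/% b
  if (hb == 0L || wb == 0L) stop("image too small for the requested binning")
  blocksum <- function(m) {
    m <- m[seq_len(hb * b), seq_len(wb * b), drop = FALSE]
    r <- rowsum(m, rep(seq_len(hb), each = b))
    t(rowsum(t(r), rep(seq_len(wb), each = b)))
  }
  mean_c <- blocksum(act) / b^2
  # area-conserving rasterization: every marker component is assigned its
  # area-equivalent number of blocks (at least one), picking the blocks it
  # covers most. An any-pixel rule would dilate each adhesion by half a block
  # per side, making the effective anchor perimeter - and the calibrated
  # stiffness - depend on the model resolution; a majority rule can drop
  # whole adhesions at coarse resolution.
  rasterize <- function(mask) {
    if (b == 1L) return(mask[seq_len(hb), seq_len(wb), drop = FALSE])
    lab <- label_mask(mask, 8L)
    sel <- matrix(FALSE, hb, wb)
    for (comp in seq_len(max(lab))) {
      cov <- as.vector(blocksum((lab == comp) * 1L))
      k <- min(max(1L, as.integer(round(sum(cov) / b^2))), sum(cov > 0L))
      sel[order(-cov)[seq_len(k)]] <- TRUE
    }
    sel
  }
  vinc <- rasterize(images$vinculin_mask)
  nucl <- rasterize(images$nucleus_mask)
  kind <- matrix(NA_character_, hb, wb)
  kind[mean_c > 0] <- "actin"
  kind[nucl] <- "nucleus"
  kind[vinc] <- "vinculin"
  sel <- which(!is.na(kind))
  if (length(sel) == 0L) stop("empty footprint: no nodes")
  if (length(sel) > max_nodes)
    stop(sprintf("node cap exceeded (%d > %d): use coarser binning or crop the frame",
                 length(sel), max_nodes))
  br <- ((sel - 1L) %% hb) + 1L
  bc <- ((sel - 1L) %/% hb) + 1L
  kinds <- kind[sel]
  lab <- ifelse(kinds == "actin", label_of(pmin(mean_c[sel], 1)), NA_integer_)
  data.frame(id = seq_along(sel),
             kind = kinds,
             label = as.integer(lab),
             x_um = (bc - 0.5) * d0,
             y_um = (br - 0.5) * d0,
             fixed = kinds == "vinculin",
             mass_pg = mass_pg,
             radius_um = contactor_radius_factor * d0)
}

#' Interaction stiffness for a node pair
#'
#' Stiffness of the tensile interaction law between two nodes, proportional to
#' actin density through the coefficient `a` (nN): actin-actin pairs use the
#' weaker partner's label, `K = a * 0.1 * min(i, j)`; actin-nucleus and
#' actin-vinculin pairs use the actin partner's label; nucleus-involved pairs
#' without an actin side are homogeneous at ten times the strongest actin
#' interaction, `K = 10 * a`.
#'
#' @param kind_a,kind_b node kinds (`"actin"`, `"nucleus"`, `"vinculin"`),
#'   vectorized.
#' @param label_a,label_b actin labels (1..10; `NA` for non-actin nodes).
#' @param a stiffness coefficient in nN (> 0).
#' @return Numeric vector of stiffnesses K (nN per unit strain).
#' @export
stiffness_for <- function(kind_a, kind_b, label_a, label_b, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0)
    stop("'a' must be a positive number (is the model calibrated?)")
  n <- length(kind_a)
  K <- numeric(n)
  a_is_actin <- kind_a == "actin"
  b_is_actin <- kind_b == "actin"
  both <- a_is_actin & b_is_actin
  one <- xor(a_is_actin, b_is_actin)
  none <- !a_is_actin & !b_is_actin
  if (any(both)) {
    if (anyNA(label_a[both]) || anyNA(label_b[both]))
      stop("unlabeled actin node")
    K[both] <- a * 0.1 * pmin(label_a[both], label_b[both])
  }
  if (any(one)) {
    lab <- ifelse(a_is_actin[one], label_a[one], label_b[one])
    if (anyNA(lab)) stop("unlabeled actin node")
    K[one] <- a * 0.1 * lab
  }
  K[none] <- 10 * a  # nucleus-nucleus (and nucleus-vinculin) pairs
  K
}

#' Build tensile interactions between neighboring nodes
#'
#' Creates one pre-strained tensile interaction per unordered node pair whose
#' initial separation is at most the visibility threshold `g_v = gv_factor *
#' d0` (default 1.1 * d0; on the square node grid this selects exactly the
#' 4-neighborhood, since diagonal neighbors sit at 1.414 * d0). Each
#' interaction stores its creation gap `g0`, pre-strain `epsilon0`, and
#' stiffness from [stiffness_for()]. Vinculin-vinculin pairs (two anchors) are
#' never connected.
#'
#' @param nodes node data frame from [pixels_to_nodes()].
#' @param a stiffness coefficient (nN).
#' @param d0 nominal node spacing in micrometers.
#' @param gv_factor visibility threshold as a multiple of `d0`, in `(1, 2)`.
#' @param epsilon0 pre-strain (default 0.2, the measured contraction of stress
#'   fibers in static adherent cells).
#' @return A data frame of interactions: `a`, `b` (node ids), `g0`, `K`,
#'   `eps0`.
#' @export
build_interactions <- function(nodes, a, d0, gv_factor = 1.1, epsilon0 = 0.2) {
  if (gv_factor <= 1 || gv_factor >= 2)
    stop("'gv_factor' must lie in (1, 2) so diagonal neighbors stay unconnected")
  if (epsilon0 <= 0 || epsilon0 >= 1) stop("'epsilon0' must lie in (0, 1)")
  gv <- gv_factor * d0
  pairs <- pairs_within(cbind(nodes$x_um, nodes$y_um), gv)
  if (nrow(pairs) > 0L) {
    keep <- !(nodes$kind[pairs[, 1]] == "vinculin" &
              nodes$kind[pairs[, 2]] == "vinculin")
    pairs <- pairs[keep, , drop = FALSE]
  }
  ia <- pairs[, 1]; ib <- pairs[, 2]
  g0 <- sqrt((nodes$x_um[ia] - nodes$x_um[ib])^2 +
             (nodes$y_um[ia] - nodes$y_um[ib])^2)
  K <- stiffness_for(nodes$kind[ia], nodes$kind[ib],
                     nodes$label[ia], nodes$label[ib], a)
  data.frame(a = ia, b = ib, g0 = g0, K = K,
             eps0 = rep(epsilon0, length(ia)))
}

#' Assemble a cell model
#'
#' Builds the full mechanical model (labelled nodes plus tensile interactions)
#' from a registered image set at a given stiffness coefficient `a`.
#'
#' @param images a [cell_image_set()].
#' @param a stiffness coefficient (nN); the value is usually found later by
#'   [calibrate()] and the model rebuilt via [set_stiffness()].
#' @param gv_factor,epsilon0 see [build_interactions()].
#' @param binning model resolution in pixels per node edge (default 2).
#' @param ... passed to [pixels_to_nodes()].
#' @return An object of class `cell_model`: list with `nodes`, `interactions`,
#'   `d0`, `a`, `epsilon0`, `gv_factor`.
#' @export
build_cell_model <- function(images, a, gv_factor = 1.1, epsilon0 = 0.2,
                             binning = 2L, ...) {
  nodes <- pixels_to_nodes(images, binning = binning, ...)
  d0 <- binning * images$pixel_pitch
  inter <- build_interactions(nodes, a, d0, gv_factor, epsilon0)
  structure(list(nodes = nodes, interactions = inter, d0 = d0, a = a,
                 epsilon0 = epsilon0, gv_factor = gv_factor),
            class = "cell_model")
}

#' Rescale a model to a new stiffness coefficient
#'
#' All interaction stiffnesses are linear in `a`, so a model can be re-targeted
#' without rebuilding its geometry.
#'
#' @param model a `cell_model`.
#' @param a new stiffness coefficient (nN, > 0).
#' @return The rescaled `cell_model`.
#' @export
set_stiffness <- function(model, a) {
  stopifnot(inherits(model, "cell_model"), is.numeric(a), a > 0)
  model$interactions$K <- model$interactions$K * (a / model$a)
  model$a <- a
  model
}

#' @export
print.cell_model <- function(x, ...) {
  tab <- table(x$nodes$kind)
  cat(sprintf("<cell_model> %d nodes (%s), %d tensile interactions\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$interactions)))
  cat(sprintf("  d0 = %.3g um, epsilon0 = %.2g, a = %.4g nN\n",
              x$d0, x$epsilon0, x$a))
  invisible(x)
}

#' Serialize / restore a cell model as JSON
#'
#' @param model a `cell_model`.
#' @param path output (input) file path.
#' @return `write_model_json` returns the path invisibly; `read_model_json`
#'   returns the `cell_model`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(d0 = model$d0, a = model$a, epsilon0 = model$epsilon0,
         gv_factor = model$gv_factor, nodes = model$nodes,
         interactions = model$interactions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = as.data.frame(x$nodes),
                 interactions = as.data.frame(x$interactions),
                 d0 = x$d0, a = x$a, epsilon0 = x$epsilon0,
                 gv_factor = x$gv_factor),
            class = "cell_model")
}

# All unordered point pairs with separation <= cutoff, via a cell list with
# data.table joins over the half-neighborhood of cell offsets.
# Returns a 2-column integer matrix (a < b).
pairs_within <- function(x, cutoff) {
  n <- nrow(x)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  kx <- as.integer(floor(x[, 1] / cutoff))
  ky <- as.integer(floor(x[, 2] / cutoff))
  A <- data.table::data.table(id = seq_len(n), kx = kx, ky = ky, key = c("kx", "ky"))
  offs <- list(c(0L, 0L), c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  parts <- lapply(offs, function(o) {
    B <- data.table::data.table(id2 = seq_len(n), kx = kx + o[1], ky = ky + o[2])
    M <- A[B, on = c("kx", "ky"), nomatch = NULL, allow.cartesian = TRUE]
    if (o[1] == 0L && o[2] == 0L) M <- M[M$id < M$id2, ]
    cbind(M$id, M$id2)
  })
  prs <- do.call(rbind, parts)
  if (nrow(prs) == 0L) return(matrix(integer(0), 0L, 2L))
  d2 <- (x[prs[, 1], 1] - x[prs[, 2], 1])^2 + (x[prs[, 1], 2] - x[prs[, 2], 2])^2
  prs <- prs[d2 <= cutoff^2 + 1e-12, , drop = FALSE]
  cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
}
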
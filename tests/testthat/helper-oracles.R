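# Shared oracles and fixture builders. Everything here is independent of the
# package's own solver paths: the energy oracle minimizes the potential with
# stats::optim, the Otsu oracle enumerates thresholds.

# Hand-assembled mechanical model (positions in um).
toy_model <- function(x, y, fixed, springs, eps0 = 0.2, radius = 0.232,
                      d0 = 0.58, a = 1, kind = NULL) {
  n <- length(x)
  if (is.null(kind)) kind <- ifelse(fixed, "vinculin", "actin")
  nodes <- data.frame(id = seq_len(n), kind = kind,
                      label = ifelse(kind == "actin", 10L, NA_integer_),
                      x_um = x, y_um = y, fixed = fixed, mass_pg = 0.8,
                      radius_um = radius)
  inter <- data.frame(a = springs$a, b = springs$b, K = springs$K,
                      g0 = springs$g0, eps0 = eps0)
  structure(list(nodes = nodes, interactions = inter, d0 = d0, a = a,
                 epsilon0 = eps0, gv_factor = 1.1),
            class = "cell_model")
}

# Equilibrium positions by direct minimization of the elastic + contact
# potential (piecewise-quadratic spring energy, quadratic penalty), all node
# pairs considered contact candidates. Suitable for small systems.
oracle_equilibrium <- function(model, contact_enabled = TRUE, penalty = NULL,
                               reltol = 1e-14) {
  nodes <- model$nodes
  n <- nrow(nodes)
  free <- !nodes$fixed
  nf <- sum(free)
  if (is.null(penalty)) penalty <- 100 * model$a / model$d0
  inter <- model$interactions
  radii <- nodes$radius_um
  cand <- t(utils::combn(seq_len(n), 2L))
  cand <- cand[free[cand[, 1]] & free[cand[, 2]], , drop = FALSE]
  x0 <- cbind(nodes$x_um, nodes$y_um)
  unpack <- function(p) {
    xx <- x0
    xx[free, 1] <- p[seq_len(nf)]
    xx[free, 2] <- p[nf + seq_len(nf)]
    xx
  }
  energy <- function(p) {
    xx <- unpack(p)
    g <- sqrt((xx[inter$b, 1] - xx[inter$a, 1])^2 +
              (xx[inter$b, 2] - xx[inter$a, 2])^2)
    slack <- (1 - inter$eps0) * inter$g0
    e <- ifelse(g > slack,
                inter$K * ((g - inter$g0)^2 / (2 * inter$g0) +
                           inter$eps0 * (g - inter$g0)),
                inter$K * (slack - inter$g0) * inter$eps0 +
                  inter$K * (slack - inter$g0)^2 / (2 * inter$g0))
    tot <- sum(e)
    if (contact_enabled && nrow(cand)) {
      d <- sqrt((xx[cand[, 2], 1] - xx[cand[, 1], 1])^2 +
                (xx[cand[, 2], 2] - xx[cand[, 1], 2])^2)
      pen <- pmax(radii[cand[, 1]] + radii[cand[, 2]] - d, 0)
      tot <- tot + sum(penalty * pen^2 / 2)
    }
    tot
  }
  grad <- function(p) {
    xx <- unpack(p)
    dxp <- xx[inter$b, 1] - xx[inter$a, 1]
    dyp <- xx[inter$b, 2] - xx[inter$a, 2]
    g <- pmax(sqrt(dxp^2 + dyp^2), 1e-12)
    Tm <- tensile_force(g, inter$K, inter$g0, inter$eps0)
    gx <- gy <- numeric(n)
    for (k in seq_len(nrow(inter))) {
      fx <- Tm[k] * dxp[k] / g[k]; fy <- Tm[k] * dyp[k] / g[k]
      gx[inter$a[k]] <- gx[inter$a[k]] - fx; gy[inter$a[k]] <- gy[inter$a[k]] - fy
      gx[inter$b[k]] <- gx[inter$b[k]] + fx; gy[inter$b[k]] <- gy[inter$b[k]] + fy
    }
    if (contact_enabled && nrow(cand)) {
      dxc <- xx[cand[, 2], 1] - xx[cand[, 1], 1]
      dyc <- xx[cand[, 2], 2] - xx[cand[, 1], 2]
      d <- pmax(sqrt(dxc^2 + dyc^2), 1e-12)
      RN <- pmax(radii[cand[, 1]] + radii[cand[, 2]] - d, 0) * penalty
      for (k in seq_len(nrow(cand))) {
        fx <- -RN[k] * dxc[k] / d[k]; fy <- -RN[k] * dyc[k] / d[k]
        gx[cand[k, 1]] <- gx[cand[k, 1]] - fx; gy[cand[k, 1]] <- gy[cand[k, 1]] - fy
        gx[cand[k, 2]] <- gx[cand[k, 2]] + fx; gy[cand[k, 2]] <- gy[cand[k, 2]] + fy
      }
    }
    c(gx[free], gy[free])
  }
  p0 <- c(x0[free, 1], x0[free, 2])
  opt <- stats::optim(p0, energy, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = reltol))
  opt <- stats::optim(opt$par, energy, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = reltol))
  unpack(opt$par)
}

# Otsu threshold by brute force over candidate thresholds (between-class
# variance maximization on the raw values).
otsu_brute <- function(v) {
  cands <- sort(unique(as.vector(v)))
  cands <- (cands[-1] + cands[-length(cands)]) / 2
  best <- -Inf; thr <- cands[1]
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

# A small synthetic cell (fast to relax) used by module-level tests.
small_cell <- function(noise_sd = 0, seed = 7L) {
  synthetic_spec(
    canvas_px = c(70L, 100L), pixel_pitch = 0.29,
    fibers = data.frame(
      x0 = c(-11, -11), y0 = c(-4, 4), x1 = c(11, 11), y1 = c(-4, 4),
      width = c(1.2, 0.9), peak = c(0.95, 0.80)),
    belt = NULL,
    background_intensity = 0.08,
    nucleus = list(cx = 0, cy = 0, rx = 3.5, ry = 2.5),
    fa_sites = data.frame(
      x = c(-11, 11, -11, 11, 0, 0),
      y = c(-4, -4, 4, 4, 7.5, -7.5),
      area = c(1.3, 1.3, 1.3, 1.3, 1.2, 1.2)),
    support = list(cx = 0, cy = 0, rx = 13.8, ry = 9.5),
    noise_sd = noise_sd, seed = seed)
}
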
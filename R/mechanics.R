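#' Solver configuration
#'
#' The relaxation integrates the node equations of motion with a damped
#' semi-implicit Euler scheme over a fixed number of steps (default 600 steps
#' of 0.5 us, i.e. 300 us of simulated time). Units are pg / um / us, under
#' which `1 pg * um / us^2 = 1 nN` exactly.
#'
#' Contacts between the spherical node contactors implement the frictionless
#' rigid law (gap >= 0, reaction >= 0, gap * reaction = 0) by linear penalty
#' regularization: `RN = penalty * penetration`. `contact_enabled = FALSE`
#' turns the compression network off entirely (the "MT-" scenario, no
#' microtubule-like compression bearing).
#'
#' @param dt time step in microseconds.
#' @param steps number of integration steps.
#' @param damping per-step velocity retention factor in `[0, 1]`; `NULL`
#'   (default) uses 0.95 under mass preconditioning (mild momentum, which
#'   accelerates the slow global contraction mode) and otherwise the largest
#'   stable value `min(0.5, m_min / (dt^2 * k_max))` from the stiffest
#'   element (spring or penalty); see the package vignette.
#' @param precondition logical (default `TRUE`): integrate with fictitious
#'   per-node masses proportional to the local incident stiffness (classic
#'   dynamic relaxation). The static equilibrium — the quantity of interest
#'   for a fixed cell — does not depend on mass, and preconditioning lets the
#'   stiff penalty contacts and the soft network modes converge together
#'   within the standard 600 steps. Set `FALSE` to integrate with the
#'   physical node masses (true transient dynamics).
#' @param contact_enabled logical: MT+ (`TRUE`) or MT- (`FALSE`) scenario.
#' @param contact_penalty penalty stiffness in nN/um; `NULL` defaults to
#'   `100 * a / d0`, far above the stiffest tensile interaction.
#' @param equilibrium_tol residual-force tolerance (nN) used to report
#'   convergence (not enforced; the run length is fixed).
#' @param dynamic_visibility if `TRUE`, interactions stretched beyond their
#'   creation threshold `g_v` are dropped during motion. Off by default: the
#'   visibility threshold is a creation-time rule.
#' @param kinetic_restart logical (default `TRUE`): zero all velocities
#'   whenever the kinetic energy peaks (classic dynamic-relaxation damping);
#'   only active under preconditioning.
#' @param quench logical (default `TRUE`): drop the momentum retention to 0.5
#'   over the last fifth of the run so the state freezes into its
#'   equilibrium; only active under preconditioning.
#' @param step_limit maximum node displacement per step in micrometers;
#'   `NULL` (default) uses `0.1 * d0`. Displacement limiting keeps fast
#'   free-falling nodes from punching through contacts in one step; it does
#'   not affect the equilibrium reached.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt = 0.5, steps = 600L, damping = NULL,
                          contact_enabled = TRUE, contact_penalty = NULL,
                          equilibrium_tol = 1e-3, dynamic_visibility = FALSE,
                          precondition = TRUE, kinetic_restart = TRUE,
                          quench = TRUE, step_limit = NULL) {
  stopifnot(dt > 0, steps >= 1L)
  if (!is.null(damping) && (damping < 0 || damping > 1))
    stop("'damping' must lie in [0, 1]")
  structure(list(dt = dt, steps = as.integer(steps), damping = damping,
                 contact_enabled = isTRUE(contact_enabled),
                 contact_penalty = contact_penalty,
                 equilibrium_tol = equilibrium_tol,
                 dynamic_visibility = isTRUE(dynamic_visibility),
                 precondition = isTRUE(precondition),
                 kinetic_restart = isTRUE(kinetic_restart),
                 quench = isTRUE(quench),
                 step_limit = step_limit),
            class = "solver_config")
}

#' Tensile interaction force
#'
#' The pre-strained elastic band law: an interaction created at gap `g0` with
#' pre-strain `eps0` pulls with magnitude `T = K * ((g - g0)/g0 + eps0)` while
#' taut (`g > (1 - eps0) * g0`) and goes slack (T = 0) below that. The
#' visibility threshold `g_v` only gates interaction creation; a taut
#' interaction persists under stretch.
#'
#' @param g current gap (um), vectorized.
#' @param K stiffness (nN per unit strain).
#' @param g0 creation gap (um, > 0).
#' @param eps0 pre-strain in (0, 1).
#' @return Attraction magnitude in nN (>= 0).
#' @export
tensile_force <- function(g, K, g0, eps0) {
  if (any(g0 <= 0)) stop("'g0' must be positive")
  ifelse(g > (1 - eps0) * g0, K * ((g - g0) / g0 + eps0), 0)
}

#' Penalty contact force between two spherical contactors
#'
#' Linear penalty regularization of the frictionless rigid contact law: with
#' surface gap `g = distance - (r_a + r_b)`, the normal reaction is 0 for
#' `g > 0` and `penalty * (-g)` for `g <= 0` (repulsive along the pair axis).
#'
#' @param center_distance center-to-center distance (um), vectorized.
#' @param r_a,r_b contactor radii (um, > 0).
#' @param penalty penalty stiffness (nN/um).
#' @param enabled logical; `FALSE` (the MT- scenario) returns 0 always.
#' @return Normal reaction magnitude RN in nN (>= 0).
#' @export
contact_force <- function(center_distance, r_a, r_b, penalty, enabled = TRUE) {
  if (any(r_a <= 0) || any(r_b <= 0)) stop("contactor radii must be positive")
  if (any(center_distance == 0)) stop("coincident contactor centers")
  if (!enabled) return(numeric(length(center_distance)))
  g <- center_distance - (r_a + r_b)
  pmax(-g, 0) * penalty
}

# Internal: shared solver core. Runs `nsteps` steps from `state` (or from the
# model's build positions when state is NULL) and returns the full model_state.
engine_run <- function(model, config, nsteps, state = NULL) {
  nodes <- model$nodes
  inter <- model$interactions
  n <- nrow(nodes)
  dt <- config$dt
  mass <- nodes$mass_pg
  free <- !nodes$fixed
  x <- if (is.null(state)) cbind(nodes$x_um, nodes$y_um) else state$positions
  v <- if (is.null(state)) matrix(0, n, 2L) else state$velocities
  penalty <- config$contact_penalty
  if (is.null(penalty)) penalty <- 100 * model$a / model$d0

  ia <- inter$a; ib <- inter$b
  K <- inter$K; g0 <- inter$g0; eps0 <- inter$eps0
  gv <- model$gv_factor * g0
  S <- Matrix::sparseMatrix(i = c(ia, ib), j = rep(seq_along(ia), 2L),
                            x = rep(c(1, -1), each = length(ia)),
                            dims = c(n, length(ia)))
  alive <- rep(TRUE, length(ia))

  # penalty stiffness enters the stability/mass bookkeeping even when
  # contacts are off, so MT+ and MT- runs integrate identically
  k_spring <- if (length(K)) max(K / g0) else 0
  k_max <- max(k_spring, penalty)
  damping <- config$damping
  k_node <- NULL
  if (config$precondition) {
    # dynamic relaxation: fictitious mass from the local incident stiffness,
    # so every node advances at the same fraction of its local stability
    # limit; the penalty term is added per node only while it is in contact
    k_node <- numeric(n)
    if (length(ia)) {
      ks <- K / g0
      acc <- rowsum(c(ks, ks), c(ia, ib))
      k_node[as.integer(rownames(acc))] <- acc[, 1]
    }
    if (is.null(damping)) damping <- 0.95
  } else if (is.null(damping)) {
    damping <- min(0.5, min(mass) / (dt^2 * k_max))
  }

  step_limit <- config$step_limit
  if (is.null(step_limit))
    step_limit <- if (config$precondition) 0.1 * model$d0 else Inf

  radii <- nodes$radius_um
  margin <- 0.5  # um of slack in the contact candidate cutoff
  cutoff <- 2 * max(radii) + margin
  rebuild <- function(x) {
    prs <- pairs_within(x, cutoff)
    # contactors sit on movable (actin, nucleus) nodes only: compression
    # bearing is a cytoskeletal function, and anchor reactions report what
    # the contractile network transmits to the adhesion
    keep <- free[prs[, 1]] & free[prs[, 2]]
    prs <- prs[keep, , drop = FALSE]
    list(a = prs[, 1], b = prs[, 2],
         S = Matrix::sparseMatrix(i = c(prs[, 1], prs[, 2]),
                                  j = rep(seq_len(nrow(prs)), 2L),
                                  x = rep(c(1, -1), each = nrow(prs)),
                                  dims = c(n, nrow(prs))),
         rsum = radii[prs[, 1]] + radii[prs[, 2]],
         ref = x)
  }
  cand <- if (config$contact_enabled) rebuild(x) else NULL

  eval_forces <- function(x) {
    dxp <- x[ib, 1] - x[ia, 1]
    dyp <- x[ib, 2] - x[ia, 2]
    g <- sqrt(dxp^2 + dyp^2)
    Tmag <- tensile_force(g, K, g0, eps0)
    if (config$dynamic_visibility) {
      alive <<- alive & (g < gv)
      Tmag[!alive] <- 0
    }
    ft <- Tmag / pmax(g, 1e-12)
    Fx <- as.vector(S %*% (ft * dxp))
    Fy <- as.vector(S %*% (ft * dyp))
    gap <- numeric(0); RN <- numeric(0)
    if (config$contact_enabled) {
      if (max(abs(x - cand$ref)) > margin / 2) cand <<- rebuild(x)
      dxc <- x[cand$b, 1] - x[cand$a, 1]
      dyc <- x[cand$b, 2] - x[cand$a, 2]
      dc <- sqrt(dxc^2 + dyc^2)
      gap <- dc - cand$rsum
      RN <- pmax(-gap, 0) * penalty
      over <- gap < 0
      if (any(over)) {
        # viscous normal damping while overlapping: suppresses contact
        # chatter during relaxation, vanishes at equilibrium (v -> 0), and
        # never turns a contact adhesive (reaction clamped at >= 0)
        ux <- dxc[over] / dc[over]; uy <- dyc[over] / dc[over]
        grate <- (v[cand$b[over], 1] - v[cand$a[over], 1]) * ux +
                 (v[cand$b[over], 2] - v[cand$a[over], 2]) * uy
        RN[over] <- pmax(RN[over] - penalty * dt * grate, 0)
      }
      fc <- -RN / pmax(dc, 1e-12)  # repulsion: a pushed away from b
      Fx <- Fx + as.vector(cand$S %*% (fc * dxc))
      Fy <- Fy + as.vector(cand$S %*% (fc * dyc))
    }
    ncontact <- if (length(RN) && any(RN > 0)) {
      act <- RN > 0
      tabulate(c(cand$a[act], cand$b[act]), n)
    } else integer(n)
    list(Fx = Fx, Fy = Fy, Tmag = Tmag, gap = gap, RN = RN,
         ncontact = ncontact)
  }

  frl <- numeric(nsteps)
  grow <- 0L
  last_frl <- Inf
  ke_prev <- 0

  quench_from <- if (config$precondition && isTRUE(config$quench))
    ceiling(0.8 * nsteps) else nsteps + 1L

  for (s in seq_len(nsteps)) {
    f <- eval_forces(x)
    Fx <- f$Fx; Fy <- f$Fy
    if (!all(is.finite(Fx)) || !all(is.finite(Fy))) {
      bad <- which(!is.finite(Fx) | !is.finite(Fy))[1]
      stop("non-finite force on node ", nodes$id[bad], " at step ", s)
    }
    m_step <- if (config$precondition)
      pmax(mass, dt^2 * (k_node + penalty * f$ncontact) / 0.5) else mass
    # terminal quench: drop the momentum over the last fifth of the run so
    # the state freezes into its (near-)equilibrium instead of chattering
    d_s <- if (s >= quench_from) min(damping, 0.5) else damping
    v[free, 1] <- d_s * (v[free, 1] + Fx[free] / m_step[free] * dt)
    v[free, 2] <- d_s * (v[free, 2] + Fy[free] / m_step[free] * dt)
    if (is.finite(step_limit)) {
      sp <- sqrt(v[, 1]^2 + v[, 2]^2) * dt
      fast <- sp > step_limit
      if (any(fast)) {
        sc <- step_limit / sp[fast]
        v[fast, 1] <- v[fast, 1] * sc
        v[fast, 2] <- v[fast, 2] * sc
      }
    }
    dx <- v[, 1] * dt; dy <- v[, 2] * dt
    x[free, 1] <- x[free, 1] + dx[free]
    x[free, 2] <- x[free, 2] + dy[free]
    frl[s] <- mean(sqrt(dx[free]^2 + dy[free]^2))
    if (config$precondition && isTRUE(config$kinetic_restart)) {
      # kinetic restart (classic dynamic relaxation): zero velocities when
      # kinetic energy peaks, dropping the system near an energy minimum
      ke <- sum(m_step[free] * (v[free, 1]^2 + v[free, 2]^2))
      if (ke < ke_prev) { v[] <- 0; ke_prev <- 0 } else ke_prev <- ke
    }
    # count only clear growth: the velocity ramp toward terminal speed at the
    # start of a run must not trip the divergence guard
    grow <- if (frl[s] > last_frl * 1.01) grow + 1L else 0L
    last_frl <- frl[s]
    if (grow >= 50L)
      stop(sprintf("relaxation diverging: free run length grew for 50 consecutive steps (step %d, frl %.3g um)", s, frl[s]))
  }

  f <- eval_forces(x)  # diagnostics at the final positions
  Fx <- f$Fx; Fy <- f$Fy; Tmag <- f$Tmag; gap <- f$gap; RN <- f$RN
  residual <- if (any(free)) max(sqrt(Fx[free]^2 + Fy[free]^2)) else 0
  contacts <- if (config$contact_enabled && length(RN)) {
    act <- RN > 0
    data.frame(a = cand$a[act], b = cand$b[act],
               gap = gap[act], RN = RN[act])
  } else data.frame(a = integer(0), b = integer(0),
                    gap = numeric(0), RN = numeric(0))
  fixed_idx <- which(!free)
  fa <- data.frame(node = nodes$id[fixed_idx],
                   fx = Fx[fixed_idx], fy = Fy[fixed_idx])
  fa$magnitude <- sqrt(fa$fx^2 + fa$fy^2)
  structure(list(positions = x, velocities = v,
                 tensions = data.frame(a = ia, b = ib, tension = Tmag),
                 contacts = contacts,
                 fa_reactions = fa,
                 free_run_length = if (is.null(state)) frl
                                   else c(state$free_run_length, frl),
                 residual = residual,
                 converged = residual <= config$equilibrium_tol,
                 penetration_max = if (length(gap)) max(-gap, 0) else 0,
                 damping = damping, penalty = penalty,
                 step = (if (is.null(state)) 0L else state$step) + nsteps),
            class = "model_state")
}

#' Advance the model state by one integration step
#'
#' Semi-implicit update: forces (tensile plus contact) are accumulated on each
#' free node, then `v <- damping * (v + F/m * dt)` and `x <- x + v * dt`.
#' Fixed (vinculin) nodes never move.
#'
#' @param model a `cell_model`.
#' @param state a `model_state` from a previous call, or `NULL` to start from
#'   the build positions at rest.
#' @param config a [solver_config()].
#' @return The updated `model_state`.
#' @export
step_state <- function(model, state = NULL, config = solver_config()) {
  engine_run(model, config, 1L, state)
}

#' Relax a cell model to mechanical equilibrium
#'
#' Runs the configured number of fixed steps (default 600) and returns the
#' final state with diagnostics: maximal residual force on free nodes, the
#' per-step free-run-length series (mean free-node displacement per step, a
#' divided-medium stability indicator), maximal contact penetration, and a
#' convergence flag. Convergence is reported, not enforced. The solver is
#' fully deterministic.
#'
#' @param model a `cell_model`.
#' @param config a [solver_config()].
#' @return A `model_state`.
#' @export
relax <- function(model, config = solver_config()) {
  st <- engine_run(model, config, config$steps, NULL)
  if (config$contact_enabled && st$penetration_max > 0.01 * model$d0)
    warning(sprintf("contact penetration %.3g um exceeds 1%% of d0; consider a higher contact_penalty",
                    st$penetration_max))
  st
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> step %d, residual %.3g nN (%s)\n", x$step,
              x$residual, if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final free run length %.3g um/step, %d active contacts, max penetration %.3g um\n",
              x$free_run_length[length(x$free_run_length)],
              nrow(x$contacts), x$penetration_max))
  invisible(x)
}

#' Sum of focal-adhesion reaction forces
#'
#' Total of net-force magnitudes on the fixed (vinculin) nodes: the model's
#' counterpart of the experimentally estimated FA force sum, and the quantity
#' matched during calibration.
#'
#' @param state a `model_state`.
#' @return Force sum in nN.
#' @export
sum_fa_forces <- function(state) {
  sum(state$fa_reactions$magnitude)
}

#' Tension / compression summary of a relaxed state
#'
#' @param state a `model_state`.
#' @return A list: `tension_sum`, `compression_sum`, `ratio`
#'   (compression/tension), `tension_mean` (over taut interactions),
#'   `compression_mean`, `n_tension` (taut interactions), `n_compression`
#'   (active contacts).
#' @export
tension_compression_summary <- function(state) {
  tns <- state$tensions$tension
  act <- tns > 0
  cmp <- state$contacts$RN
  ts <- sum(tns); cs <- sum(cmp)
  list(tension_sum = ts, compression_sum = cs,
       ratio = if (ts > 0) cs / ts else 0,
       tension_mean = if (any(act)) mean(tns[act]) else 0,
       compression_mean = if (length(cmp)) mean(cmp) else 0,
       n_tension = sum(act), n_compression = length(cmp))
}
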
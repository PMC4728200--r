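test_that("the tensile law is pre-strained, slack below threshold, linear above", {
  expect_equal(tensile_force(1, K = 4.4, g0 = 1, eps0 = 0.2), 0.88)
  expect_equal(tensile_force(0.8, K = 4.4, g0 = 1, eps0 = 0.2), 0)  # slack boundary
  expect_equal(tensile_force(1.1, K = 1, g0 = 1, eps0 = 0.2), 0.3)
  expect_error(tensile_force(1, 1, 0, 0.2), "positive")
  # slack whenever g <= (1-eps0)*g0, property over random gaps
  set.seed(5)
  g <- runif(500, 0, 2); g0 <- runif(500, 0.5, 1.5); e <- runif(500, 0.05, 0.5)
  Tm <- tensile_force(g, 1, g0, e)
  expect_true(all(Tm[g <= (1 - e) * g0] == 0))
  expect_true(all(Tm[g > (1 - e) * g0] > 0))
  expect_true(all(Tm >= 0))
})

test_that("the contact law is one-sided, penalty-linear, and off in the MT- scenario", {
  expect_equal(contact_force(0.6, 0.232, 0.232, penalty = 1000), 0)
  expect_equal(contact_force(0.464 - 0.01, 0.232, 0.232, penalty = 1000), 10)
  expect_equal(contact_force(0.3, 0.232, 0.232, penalty = 1000, enabled = FALSE), 0)
  expect_error(contact_force(0, 0.1, 0.1, 10), "coincident")
  expect_error(contact_force(1, -0.1, 0.1, 10), "positive")
})

test_that("a single step follows the damped semi-implicit update exactly", {
  # one free node pulled by one interaction at its rest gap: after one step
  # with damping 1, displacement is (K*eps0/m)*dt^2 toward the anchor
  m <- toy_model(x = c(0, 1), y = c(0, 0), fixed = c(TRUE, FALSE),
                 springs = data.frame(a = 1, b = 2, K = 4.4, g0 = 1))
  cfg <- solver_config(dt = 0.5, damping = 1, precondition = FALSE,
                       contact_enabled = FALSE)
  st <- step_state(m, NULL, cfg)
  expect_equal(st$positions[2, 1], 1 - (4.4 * 0.2 / 0.8) * 0.25, tolerance = 1e-12)
  expect_equal(st$positions[2, 2], 0)
  expect_equal(st$positions[1, ], c(0, 0))  # fixed node untouched
})

test_that("zero-force and symmetric configurations do not move", {
  # all springs exactly slack: nothing moves
  m0 <- toy_model(x = c(0, 0.8), y = c(0, 0), fixed = c(FALSE, FALSE),
                  springs = data.frame(a = 1, b = 2, K = 2, g0 = 1))
  st0 <- step_state(m0, NULL, solver_config(contact_enabled = FALSE))
  expect_equal(st0$positions, cbind(c(0, 0.8), c(0, 0)))
  expect_equal(st0$free_run_length, 0)
  # free node midway between two identical anchors stays there
  m1 <- toy_model(x = c(0, 1, 2), y = c(0, 0, 0), fixed = c(TRUE, FALSE, TRUE),
                  springs = data.frame(a = c(1, 2), b = c(2, 3), K = 3, g0 = 1))
  st1 <- relax(m1, solver_config(steps = 200, contact_enabled = FALSE))
  expect_equal(st1$positions[2, 1], 1, tolerance = 1e-9)
})

test_that("an anchored pre-strained chain loads each anchor with K*eps0", {
  n <- 6
  m <- toy_model(x = 0:(n - 1), y = rep(0, n),
                 fixed = c(TRUE, rep(FALSE, n - 2), TRUE),
                 springs = data.frame(a = 1:(n - 1), b = 2:n, K = 2.5, g0 = 1))
  st <- relax(m, solver_config(steps = 2000, contact_enabled = FALSE))
  expect_true(st$converged)
  # fixed ends at original spacing: every spring stays at g0, T = K*eps0
  expect_equal(st$fa_reactions$magnitude, rep(2.5 * 0.2, 2), tolerance = 1e-6)
  expect_equal(sum_fa_forces(st), 2 * 2.5 * 0.2, tolerance = 1e-6)
  expect_equal(st$tensions$tension, rep(0.5, n - 1), tolerance = 1e-6)
})

test_that("equilibrium of a heterogeneous chain matches the analytic solution", {
  # anchors at 0 and 4, three free nodes, K = 1,2,3,4: uniform tension T
  # with x_i = i-th partial sum of (1 + T/K_i - eps0); closed form below
  K <- 1:4
  Tstar <- (4 - 4 * 0.8) / sum(1 / K)
  gaps <- 1 + Tstar / K - 0.2
  m <- toy_model(x = c(0, 1, 2, 3, 4), y = rep(0, 5),
                 fixed = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                 springs = data.frame(a = 1:4, b = 2:5, K = K, g0 = 1))
  st <- relax(m, solver_config(steps = 4000, contact_enabled = FALSE))
  expect_equal(st$positions[2:4, 1], cumsum(gaps)[1:3], tolerance = 1e-6)
  expect_equal(st$tensions$tension, rep(Tstar, 4), tolerance = 1e-5)
})

test_that("relaxed positions match the energy-minimization oracle (no contacts)", {
  set.seed(21)
  # a 5-node asymmetric truss between two anchors
  m <- toy_model(x = c(0, 0.9, 1.8, 1.1, 2.4), y = c(0, 0.5, 0.4, -0.6, 0),
                 fixed = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                 springs = data.frame(a = c(1, 2, 3, 1, 4, 2),
                                      b = c(2, 3, 5, 4, 5, 4),
                                      K = c(2, 1.5, 2.5, 1, 2, 1.2),
                                      g0 = c(1, 1, 0.8, 1.2, 1.4, 1.2)))
  st <- relax(m, solver_config(steps = 8000, contact_enabled = FALSE,
                               equilibrium_tol = 1e-8))
  xo <- oracle_equilibrium(m, contact_enabled = FALSE)
  expect_lt(max(abs(st$positions - xo)), 1e-6)
})

test_that("relaxed positions match the energy-minimization oracle with an active contact", {
  # two free nodes pulled toward the axis between two anchors; their
  # contactors meet and the penalty contact props them apart
  g0 <- sqrt(1 + 0.5^2)
  m <- toy_model(x = c(0, 1, 1, 2), y = c(0, 0.5, -0.5, 0),
                 fixed = c(TRUE, FALSE, FALSE, TRUE),
                 springs = data.frame(a = c(1, 1, 2, 3), b = c(2, 3, 4, 4),
                                      K = 2, g0 = g0),
                 radius = 0.3, a = 2)
  cfg <- solver_config(steps = 8000, contact_enabled = TRUE,
                       contact_penalty = 200)
  st <- relax(m, cfg)
  xo <- oracle_equilibrium(m, contact_enabled = TRUE, penalty = 200)
  expect_lt(max(abs(st$positions - xo)), 1e-6)
  expect_equal(nrow(st$contacts), 1L)
  expect_true(all(st$contacts$RN > 0))
  # complementarity: reaction only with (slight) penetration
  expect_true(all(st$contacts$gap <= 0))
  # the MT- run of the same model has no contacts and the nodes collapse further
  stm <- relax(m, solver_config(steps = 8000, contact_enabled = FALSE))
  expect_equal(nrow(stm$contacts), 0L)
  expect_lt(abs(stm$positions[2, 2] - stm$positions[3, 2]),
            abs(st$positions[2, 2] - st$positions[3, 2]))
})

test_that("relax reports diagnostics and the engine is deterministic", {
  cell <- generate_cell(small_cell())
  m <- build_cell_model(cell$images, a = 3)
  st1 <- relax(m)
  st2 <- relax(m)
  expect_identical(st1$positions, st2$positions)  # bit-reproducible
  expect_identical(st1$free_run_length, st2$free_run_length)
  expect_equal(st1$step, 600L)
  expect_length(st1$free_run_length, 600L)
  expect_true(all(st1$tensions$tension >= 0))
  expect_true(is.finite(st1$residual))
  # fixed nodes never move
  fixed <- m$nodes$fixed
  expect_equal(st1$positions[fixed, 1], m$nodes$x_um[fixed])
  expect_equal(st1$positions[fixed, 2], m$nodes$y_um[fixed])
})

test_that("unit bookkeeping: pg um / us^2 accelerations integrate to nN forces", {
  # F = m a with m = 0.8 pg and a in um/us^2 gives F in nN exactly: a single
  # undamped step converts a 1 nN force into dv = F/m*dt = 0.625 um/us
  m <- toy_model(x = c(0, 1), y = c(0, 0), fixed = c(TRUE, FALSE),
                 springs = data.frame(a = 1, b = 2, K = 5, g0 = 1))
  cfg <- solver_config(dt = 0.5, damping = 1, precondition = FALSE,
                       contact_enabled = FALSE)
  st <- step_state(m, NULL, cfg)
  # T = K*eps0 = 1 nN exactly; dv = 1/0.8*0.5
  expect_equal(st$velocities[2, 1], -1 / 0.8 * 0.5, tolerance = 1e-12)
})

test_that("tension/compression summary aggregates the state", {
  st <- structure(list(
    tensions = data.frame(a = 1:3, b = 2:4, tension = c(1, 3, 0)),
    contacts = data.frame(a = 1, b = 2, gap = -0.001, RN = 0.5)),
    class = "model_state")
  s <- tension_compression_summary(st)
  expect_equal(s$tension_mean, 2)  # slack member excluded
  expect_equal(s$tension_sum, 4)
  expect_equal(s$compression_sum, 0.5)
  expect_equal(s$ratio, 0.125)
  expect_equal(s$n_tension, 2L)
  st$contacts <- st$contacts[0, ]
  expect_equal(tension_compression_summary(st)$ratio, 0)
  expect_equal(sum_fa_forces(list(fa_reactions = data.frame(magnitude = numeric(0)))), 0)
})
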
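test_that("gray values map to the right-closed density bins", {
  expect_equal(label_of(1.0), 10L)
  expect_equal(label_of(0.1), 1L)   # right-closed: 0.1 belongs to bin 1
  expect_equal(label_of(0.35), 4L)
  expect_equal(label_of(c(0.1000001, 0.2, 0.9000001)), c(2L, 2L, 10L))
  expect_true(is.na(label_of(0)))
  expect_error(label_of(1.2), "\\[0, 1\\]")
  expect_error(label_of(-0.1), "\\[0, 1\\]")
  # every bin boundary lands in the lower bin
  expect_equal(label_of(seq(0.1, 1, 0.1)), 1:10)
})

test_that("2x2 blocks become nodes with kind priority vinculin > nucleus > actin", {
  act <- matrix(0, 4, 6)
  act[1:2, 1:2] <- 0.35          # block (1,1): mean 0.35 -> actin l4
  act[1:2, 3:4] <- c(0.4, 0.4, 0.4, 0.4)  # block (1,2)
  act[3:4, 1:2] <- 0.9           # block (2,1) but overlaps nucleus
  vin <- matrix(FALSE, 4, 6); vin[1, 3] <- TRUE   # one px -> block (1,2) vinculin
  nuc <- matrix(FALSE, 4, 6); nuc[3, 1] <- TRUE   # block (2,1) nucleus
  set <- cell_image_set(channel_image(act, 0.29), vin, nuc,
                        cell_mask = matrix(TRUE, 4, 6))
  nodes <- pixels_to_nodes(set)
  expect_equal(nrow(nodes), 3L)
  n11 <- nodes[nodes$x_um == 0.29 & nodes$y_um == 0.29, ]
  expect_equal(n11$kind, "actin"); expect_equal(n11$label, 4L)
  n12 <- nodes[nodes$x_um == 3 * 0.29, ]
  expect_equal(n12$kind, "vinculin"); expect_true(n12$fixed)
  n21 <- nodes[nodes$y_um == 3 * 0.29 & nodes$x_um == 0.29, ]
  expect_equal(n21$kind, "nucleus"); expect_false(n21$fixed)
  expect_true(all(nodes$mass_pg == 0.8))
  expect_equal(unique(nodes$radius_um), 0.4 * 0.58)
})

test_that("node cap triggers a coarser-binning error", {
  act <- matrix(0.5, 64, 64)
  set <- cell_image_set(channel_image(act, 0.29),
                        matrix(FALSE, 64, 64), matrix(FALSE, 64, 64),
                        cell_mask = matrix(TRUE, 64, 64))
  expect_error(pixels_to_nodes(set, max_nodes = 500L), "coarser binning")
  expect_equal(nrow(pixels_to_nodes(set, binning = 4L, max_nodes = 500L)), 256L)
})

test_that("stiffness follows density labels, the weakest-label rule and the nucleus factor", {
  expect_equal(stiffness_for("actin", "actin", 10L, 10L, 4.4), 4.4)
  expect_equal(stiffness_for("actin", "actin", 3L, 7L, 10), 3.0)
  expect_equal(stiffness_for("nucleus", "nucleus", NA, NA, 4.4), 44)
  expect_equal(stiffness_for("actin", "vinculin", 6L, NA, 2), 1.2)
  expect_equal(stiffness_for("actin", "nucleus", 2L, NA, 2), 0.4)
  expect_error(stiffness_for("actin", "actin", NA, 5L, 1), "unlabeled")
  expect_error(stiffness_for("actin", "actin", 5L, 5L, -1), "positive")
  # monotonicity: raising a label never lowers K
  for (i in 1:9)
    expect_gte(stiffness_for("actin", "actin", i + 1L, 10L, 1),
               stiffness_for("actin", "actin", i, 10L, 1))
})

test_that("interactions connect the 4-neighborhood under the visibility threshold", {
  nodes <- data.frame(id = 1:9, kind = "actin", label = 5L,
                      x_um = rep(c(0.58, 1.16, 1.74), 3),
                      y_um = rep(c(0.58, 1.16, 1.74), each = 3),
                      fixed = FALSE, mass_pg = 0.8, radius_um = 0.232)
  inter <- build_interactions(nodes, a = 2, d0 = 0.58)
  expect_equal(nrow(inter), 12L)  # 3x3 grid: 12 axis-aligned edges, no diagonals
  center <- nodes$id[nodes$x_um == 1.16 & nodes$y_um == 1.16]
  expect_equal(sum(inter$a == center | inter$b == center), 4L)
  expect_true(all(inter$K == 2 * 0.5))
  expect_equal(inter$g0, rep(0.58, 12), tolerance = 1e-12)
  # two nodes beyond g_v are not connected
  pair <- nodes[1:2, ]; pair$x_um <- c(0, 1.2 * 0.58); pair$y_um <- 0
  expect_equal(nrow(build_interactions(pair, 1, 0.58)), 0L)
  expect_equal(nrow(build_interactions(nodes[5, ], 1, 0.58)), 0L)
})

test_that("the interaction graph is simple, symmetric-free and anchors are never linked", {
  cell <- generate_cell(small_cell())
  model <- build_cell_model(cell$images, a = 3)
  inter <- model$interactions
  expect_true(all(inter$a < inter$b))            # one record per unordered pair
  expect_false(any(duplicated(inter[c("a", "b")])))
  expect_false(any(inter$a == inter$b))
  kinds <- model$nodes$kind
  expect_false(any(kinds[inter$a] == "vinculin" & kinds[inter$b] == "vinculin"))
  expect_true(all(inter$g0 <= 1.1 * model$d0 + 1e-9))
})

test_that("the reference cell stays below the node cap after 2x2 binning", {
  cell <- generate_cell(reference_cell())
  nodes <- pixels_to_nodes(cell$images)
  expect_lt(nrow(nodes), 10000L)
  expect_gt(nrow(nodes), 2000L)  # and is a non-trivial model
})

test_that("stiffness rescaling and JSON round trip preserve the model", {
  cell <- generate_cell(small_cell())
  m <- build_cell_model(cell$images, a = 2)
  m2 <- set_stiffness(m, 4)
  expect_equal(m2$interactions$K, 2 * m$interactions$K)
  expect_equal(m2$a, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m3 <- read_model_json(f)
  expect_equal(m3$nodes$x_um, m$nodes$x_um)
  expect_equal(m3$interactions$K, m$interactions$K)
  expect_equal(m3$d0, m$d0)
})
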